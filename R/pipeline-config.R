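# Declarative per-run configuration. One human-readable YAML file holds
# every stage parameter, the input/output paths and the seed, so a
# clinical batch run is reproducible from its config alone; command-line
# flags override individual entries.

#' Default pipeline configuration
#'
#' Returns the complete set of stage parameters with their defaults, as a
#' named list ready to be edited, saved with
#' \code{\link{writePipelineConfig}} and passed to the command-line
#' front end.
#'
#' @param seed integer seed governing all stochastic stages.
#' @param inputDir,outputDir paths recorded for batch runs.
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(seed = 1L, inputDir = ".", outputDir = ".") {
  structure(list(
    seed = as.integer(seed),
    paths = list(input = inputDir, output = outputDir),
    phantom = list(shape = c(64L, 256L, 256L), voxelSize = 0.25,
                   nCells = 20L, nucleusRadius = 2.0,
                   membraneThickness = 0.25, fiberRadius = 0.5,
                   ensheathedFraction = 0.6, cx43Count = 120L,
                   cx43ContactFraction = 0.1, psfSigma = 0.1,
                   photonScale = 200, gainAmplitude = 0.3),
    expansionQC = list(sigma = 1, minArea = 30L, pixelSize = 0.5),
    segmentation = list(scales = c(0.5, 1, 2, 4), nPlanes = 5L,
                        nTrees = 100L, maxPerClass = 4000L,
                        threshold = 0.5, smoothRadius = 1,
                        gainPercentile = 0.2, gainSigmaFrac = 0.125,
                        correctGainChannels = "wga"),
    quantify = list(plaqueFilter = FALSE, sectionThicknessNm = 100,
                    minZExtentNm = 200),
    calcium = list(samplingRate = 4, activityThreshold = 0.10,
                   prominence = 0.10, onsetFraction = 0.2,
                   couplingWindowS = 30)),
    class = "PipelineConfig")
}

#' Save / load a pipeline configuration
#'
#' YAML serialization; \code{readPipelineConfig(writePipelineConfig(x))}
#' returns \code{x} unchanged.
#'
#' @param config a \code{PipelineConfig} list.
#' @param path YAML file path.
#' @return \code{path} invisibly (write); the config (read).
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path,
                   handlers = list(int = function(x) x))
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  structure(yaml::read_yaml(path), class = "PipelineConfig")
}
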