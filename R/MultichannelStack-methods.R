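#' Construct a MultichannelStack
#'
#' @param data numeric array: 3D (z, y, x) for one channel or 4D
#'   (z, y, x, channel).
#' @param channelNames character vector of channel names; defaults to the
#'   array's channel dimnames or \code{"ch1"}, \code{"ch2"}, ...
#' @param voxelSize micrometres per voxel (z, y, x); a scalar is recycled.
#' @param frameInterval seconds between frames for time-resolved data.
#' @return a \linkS4class{MultichannelStack}.
#' @examples
#' a <- array(runif(4 * 8 * 8), dim = c(4, 8, 8))
#' s <- MultichannelStack(a, channelNames = "wga", voxelSize = 0.25)
#' channelNames(s)
#' dim(getChannel(s, "wga"))
#' @export
MultichannelStack <- function(data, channelNames = NULL, voxelSize = c(1, 1, 1),
                              frameInterval = NA_real_) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (is.null(channelNames)) {
    channelNames <- dimnames(data)[[4L]]
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(dim(data)[4L]))
  }
  dimnames(data) <- list(NULL, NULL, NULL, channelNames)
  new("MultichannelStack", data = data, channelNames = channelNames,
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      frameInterval = frameInterval)
}

#' @rdname MultichannelStack-class
#' @aliases channelNames,MultichannelStack-method
setMethod("channelNames", "MultichannelStack", function(x) x@channelNames)

#' @rdname MultichannelStack-class
#' @aliases voxelSize,MultichannelStack-method
setMethod("voxelSize", "MultichannelStack", function(x) x@voxelSize)

#' @rdname MultichannelStack-class
#' @aliases getChannel,MultichannelStack-method
setMethod("getChannel", "MultichannelStack", function(x, name) {
  i <- match(name, x@channelNames)
  if (is.na(i)) stop("no channel named '", name, "'")
  x@data[, , , i]
})

#' @rdname MultichannelStack-class
#' @aliases dim,MultichannelStack-method
#' @export
setMethod("dim", "MultichannelStack", function(x) dim(x@data))

setMethod("show", "MultichannelStack", function(object) {
  d <- dim(object@data)
  cat("MultichannelStack:", d[1L], "x", d[2L], "x", d[3L], "voxels (z,y,x),",
      d[4L], "channel(s)\n")
  cat("  channels:  ", paste(object@channelNames, collapse = ", "), "\n")
  cat("  voxel size:", paste(format(object@voxelSize, digits = 3),
                             collapse = " x "), "um (z,y,x)\n")
  if (!is.na(object@frameInterval))
    cat("  frame interval:", object@frameInterval, "s\n")
  invisible(NULL)
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@shape, collapse = " x "), "voxels at",
      paste(format(object@voxelSize, digits = 3), collapse = " x "),
      "um;", object@nCells, "cells\n")
  cat(sprintf("  fiber radius %.2f um, target ensheathed fraction %.2f\n",
              object@fiberRadius, object@ensheathedFraction))
  cat(sprintf("  %d Cx43 puncta (%.2f-%.2f um), contact fraction %.2f\n",
              object@cx43Count, object@cx43Diameter[1L],
              object@cx43Diameter[2L], object@cx43ContactFraction))
  cat(sprintf("  photon scale %g, gain amplitude %.2f, seed %d\n",
              object@photonScale, object@gainAmplitude, object@seed))
  invisible(NULL)
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", paste(dim(object@cellLabels), collapse = " x "),
      "voxels;", max(object@cellLabels), "cells\n")
  cat(sprintf("  fiber voxels: %d (%d ensheathed), Cx43 voxels: %d\n",
              sum(object@fiberMask), sum(object@fiberEnsheathedMask),
              sum(object@cx43Mask)))
  cat(sprintf("  true ensheathment ratio: %.4f, true Cx43 contact ratio: %.4f\n",
              object@trueEnsheathmentRatio, object@trueCx43ContactRatio))
  invisible(NULL)
})

setMethod("show", "RenderedPhantom", function(object) {
  cat("RenderedPhantom (seed", object@spec@seed, ")\n")
  show(object@stack)
  invisible(NULL)
})

setMethod("show", "VoxelClassifier", function(object) {
  cat("VoxelClassifier for channel '", object@channel,
      "': random-forest ensemble, feature scales {",
      paste(object@scales, collapse = ", "), "} voxels\n", sep = "")
  cat("  trained on z-planes", paste(range(object@trainPlanes),
                                     collapse = "-"),
      "; threshold", object@threshold, "\n")
  invisible(NULL)
})

#' @rdname CalciumTraceSet-class
#' @aliases cellType,CalciumTraceSet-method
setMethod("cellType", "CalciumTraceSet", function(x) x@cellType)

#' @rdname CalciumTraceSet-class
#' @aliases samplingRate,CalciumTraceSet-method
setMethod("samplingRate", "CalciumTraceSet", function(x) x@samplingRate)

setMethod("show", "CalciumTraceSet", function(object) {
  cat("CalciumTraceSet:", ncol(object@traces), "ROIs x",
      nrow(object@traces), "frames at", object@samplingRate, "Hz",
      if (object@normalized) "(dF = F/F0)" else "(raw)", "\n")
  cat("  ", sum(object@cellType == "keratinocyte"), "keratinocyte(s),",
      sum(object@cellType == "neurite"), "neurite(s)\n")
  invisible(NULL)
})
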