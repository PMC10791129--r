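# TIFF stack IO. Pixel data go through the tiff package as multi-page
# TIFFs (pages ordered z within channel); stack metadata (axis order,
# channel names, voxel size, intensity scale, storage type) travel in a
# JSON sidecar next to the TIFF, because baseline TIFF tags cannot carry
# them portably. write/read round-trips are lossless for integer dtypes
# and float32-precision for floating point data.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a multichannel stack to TIFF + JSON sidecar
#'
#' @param stack a \linkS4class{MultichannelStack}.
#' @param path output TIFF path; metadata go to \code{<path>.json}.
#' @param dtype storage type: \code{"uint16"} (default), \code{"uint8"}
#'   or \code{"float32"}. Integer dtypes require integer-valued data
#'   within range.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, dtype = c("uint16", "uint8", "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(is(stack, "MultichannelStack"))
  d <- dim(stack@data)
  if (dtype %in% c("uint8", "uint16")) {
    maxv <- if (dtype == "uint8") 255 else 65535
    if (any(stack@data != round(stack@data)) || max(stack@data) > maxv)
      stop("data not representable as ", dtype)
    norm <- stack@data / maxv
    scale <- maxv
    bits <- if (dtype == "uint8") 8L else 16L
  } else {
    scale <- max(stack@data, 1e-12)
    norm <- stack@data / scale
    bits <- 32L
  }
  pages <- vector("list", d[4L] * d[1L])
  k <- 0L
  for (ci in seq_len(d[4L])) {
    for (zi in seq_len(d[1L])) {
      k <- k + 1L
      pages[[k]] <- matrix(norm[zi, , , ci], d[2L], d[3L])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- list(shape = d, pageOrder = "z-within-channel",
               axes = "zyxc", channelNames = stack@channelNames,
               voxelSize = stack@voxelSize, scale = scale, dtype = dtype)
  if (!is.na(stack@frameInterval))
    meta$frameInterval <- stack@frameInterval
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel stack from TIFF (+ JSON sidecar)
#'
#' Restores a stack written by \code{\link{writeStack}}. Without a
#' sidecar, a plain (multi-page) TIFF is read as a single-channel z-stack
#' and missing calibration falls back to defaults with a warning.
#'
#' @param path TIFF path.
#' @param channelNames,voxelSize overrides when no sidecar is present.
#' @return a \linkS4class{MultichannelStack}.
#' @export
readStack <- function(path, channelNames = NULL, voxelSize = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    arr <- array(0, d)
    k <- 0L
    for (ci in seq_len(d[4L])) {
      for (zi in seq_len(d[1L])) {
        k <- k + 1L
        arr[zi, , , ci] <- pages[[k]]
      }
    }
    arr <- arr * meta$scale
    if (meta$dtype %in% c("uint8", "uint16")) arr <- round(arr)
    fi <- suppressWarnings(as.numeric(meta$frameInterval))
    MultichannelStack(arr, channelNames = meta$channelNames,
                      voxelSize = meta$voxelSize,
                      frameInterval = if (length(fi)) fi else NA_real_)
  } else {
    nz <- length(pages)
    dyx <- dim(pages[[1L]])
    arr <- array(0, c(nz, dyx[1L], dyx[2L], 1L))
    for (zi in seq_len(nz)) arr[zi, , , 1L] <- pages[[zi]]
    if (is.null(voxelSize)) {
      warning("no calibration metadata for '", path,
              "'; assuming 1 um isotropic voxels")
      voxelSize <- c(1, 1, 1)
    }
    MultichannelStack(arr,
                      channelNames = if (is.null(channelNames)) "ch1"
                      else channelNames,
                      voxelSize = voxelSize)
  }
}

.resultColumns <- c("sample_id", "roi_id", "group", "n_pgp", "n_pgp_wga",
                    "n_pgp_cx43_wga", "ensheathment_ratio",
                    "cx43_contact_ratio", "expansion_factor", "qc_flags")

#' Write / read a per-ROI result table
#'
#' CSV with a fixed column order; ratios are serialized as decimal
#' fractions, never percent.
#'
#' @param table data.frame from \code{\link{resultTable}}.
#' @param path CSV path.
#' @return \code{path} invisibly (write); the table (read).
#' @export
writeResults <- function(table, path) {
  missing <- setdiff(.resultColumns, names(table))
  for (m in missing) table[[m]] <- if (m == "qc_flags") "" else NA
  utils::write.csv(table[, .resultColumns, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(qc_flags = "character",
                                 sample_id = "character",
                                 roi_id = "character"))
}

#' Read a per-nucleus measurement table
#'
#' CSV layout for externally measured nuclei (one row per nucleus):
#' columns \code{section_id}, \code{condition} (\code{pre}/\code{post}),
#' \code{area_um2} and optionally \code{equiv_diameter_um} (computed from
#' the area as 2*sqrt(area/pi) when absent).
#'
#' @param path CSV path.
#' @return data.frame in the layout of \code{\link{measureNuclei}}.
#' @export
readNucleusTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "condition", "area_um2")
  if (!all(need %in% names(tab)))
    stop("nucleus table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$condition %in% c("pre", "post")))
    stop("condition must be 'pre' or 'post'")
  if (is.null(tab$equiv_diameter_um))
    tab$equiv_diameter_um <- 2 * sqrt(tab$area_um2 / pi)
  tab
}

#' Write phantom truth and rendering to disk
#'
#' Writes the rendered four-channel stack as TIFF (+ sidecar), each truth
#' mask as a single-channel 8-bit TIFF (0/255), and a JSON sidecar with
#' the spec parameters, seed, designed true ratios and the epidermal box.
#'
#' @param phantom list with \code{truth} and \code{rendered} from
#'   \code{\link{simulatePhantom}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- phantom$truth
  spec <- truth@spec
  writeStack(phantom$rendered@stack, file.path(dir, "rendered.tif"),
             dtype = "float32")
  masks <- list(nucleus = truth@nucleusMask, membrane = truth@membraneMask,
                fiber = truth@fiberMask, cx43 = truth@cx43Mask,
                fiber_ensheathed = truth@fiberEnsheathedMask)
  for (nm in names(masks)) {
    m <- MultichannelStack(array(255 * as.numeric(masks[[nm]]),
                                 c(dim(masks[[nm]]), 1L)),
                           channelNames = nm, voxelSize = spec@voxelSize)
    writeStack(m, file.path(dir, paste0("truth_", nm, ".tif")),
               dtype = "uint8")
  }
  sidecar <- list(
    seed = spec@seed, shape = spec@shape, voxelSize = spec@voxelSize,
    nCells = spec@nCells, ensheathedFraction = spec@ensheathedFraction,
    cx43Count = spec@cx43Count,
    cx43ContactFraction = spec@cx43ContactFraction,
    photonScale = spec@photonScale, gainAmplitude = spec@gainAmplitude,
    trueEnsheathmentRatio = truth@trueEnsheathmentRatio,
    trueCx43ContactRatio = truth@trueCx43ContactRatio,
    epidermalBox = truth@epidermalBox)
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
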