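# Retrospective flat-field (shading) correction. The smooth multiplicative
# illumination field of a channel is estimated from the stack itself: a
# per-pixel low-percentile projection across z captures background-level
# signal (which scales with the gain), heavy Gaussian smoothing removes
# structure, and normalization to unit mean makes the correction
# intensity-preserving. This is a percentile-projection retrospective
# flat-field; the interface admits a drop-in low-rank decomposition
# estimator should one be needed.

#' Estimate the multiplicative illumination field of a channel
#'
#' @param channel 3D array (z, y, x) with at least 4 z-planes.
#' @param percentile per-pixel projection quantile across z (default
#'   0.2; low percentiles track background rather than structures).
#' @param sigmaFrac smoothing sigma as a fraction of each lateral image
#'   dimension (default 1/8).
#' @return numeric (y, x) matrix, strictly positive, unit mean. A
#'   constant-zero channel yields an identity field with a warning.
#' @export
estimateGainField <- function(channel, percentile = 0.2, sigmaFrac = 1 / 8) {
  d <- dim(channel)
  stopifnot(length(d) == 3L)
  if (d[1L] < 4L) stop("need at least 4 z-planes to estimate a gain field")
  if (all(channel == 0)) {
    warning("constant-zero channel; returning identity gain field")
    return(matrix(1, d[2L], d[3L]))
  }
  # average over axial windows first: the low percentile of a windowed
  # mean keeps its robustness to sparse structures while shrinking the
  # skew bias of low Poisson quantiles by sqrt(window)
  w <- max(1L, min(8L, d[1L] %/% 4L))
  zs <- .convAxis(channel, rep(1 / w, w), 1L)
  proj <- apply(zs, c(2L, 3L), stats::quantile, probs = percentile,
                names = FALSE)
  # mask pixels whose projection is still dominated by structure (e.g.
  # membrane walls running through every z-plane) and infill them by
  # normalized smoothing of the remaining background pixels
  bg <- proj <= 2 * stats::median(proj)
  if (!any(bg)) bg[] <- TRUE
  smooth2 <- function(m) {
    matrix(gaussSmooth3D(array(m, c(1L, d[2L], d[3L])),
                         c(0, sigmaFrac * d[2L], sigmaFrac * d[3L])),
           d[2L], d[3L])
  }
  field <- smooth2(proj * bg) / pmax(smooth2(bg * 1), 1e-12)
  field <- pmax(field, 1e-9 * max(field))
  field / mean(field)
}

#' Divide a channel by its illumination field
#'
#' @param channel 3D array (z, y, x).
#' @param field (y, x) gain field, e.g. from
#'   \code{\link{estimateGainField}}.
#' @return corrected 3D array.
#' @export
correctIllumination <- function(channel, field) {
  d <- dim(channel)
  stopifnot(identical(dim(field), d[2:3]), all(field > 0))
  field3 <- aperm(array(field, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  channel / field3
}
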