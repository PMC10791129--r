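# Calcium trace analysis for keratinocyte / sensory-neurite co-cultures:
# dF = F/F0 normalization with F0 the first time point, spontaneous
# activity calling at a >= 10% increase, peak/onset detection, and
# keratinocyte-to-neurite lead-lag coupling.

#' Construct a CalciumTraceSet
#'
#' @param traces numeric matrix, frames x ROIs, column names = ROI ids.
#' @param cellType "keratinocyte" or "neurite" per ROI.
#' @param samplingRate frames per second (default 4).
#' @param normalized whether traces are already dF = F/F0.
#' @return a \linkS4class{CalciumTraceSet}.
#' @export
CalciumTraceSet <- function(traces, cellType, samplingRate = 4,
                            normalized = FALSE) {
  traces <- as.matrix(traces)
  if (is.null(colnames(traces)))
    colnames(traces) <- paste0("roi", seq_len(ncol(traces)))
  new("CalciumTraceSet", traces = traces,
      cellType = rep_len(cellType, ncol(traces)),
      samplingRate = samplingRate, normalized = normalized)
}

#' Extract per-ROI traces from a time-lapse stack
#'
#' Mean intensity inside each ROI mask per frame.
#'
#' @param timelapse numeric 3D array (y, x, frames).
#' @param roiLabels integer (y, x) label matrix; 0 = background, each
#'   positive label is one ROI.
#' @param cellType cell type per ROI (in label order).
#' @param samplingRate frames per second.
#' @return a raw \linkS4class{CalciumTraceSet}.
#' @export
extractTraces <- function(timelapse, roiLabels, cellType = "keratinocyte",
                          samplingRate = 4) {
  d <- dim(timelapse)
  stopifnot(length(d) == 3L, identical(dim(roiLabels), d[1:2]))
  ids <- sort(unique(as.integer(roiLabels[roiLabels > 0L])))
  if (!length(ids)) stop("no ROIs in label image")
  flat <- matrix(timelapse, nrow = d[1L] * d[2L], ncol = d[3L])
  traces <- vapply(ids, function(i) {
    px <- which(roiLabels == i)
    if (!length(px)) stop("empty ROI mask for label ", i)
    colMeans(flat[px, , drop = FALSE])
  }, numeric(d[3L]))
  colnames(traces) <- paste0("roi", ids)
  CalciumTraceSet(traces, cellType = cellType, samplingRate = samplingRate)
}

#' Normalize traces to dF = F/F0
#'
#' F0 is the intensity at the first time point (optionally the mean of
#' the first \code{baselineFrames} frames as a robust alternative, off by
#' default). Traces with F0 <= 0 are flagged and excluded with a warning.
#'
#' @param tset a raw \linkS4class{CalciumTraceSet}.
#' @param baselineFrames number of initial frames defining F0 (default 1:
#'   the first time point exactly).
#' @return a normalized \linkS4class{CalciumTraceSet}.
#' @export
normalizeTraces <- function(tset, baselineFrames = 1L) {
  tr <- tset@traces
  f0 <- if (baselineFrames == 1L) tr[1L, ] else
    colMeans(tr[seq_len(baselineFrames), , drop = FALSE])
  bad <- !is.finite(f0) | f0 <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " trace(s) with F0 <= 0: ",
            paste(colnames(tr)[bad], collapse = ", "))
    tr <- tr[, !bad, drop = FALSE]
    f0 <- f0[!bad]
  }
  norm <- sweep(tr, 2L, f0, "/")
  if (baselineFrames == 1L) norm[1L, ] <- 1  # exact by definition
  new("CalciumTraceSet", traces = norm,
      cellType = tset@cellType[!bad], samplingRate = tset@samplingRate,
      normalized = TRUE)
}

#' Relative-change view of normalized traces
#'
#' Returns (F - F0)/F0 = dF - 1 as a plain matrix, for interoperability
#' with tools using the relative-change convention. The package-native
#' scale is the ratio F/F0.
#'
#' @param tset a normalized \linkS4class{CalciumTraceSet}.
#' @return numeric matrix, frames x ROIs.
#' @export
relativeTraces <- function(tset) {
  stopifnot(tset@normalized)
  tset@traces - 1
}

#' Call spontaneously active ROIs
#'
#' A ROI is spontaneously active if its dF reaches at least a 10%
#' increase over F0 at any time point, i.e. max dF >= 1 + threshold
#' (inclusive: a peak of exactly 1.10 is active).
#'
#' @param tset a normalized \linkS4class{CalciumTraceSet}.
#' @param threshold relative increase (default 0.10).
#' @return data.frame: roi_id, cell_type, max_df, threshold, active.
#' @export
callActivity <- function(tset, threshold = 0.10) {
  stopifnot(tset@normalized)
  maxDf <- apply(tset@traces, 2L, max)
  data.frame(roi_id = colnames(tset@traces), cell_type = tset@cellType,
             max_df = as.numeric(maxDf), threshold = threshold,
             active = as.numeric(maxDf) >= 1 + threshold,
             stringsAsFactors = FALSE)
}

#' Detect peaks and onsets in a normalized trace
#'
#' Local maxima of a moving-average-smoothed dF trace with prominence at
#' least \code{prominence}; the onset of a peak is the last frame before
#' it at which dF is at or below 1 + onsetFraction * (peak - 1).
#'
#' @param trace numeric normalized trace (dF, starts at 1).
#' @param samplingRate frames per second.
#' @param smoothFrames moving-average window, frames (odd; default 5).
#' @param prominence minimum peak prominence on the dF scale.
#' @param onsetFraction fraction of the peak rise defining the onset.
#' @return data.frame: time_s, value, amplitude, prominence, onset_s.
#' @export
detectPeaks <- function(trace, samplingRate = 4, smoothFrames = 5L,
                        prominence = 0.10, onsetFraction = 0.2) {
  n <- length(trace)
  sm <- as.numeric(stats::filter(trace, rep(1 / smoothFrames, smoothFrames),
                                 sides = 2L))
  sm[is.na(sm)] <- trace[is.na(sm)]
  cand <- which(diff(sign(diff(sm))) < 0) + 1L
  out <- list()
  for (i in cand) {
    v <- sm[i]
    # prominence: drop to the higher of the two base minima, where each
    # base extends to the nearest sample exceeding the peak value
    left <- i - 1L
    lmin <- v
    while (left >= 1L && sm[left] <= v) {
      lmin <- min(lmin, sm[left]); left <- left - 1L
    }
    right <- i + 1L
    rmin <- v
    while (right <= n && sm[right] <= v) {
      rmin <- min(rmin, sm[right]); right <- right + 1L
    }
    prom <- v - max(lmin, rmin)
    if (prom < prominence) next
    onsetLevel <- 1 + onsetFraction * (v - 1)
    before <- which(sm[seq_len(i)] <= onsetLevel)
    onset <- if (length(before)) max(before) else 1L
    out[[length(out) + 1L]] <- data.frame(
      time_s = (i - 1L) / samplingRate, value = v, amplitude = v - 1,
      prominence = prom, onset_s = (onset - 1L) / samplingRate)
  }
  if (!length(out))
    return(data.frame(time_s = numeric(0), value = numeric(0),
                      amplitude = numeric(0), prominence = numeric(0),
                      onset_s = numeric(0)))
  do.call(rbind, out)
}

#' Detect peaks for every ROI of a trace set
#'
#' @param tset a normalized \linkS4class{CalciumTraceSet}.
#' @param ... passed to \code{\link{detectPeaks}}.
#' @return named list of per-ROI peak data.frames.
#' @export
detectPeakSet <- function(tset, ...) {
  stopifnot(tset@normalized)
  out <- lapply(seq_len(ncol(tset@traces)), function(i) {
    detectPeaks(tset@traces[, i], samplingRate = tset@samplingRate, ...)
  })
  names(out) <- colnames(tset@traces)
  out
}

#' Score keratinocyte-to-neurite temporal coupling
#'
#' For each neurite peak, the nearest earlier keratinocyte onset within
#' \code{windowS} seconds forms a coupling event with
#' lead = neurite peak time - keratinocyte onset time (positive =
#' keratinocyte precedes). Pairs where either ROI is inactive yield no
#' events.
#'
#' @param calls activity table from \code{\link{callActivity}}.
#' @param peaks per-ROI peak list from \code{\link{detectPeakSet}}.
#' @param pairs data.frame with columns \code{keratinocyte},
#'   \code{neurite} (ROI ids of spatially associated pairs).
#' @param windowS coupling window, seconds (default 30).
#' @return data.frame: keratinocyte, neurite, k_onset_s, n_peak_s,
#'   lead_s.
#' @export
leadLagCoupling <- function(calls, peaks, pairs, windowS = 30) {
  ev <- list()
  for (i in seq_len(nrow(pairs))) {
    kid <- pairs$keratinocyte[i]
    nid <- pairs$neurite[i]
    actK <- calls$active[match(kid, calls$roi_id)]
    actN <- calls$active[match(nid, calls$roi_id)]
    if (!isTRUE(actK) || !isTRUE(actN)) next
    kOnsets <- peaks[[kid]]$onset_s
    for (tPeak in peaks[[nid]]$time_s) {
      earlier <- kOnsets[kOnsets <= tPeak & tPeak - kOnsets <= windowS]
      if (!length(earlier)) next
      kOn <- max(earlier)
      ev[[length(ev) + 1L]] <- data.frame(
        keratinocyte = kid, neurite = nid, k_onset_s = kOn,
        n_peak_s = tPeak, lead_s = tPeak - kOn,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(ev))
    return(data.frame(keratinocyte = character(0), neurite = character(0),
                      k_onset_s = numeric(0), n_peak_s = numeric(0),
                      lead_s = numeric(0)))
  do.call(rbind, ev)
}

#' Simulate a coupled keratinocyte/neurite trace pair
#'
#' Synthetic 4 Hz recording of one keratinocyte and one neurite: the
#' keratinocyte shows slow, wide calcium rises (Gaussian bumps, sigma
#' \code{kSigmaS}), the neurite sharp ones (sigma \code{nSigmaS}); each
#' neurite peak is placed \code{leadS} seconds after the keratinocyte's
#' 20%-rise onset so the designed keratinocyte lead is exactly
#' \code{leadS}. Gaussian noise is added to both traces.
#'
#' @param leadS designed keratinocyte lead, seconds.
#' @param nEvents number of coupled events.
#' @param durationS recording length, seconds (default 240).
#' @param samplingRate frames per second (default 4).
#' @param kAmp,nAmp bump amplitudes on the dF scale.
#' @param kSigmaS,nSigmaS bump widths, seconds.
#' @param noiseSd additive noise SD.
#' @param onsetFraction onset definition used to place the neurite peak
#'   (must match the detector's).
#' @param seed RNG seed.
#' @return list with \code{tset} (raw \linkS4class{CalciumTraceSet},
#'   ROIs "ker" and "neu") and \code{trueLeadS}.
#' @export
simulateCoupledPair <- function(leadS = 2, nEvents = 3, durationS = 240,
                                samplingRate = 4, kAmp = 0.5, nAmp = 0.4,
                                kSigmaS = 4, nSigmaS = 1, noiseSd = 0.01,
                                onsetFraction = 0.2, seed = 1) {
  .withSeed(seed, {
    t <- seq(0, durationS - 1 / samplingRate, by = 1 / samplingRate)
    # keratinocyte onset (onsetFraction of rise) precedes the bump center
    onsetOffset <- kSigmaS * sqrt(2 * log(1 / onsetFraction))
    centers <- seq(40, durationS - 40, length.out = nEvents) +
      stats::runif(nEvents, -5, 5)
    ker <- rep(1, length(t))
    neu <- rep(1, length(t))
    for (ct in centers) {
      ker <- ker + kAmp * exp(-(t - ct)^2 / (2 * kSigmaS^2))
      nCenter <- (ct - onsetOffset) + leadS
      neu <- neu + nAmp * exp(-(t - nCenter)^2 / (2 * nSigmaS^2))
    }
    traces <- cbind(ker = ker * 100, neu = neu * 80)  # arbitrary raw scale
    traces <- traces + matrix(stats::rnorm(length(traces),
                                           sd = noiseSd * 100),
                              ncol = 2L,
                              dimnames = list(NULL, c("ker", "neu")))
    list(tset = CalciumTraceSet(traces,
                                cellType = c("keratinocyte", "neurite"),
                                samplingRate = samplingRate),
         trueLeadS = leadS)
  })
}
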