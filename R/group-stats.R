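# Group comparison of per-ROI ratios. The sampling unit is the ROI; the
# test is a two-sided Mann-Whitney U, exact by full enumeration of all
# choose(n1 + n2, n1) group assignments for small tie-free samples, else a
# normal approximation with tie and continuity correction.

#' Two-sided Mann-Whitney U test
#'
#' @param x,y numeric samples for the two groups.
#' @param exactMax use the exact enumeration when \code{length(x) +
#'   length(y) <= exactMax} and there are no ties (default 20).
#' @return list with \code{U} (statistic for \code{x}), \code{p}
#'   (two-sided) and \code{method}, one of \code{"exact"} or
#'   \code{"normal-approx-tie-corrected"}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, exactMax = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n <= exactMax) {
    # null distribution of U by full enumeration of group assignments
    comb <- utils::combn(n, n1)
    Us <- colSums(matrix(r[comb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    tieTerm <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal-approx-tie-corrected"
  }
  list(U = U, p = p, method = method)
}

#' Per-group descriptives and Mann-Whitney comparison
#'
#' Summarizes a per-ROI statistic by group (n, mean, SD with n-1
#' denominator, median, IQR, min, max) and, when two groups with at least
#' two observations each are present, compares them with the two-sided
#' Mann-Whitney U test. Missing values (e.g. flagged fiber-free ROIs) are
#' dropped with a count.
#'
#' @param values numeric per-ROI statistic (e.g. ensheathment ratios).
#' @param groups group label per value (e.g. "HC" / "SFN").
#' @return list with \code{perGroup} (data.frame of descriptives),
#'   \code{U}, \code{p}, \code{method} (test fields \code{NA} when not
#'   applicable) and \code{nDropped}.
#' @export
summarizeGroups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  nDropped <- sum(!keep)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  if (!length(values)) stop("no finite values to summarize")
  gs <- split(values, groups)
  perGroup <- do.call(rbind, lapply(names(gs), function(g) {
    v <- gs[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v),
               iqr = stats::IQR(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  out <- list(perGroup = perGroup, U = NA_real_, p = NA_real_,
              method = NA_character_, nDropped = nDropped)
  if (length(gs) == 2L && all(lengths(gs) >= 2L)) {
    mw <- mannWhitneyU(gs[[1L]], gs[[2L]])
    out[c("U", "p", "method")] <- mw
  }
  out
}
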