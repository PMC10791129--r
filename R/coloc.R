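# Voxel colocalization statistics of the neuro-cutaneous unit.
#
# The two headline quantities are pure voxel-count ratios inside an
# epidermal 3D box:
#   ensheathment ratio = [px(PGP9.5) - px(PGP9.5 & WGA)] / px(PGP9.5)
#   Cx43 contact ratio =  px(PGP9.5 & Cx43 & WGA)        / px(PGP9.5)
# Colocalization is voxel-wise logical AND with no distance tolerance.

#' Define an epidermal 3D box
#'
#' Axis-aligned box delimiting the epidermis inside a volume, used to
#' exclude dermal fiber signal below and the stratum corneum above from
#' all voxel counting. Bounds are 1-based inclusive integer ranges per
#' axis, in (z, y, x) order.
#'
#' @param zlim,ylim,xlim integer (lo, hi) pairs, lo <= hi, lo >= 1.
#' @return an object of class \code{EpidermalBox}.
#' @examples
#' epidermalBox(c(5, 60), c(2, 127), c(2, 127))
#' @export
epidermalBox <- function(zlim, ylim, xlim) {
  box <- list(z = as.integer(zlim), y = as.integer(ylim),
              x = as.integer(xlim))
  for (ax in names(box)) {
    b <- box[[ax]]
    if (length(b) != 2L || any(is.na(b)) || b[1L] < 1L || b[2L] < b[1L])
      stop("invalid ", ax, " bounds: need integer lo <= hi with lo >= 1")
  }
  structure(box, class = "EpidermalBox")
}

#' Crop a volume to an epidermal box
#'
#' @param vol 3D array (z, y, x).
#' @param box an \code{\link{epidermalBox}}; \code{NULL} keeps the full
#'   volume.
#' @return the sub-volume inside the box.
#' @export
cropBox <- function(vol, box = NULL) {
  if (is.null(box)) return(vol)
  d <- dim(vol)
  if (box$z[2L] > d[1L] || box$y[2L] > d[2L] || box$x[2L] > d[3L])
    stop("epidermal box exceeds volume bounds (",
         paste(d, collapse = "x"), ")")
  vol[box$z[1L]:box$z[2L], box$y[1L]:box$y[2L], box$x[1L]:box$x[2L],
      drop = FALSE]
}

#' Count colocalized voxels inside an epidermal box
#'
#' Counts fiber (PGP9.5) voxels, fiber voxels colocalized with membrane
#' (WGA), and fiber voxels triple-colocalized with Cx43 and membrane,
#' restricted to \code{box}. Colocalization is strict voxel-wise AND.
#'
#' @param pgpMask,wgaMask logical 3D arrays of identical shape.
#' @param cx43Mask logical 3D array, or \code{NULL} if no Cx43 channel was
#'   recorded (the triple count is then \code{NA}).
#' @param box optional \code{\link{epidermalBox}}.
#' @return a \code{ColocCounts} list with elements \code{nPgp},
#'   \code{nPgpWga}, \code{nPgpCx43Wga} and \code{box}.
#' @examples
#' p <- array(FALSE, c(4, 8, 8)); p[2, 3, 3:6] <- TRUE
#' w <- array(FALSE, c(4, 8, 8)); w[2, 3, 5:6] <- TRUE
#' countColocalization(p, w, NULL)
#' @export
countColocalization <- function(pgpMask, wgaMask, cx43Mask = NULL,
                                box = NULL) {
  if (!identical(dim(pgpMask), dim(wgaMask)))
    stop("mask shape mismatch")
  if (!is.null(cx43Mask) && !identical(dim(cx43Mask), dim(pgpMask)))
    stop("mask shape mismatch")
  p <- cropBox(pgpMask, box)
  w <- cropBox(wgaMask, box)
  nPgp <- sum(p)
  nPgpWga <- sum(p & w)
  nTriple <- if (is.null(cx43Mask)) NA_integer_ else
    sum(p & w & cropBox(cx43Mask, box))
  structure(list(nPgp = as.integer(nPgp), nPgpWga = as.integer(nPgpWga),
                 nPgpCx43Wga = nTriple, box = box),
            class = "ColocCounts")
}

#' Fiber ensheathment ratio
#'
#' Fraction of fiber voxels not colocalized with membrane signal, the
#' voxel-count correlate of nerve-fiber ensheathment by keratinocytes:
#' (nPgp - nPgpWga) / nPgp. Undefined (NA, flagged) when the box contains
#' no fiber voxels; a fiber-free ROI must not enter group statistics as 0.
#'
#' @param counts a \code{ColocCounts} from
#'   \code{\link{countColocalization}}.
#' @return fraction in [0, 1], or \code{NA} with attribute
#'   \code{qcFlag = "no_fiber_voxels"}.
#' @export
ensheathmentRatio <- function(counts) {
  if (counts$nPgp == 0L)
    return(structure(NA_real_, qcFlag = "no_fiber_voxels"))
  (counts$nPgp - counts$nPgpWga) / counts$nPgp
}

#' Cx43 contact ratio
#'
#' Fraction of fiber voxels triple-colocalized with Cx43 and membrane:
#' nPgpCx43Wga / nPgp. Undefined (NA, flagged) when no fiber voxels.
#'
#' @inheritParams ensheathmentRatio
#' @return fraction in [0, 1], or flagged \code{NA}.
#' @export
cx43ContactRatio <- function(counts) {
  if (counts$nPgp == 0L)
    return(structure(NA_real_, qcFlag = "no_fiber_voxels"))
  counts$nPgpCx43Wga / counts$nPgp
}

#' Quantify one ROI
#'
#' Runs the full counting step for one region of interest: crop to the
#' epidermal box, count colocalized voxels, compute both ratios. Optionally
#' applies the plaque-persistence filter to the Cx43 mask first (off by
#' default; it is a serial-section criterion, not part of the expansion
#' pipeline).
#'
#' @param pgpMask,wgaMask,cx43Mask logical 3D masks (fiber, membrane,
#'   Cx43).
#' @param box optional \code{\link{epidermalBox}}.
#' @param sampleId,roiId,group identifiers carried into the result row;
#'   \code{group} is typically \code{"HC"} or \code{"SFN"}.
#' @param plaqueFilter apply \code{\link{plaquePersistenceFilter}} to the
#'   Cx43 mask before counting.
#' @param sectionThicknessNm section thickness used by the plaque filter.
#' @return an \code{NCUResult} list: ids, \code{counts},
#'   \code{ensheathmentRatio}, \code{cx43ContactRatio}, \code{qcFlags}.
#' @export
quantifyROI <- function(pgpMask, wgaMask, cx43Mask = NULL, box = NULL,
                        sampleId = "sample", roiId = "roi1",
                        group = c("HC", "SFN", "other"),
                        plaqueFilter = FALSE, sectionThicknessNm = 100) {
  group <- match.arg(group)
  if (plaqueFilter && !is.null(cx43Mask))
    cx43Mask <- plaquePersistenceFilter(
      cx43Mask, sectionThicknessNm = sectionThicknessNm)
  counts <- countColocalization(pgpMask, wgaMask, cx43Mask, box)
  er <- ensheathmentRatio(counts)
  cr <- cx43ContactRatio(counts)
  flags <- unique(c(attr(er, "qcFlag"), attr(cr, "qcFlag")))
  structure(list(sampleId = sampleId, roiId = roiId, group = group,
                 counts = counts,
                 ensheathmentRatio = as.numeric(er),
                 cx43ContactRatio = as.numeric(cr),
                 qcFlags = if (length(flags)) flags else character(0)),
            class = "NCUResult")
}

#' Collect NCU results into a table
#'
#' One row per ROI with identifiers, voxel counts, both ratios (as
#' fractions, not percent) and QC flags; the layout written by
#' \code{\link{writeResults}}.
#'
#' @param results list of \code{NCUResult} objects.
#' @param expansionFactor optional per-ROI expansion factor column.
#' @return data.frame with one row per ROI.
#' @export
resultTable <- function(results, expansionFactor = NA_real_) {
  if (inherits(results, "NCUResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(sample_id = r$sampleId, roi_id = r$roiId, group = r$group,
               n_pgp = r$counts$nPgp, n_pgp_wga = r$counts$nPgpWga,
               n_pgp_cx43_wga = r$counts$nPgpCx43Wga,
               ensheathment_ratio = r$ensheathmentRatio,
               cx43_contact_ratio = r$cx43ContactRatio,
               expansion_factor = NA_real_,
               qc_flags = paste(r$qcFlags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$expansion_factor <- rep_len(expansionFactor, nrow(out))
  out
}

#' Filter Cx43 components by axial persistence
#'
#' Serial-section bona-fide criterion for Cx43 plaques: a labeling event is
#' kept only if it persists across at least \code{minZExtentNm} of axial
#' extent (default 200 nm, i.e. two or more consecutive 100 nm sections,
#' matching plaque sizes of 200-400 nm). Components are 26-connected in 3D.
#'
#' @param cx43Mask logical 3D mask (z, y, x).
#' @param minZExtentNm minimum axial extent, nm.
#' @param sectionThicknessNm axial section thickness, nm.
#' @return filtered logical mask.
#' @export
plaquePersistenceFilter <- function(cx43Mask, minZExtentNm = 200,
                                    sectionThicknessNm = 100) {
  stopifnot(sectionThicknessNm > 0)
  minSections <- ceiling(minZExtentNm / sectionThicknessNm)
  lab <- labelComponents3D(cx43Mask)
  if (max(lab) == 0L) return(cx43Mask)
  idx <- which(lab > 0L)
  z <- arrayInd(idx, dim(lab))[, 1L]
  ext <- tapply(z, lab[idx], function(v) max(v) - min(v) + 1L)
  keep <- as.integer(names(ext))[ext >= minSections]
  out <- array(lab %in% keep, dim(cx43Mask))
  out
}
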