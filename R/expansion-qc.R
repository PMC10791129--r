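# Expansion-factor quality control from epidermal nucleus sizes.
#
# The physical expansion factor of a gel is estimated by comparing nucleus
# equivalent diameters measured pre-expansion (20x snaps) and
# post-expansion (maximum projections of z-stacks): per section, the
# factor is the ratio of median equivalent diameters; the overall factor
# is the median across sections, reported with both SD and MAD.

#' Segment nuclei in a 2D image
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, removal of
#' objects below \code{minArea}, splitting of touching nuclei by
#' distance-transform watershed, and removal of border-touching objects.
#' A blank image yields zero labels (not an error); a saturated image is
#' flagged via the \code{"saturated"} attribute.
#'
#' @param img numeric 2D matrix (single channel).
#' @param sigma Gaussian smoothing sigma, pixels.
#' @param minArea minimum object area, pixels.
#' @param removeBorder drop objects touching the image border.
#' @param watershedTolerance tolerance of the watershed split.
#' @return integer label matrix (0 = background) with attribute
#'   \code{saturated}.
#' @export
segmentNuclei2D <- function(img, sigma = 1, minArea = 30,
                            removeBorder = TRUE, watershedTolerance = 1) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  saturated <- FALSE
  if (diff(rng) <= 0) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "saturated") <- saturated
    return(out)
  }
  xn <- (img - rng[1L]) / diff(rng)
  saturated <- mean(xn >= 1 - 1e-9) > 0.05
  if (saturated) warning("image looks saturated (>5% of pixels at maximum)")
  eb <- EBImage::Image(xn)
  sm <- EBImage::gblur(eb, sigma = sigma)
  th <- EBImage::otsu(sm)
  bw <- EBImage::fillHull(sm > th)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershedTolerance)
  lab <- EBImage::imageData(lab)
  # drop small debris
  sizes <- tabulate(lab)
  drop <- which(sizes < minArea)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (removeBorder) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                       lab[, ncol(lab)]))
    border <- border[border > 0L]
    if (length(border)) lab[lab %in% border] <- 0L
  }
  # relabel compactly
  ids <- sort(unique(as.integer(lab[lab > 0L])))
  out <- matrix(match(as.integer(lab), ids, nomatch = 0L),
                nrow(img), ncol(img))
  attr(out, "saturated") <- saturated
  out
}

#' Measure segmented nuclei
#'
#' Per-label area in um^2 and equivalent circular diameter
#' 2*sqrt(area/pi) in um.
#'
#' @param labels integer label matrix from \code{\link{segmentNuclei2D}}.
#' @param pixelSize um per pixel (scalar, or (y, x) pair).
#' @param sectionId,condition identifiers for the output rows;
#'   \code{condition} is \code{"pre"} or \code{"post"}.
#' @return data.frame: section_id, condition, label, area_um2,
#'   equiv_diameter_um, centroid_y, centroid_x.
#' @export
measureNuclei <- function(labels, pixelSize, sectionId = "s1",
                          condition = c("pre", "post")) {
  condition <- match.arg(condition)
  pixelSize <- rep_len(as.numeric(pixelSize), 2L)
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  if (!length(ids)) {
    return(data.frame(section_id = character(0), condition = character(0),
                      label = integer(0), area_um2 = numeric(0),
                      equiv_diameter_um = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0)))
  }
  pxArea <- prod(pixelSize)
  idx <- which(labels > 0L)
  co <- arrayInd(idx, dim(labels))
  lv <- as.integer(labels[idx])
  npx <- tabulate(match(lv, ids))
  area <- npx * pxArea
  data.frame(
    section_id = sectionId, condition = condition, label = ids,
    area_um2 = area,
    equiv_diameter_um = 2 * sqrt(area / pi),
    centroid_y = as.numeric(tapply(co[, 1L], match(lv, ids), mean)),
    centroid_x = as.numeric(tapply(co[, 2L], match(lv, ids), mean)))
}

#' Estimate the expansion factor from nucleus tables
#'
#' Per paired section, factor = median post-expansion equivalent diameter
#' divided by median pre-expansion equivalent diameter; the overall
#' estimate is the median of per-section factors, with SD and MAD of the
#' per-section factors as dispersion. Sections missing from either
#' condition are excluded with a warning. Measured sizes are reported on
#' the expanded scale; no division by the factor is applied here.
#'
#' @param pre,post nucleus tables (\code{\link{measureNuclei}} /
#'   \code{\link{readNucleusTable}} layout) for the two conditions.
#' @param pairing optional data.frame with columns \code{post_section},
#'   \code{pre_section}; by default sections are paired by identical
#'   \code{section_id}.
#' @return an \code{ExpansionEstimate} list: \code{perSection}
#'   (data.frame: section_id, factor, median_pre_um, median_post_um),
#'   \code{medianFactor}, \code{sdFactor}, \code{madFactor},
#'   \code{medianPreDiameter}, \code{medianPostDiameter}.
#' @examples
#' pre <- data.frame(section_id = "s1", condition = "pre",
#'                   area_um2 = pi * 5^2 / 4)
#' pre$equiv_diameter_um <- 2 * sqrt(pre$area_um2 / pi)
#' post <- pre; post$condition <- "post"; post$equiv_diameter_um <- 20
#' estimateExpansionFactor(pre, post)$medianFactor  # 4
#' @export
estimateExpansionFactor <- function(pre, post, pairing = NULL) {
  stopifnot(nrow(pre) > 0, nrow(post) > 0)
  if (is.null(pairing)) {
    shared <- intersect(unique(pre$section_id), unique(post$section_id))
    unpaired <- setdiff(union(unique(pre$section_id),
                              unique(post$section_id)), shared)
    if (length(unpaired))
      warning("excluding unpaired section(s): ",
              paste(unpaired, collapse = ", "))
    pairing <- data.frame(post_section = shared, pre_section = shared,
                          stringsAsFactors = FALSE)
  }
  if (!nrow(pairing)) stop("no paired sections")
  perSection <- do.call(rbind, lapply(seq_len(nrow(pairing)), function(i) {
    dPre <- pre$equiv_diameter_um[pre$section_id == pairing$pre_section[i]]
    dPost <- post$equiv_diameter_um[post$section_id ==
                                      pairing$post_section[i]]
    mPre <- stats::median(dPre)
    mPost <- stats::median(dPost)
    if (!is.finite(mPre) || mPre <= 0)
      stop("pre-expansion median diameter is zero for section ",
           pairing$pre_section[i])
    data.frame(section_id = pairing$post_section[i], factor = mPost / mPre,
               median_pre_um = mPre, median_post_um = mPost,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    perSection = perSection,
    medianFactor = stats::median(perSection$factor),
    sdFactor = if (nrow(perSection) > 1) stats::sd(perSection$factor)
    else NA_real_,
    madFactor = stats::mad(perSection$factor),
    medianPreDiameter = stats::median(perSection$median_pre_um),
    medianPostDiameter = stats::median(perSection$median_post_um)),
    class = "ExpansionEstimate")
}

#' Simulate a 2D nucleus field
#'
#' Synthetic pre/post-expansion nucleus images for testing the QC chain:
#' non-overlapping discs of the given radius (2% radius jitter), soft
#' edges via 1-pixel Gaussian blur, additive Gaussian noise. An isotropic
#' expansion by factor s is emulated by bilinear magnification of the
#' same rendered scene (the same seed yields the same nuclei), with fresh
#' per-pixel noise added after rescaling.
#'
#' @param nNuclei number of nuclei.
#' @param radiusUm nucleus radius, um.
#' @param pixelSizeUm um per pixel.
#' @param shape image size (y, x) pixels.
#' @param scaleFactor isotropic scene scale (1 = pre-expansion).
#' @param noiseSd additive Gaussian noise SD (signal is 0/1).
#' @param radiusJitter relative SD of per-nucleus radius jitter.
#' @param seed RNG seed; the same seed with a different
#'   \code{scaleFactor} rescales the same scene.
#' @return numeric image matrix.
#' @export
simulateNucleusImage <- function(nNuclei = 12, radiusUm = 4.4,
                                 pixelSizeUm = 0.5, shape = c(256, 256),
                                 scaleFactor = 1, noiseSd = 0.02,
                                 radiusJitter = 0.02, seed = 1) {
  shape <- as.integer(shape)
  .withSeed(seed, {
    rpx <- radiusUm / pixelSizeUm
    margin <- rpx * 1.4 + 2
    centers <- matrix(NA_real_, nNuclei, 2L)
    radii <- rpx * (1 + stats::rnorm(nNuclei, sd = radiusJitter))
    placed <- 0L
    tries <- 0L
    while (placed < nNuclei && tries < 20000L) {
      tries <- tries + 1L
      cand <- margin + stats::runif(2L) * (shape - 2 * margin)
      if (placed == 0L ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2))) > 2.4 * rpx) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    if (placed < nNuclei) stop("could not place ", nNuclei, " nuclei")
    yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    img <- matrix(0, shape[1L], shape[2L])
    for (i in seq_len(nNuclei)) {
      img <- img + ((yy - centers[i, 1L])^2 +
                      (xx - centers[i, 2L])^2 <= radii[i]^2)
    }
    img <- pmin(img, 1)
    img <- EBImage::gblur(EBImage::Image(img), sigma = 1)
    if (scaleFactor != 1) {
      img <- EBImage::resize(img, w = round(shape[1L] * scaleFactor),
                             h = round(shape[2L] * scaleFactor))
    }
    img <- EBImage::imageData(img)
    img + matrix(stats::rnorm(length(img), sd = noiseSd),
                 nrow(img), ncol(img))
  })
}
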