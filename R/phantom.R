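# Synthetic epidermis phantom with voxel-level ground truth.
#
# Geometry: keratinocytes as a nearest-seed (Voronoi) partition grown from
# Poisson-disc seed points, a membrane shell along inter-cell boundaries,
# one nucleus per cell, a tubular nerve fiber crossing the volume in z
# whose segments alternate between inter-cell routes (membrane-positive)
# and intracellular tunnels (membrane-negative, "ensheathed"), and Cx43
# puncta on membranes with a controllable fiber-contact fraction.
# Imaging: Gaussian PSF, smooth multiplicative gain field, Poisson photon
# noise, Gaussian read noise.

# Evaluate expr with a temporary RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Create a phantom specification
#'
#' Builds a validated \linkS4class{PhantomSpec}. Defaults describe a
#' 16 x 64 x 64 um epidermal block at 0.25 um isotropic sampling with 20
#' keratinocytes, a single 1 um diameter fiber of which 60% of the voxels
#' are ensheathed, and 120 Cx43 puncta of 0.2-0.4 um diameter (plaques
#' are abundant at keratinocyte contact zones). The default PSF sigma of
#' 0.1 um is the effective biological-coordinate resolution after ~4x
#' physical expansion.
#'
#' @param shape voxel counts (z, y, x).
#' @param voxelSize um per voxel (z, y, x); scalar recycled.
#' @param nCells number of keratinocytes.
#' @param nucleusRadius nucleus radius, um.
#' @param membraneThickness membrane shell half-thickness, um.
#' @param fiberRadius fiber radius, um.
#' @param ensheathedFraction target fraction of fiber voxels inside cells.
#' @param nFibers number of fibers.
#' @param cx43Count number of Cx43 puncta.
#' @param cx43Diameter punctum diameter range (min, max), um.
#' @param cx43ContactFraction fraction of puncta contacting the fiber.
#' @param psfSigma PSF sigma (z, y, x), um; scalar recycled.
#' @param photonScale expected photons at unit truth intensity.
#' @param background pre-gain background as fraction of photonScale.
#' @param readNoiseSd read-noise SD as fraction of photonScale.
#' @param gainAmplitude relative amplitude of the illumination field.
#' @param dermisMargin,cornifiedMargin z-margins (voxels) excluded from
#'   the epidermal box.
#' @param seed integer seed for all phantom randomness.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(shape = c(16, 48, 48), nCells = 4, seed = 1)
#' spec
#' @export
phantomSpec <- function(shape = c(64L, 256L, 256L), voxelSize = 0.25,
                        nCells = 20L, nucleusRadius = 2.0,
                        membraneThickness = 0.25, fiberRadius = 0.5,
                        ensheathedFraction = 0.6, nFibers = 1L,
                        cx43Count = 120L, cx43Diameter = c(0.2, 0.4),
                        cx43ContactFraction = 0.1, psfSigma = 0.1,
                        photonScale = 200, background = 0.05,
                        readNoiseSd = 0.01, gainAmplitude = 0.3,
                        dermisMargin = 4L, cornifiedMargin = 4L,
                        seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      nCells = as.integer(nCells), nucleusRadius = nucleusRadius,
      membraneThickness = membraneThickness, fiberRadius = fiberRadius,
      ensheathedFraction = ensheathedFraction, nFibers = as.integer(nFibers),
      cx43Count = as.integer(cx43Count), cx43Diameter = cx43Diameter,
      cx43ContactFraction = cx43ContactFraction,
      psfSigma = rep_len(as.numeric(psfSigma), 3L),
      photonScale = photonScale, background = background,
      readNoiseSd = readNoiseSd, gainAmplitude = gainAmplitude,
      dermisMargin = as.integer(dermisMargin),
      cornifiedMargin = as.integer(cornifiedMargin), seed = as.integer(seed))
}

#' Epidermal box of a phantom
#'
#' The box excludes the dermis margin (low z), the cornified margin (high
#' z) and a one-voxel border on every face, so border membranes and the
#' dermal fiber stub never enter voxel counts.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return an \code{\link{epidermalBox}}.
#' @export
phantomEpidermalBox <- function(spec) {
  d <- spec@shape
  epidermalBox(
    zlim = c(max(2L, spec@dermisMargin + 1L),
             min(d[1L] - 1L, d[1L] - spec@cornifiedMargin)),
    ylim = c(2L, d[2L] - 1L),
    xlim = c(2L, d[3L] - 1L))
}

#' Build the keratinocyte partition of a phantom
#'
#' Draws Poisson-disc seed points (minimum separation wide enough that
#' every Voronoi cell can hold its nucleus plus membrane shell), labels
#' every voxel with its nearest seed, marks the membrane shell as all
#' voxels within \code{membraneThickness} of an inter-cell boundary, and
#' paints one spherical nucleus per cell.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{cellLabels} (integer array, labels 1..nCells),
#'   \code{nucleusMask}, \code{membraneMask} (logical arrays) and
#'   \code{seeds} (nCells x 3 matrix of seed coordinates, um).
#' @export
buildCellLabels <- function(spec) {
  validObject(spec)
  d <- spec@shape
  vs <- spec@voxelSize
  ext <- d * vs  # physical extent, um
  # the discrete boundary is ~2 voxels thick before dilation, so allow
  # nucleus + membrane shell + ~3 voxels of discretization slack per cell
  pad <- spec@nucleusRadius + spec@membraneThickness + 3 * max(vs)
  minSep <- 2 * pad
  if (any(ext - 2 * pad <= 0))
    stop("cells too small to contain a nucleus: volume extent ",
         paste(round(ext, 2), collapse = " x "),
         " um cannot hold nuclei of radius ", spec@nucleusRadius, " um")
  seeds <- .withSeed(spec@seed, {
    pts <- matrix(NA_real_, spec@nCells, 3L)
    placed <- 0L
    tries <- 0L
    maxTries <- 4000L * spec@nCells
    while (placed < spec@nCells && tries < maxTries) {
      tries <- tries + 1L
      cand <- pad + stats::runif(3L) * (ext - 2 * pad)
      if (placed == 0L ||
          min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) -
                              cand)^2))) >= minSep) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }
    if (placed < spec@nCells)
      stop("cells too small to contain a nucleus: could only place ",
           placed, " of ", spec@nCells,
           " seeds at minimum separation ", round(minSep, 2), " um")
    pts
  })
  # nearest-seed partition in physical coordinates
  zc <- (seq_len(d[1L]) - 0.5) * vs[1L]
  yc <- (seq_len(d[2L]) - 0.5) * vs[2L]
  xc <- (seq_len(d[3L]) - 0.5) * vs[3L]
  Z <- array(zc, d)
  Y <- array(rep(yc, each = d[1L]), d)
  X <- array(rep(xc, each = d[1L] * d[2L]), d)
  best <- array(Inf, d)
  labels <- array(0L, d)
  for (i in seq_len(spec@nCells)) {
    d2 <- (Z - seeds[i, 1L])^2 + (Y - seeds[i, 2L])^2 + (X - seeds[i, 3L])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  # inter-cell boundary: voxel with a 6-neighbor of a different label
  boundary <- array(FALSE, d)
  for (ax in 1:3) {
    o <- c(0L, 0L, 0L); o[ax] <- 1L
    shifted <- .shiftArray(labels, o, fill = NA_integer_)
    diffv <- !is.na(shifted) & shifted != labels
    boundary <- boundary | diffv | .shiftArray(diffv, -o, FALSE)
  }
  membrane <- if (any(boundary))
    dilateMask3D(boundary, spec@membraneThickness / vs) else boundary
  # one nucleus per cell, centered on its seed
  nucleus <- array(FALSE, d)
  offs <- .ballOffsets(spec@nucleusRadius / vs)
  for (i in seq_len(spec@nCells)) {
    ctr <- pmin(pmax(round(seeds[i, ] / vs + 0.5), 1L), d)
    vox <- cbind(offs[, 1L] + ctr[1L], offs[, 2L] + ctr[2L],
                 offs[, 3L] + ctr[3L])
    ok <- vox[, 1L] >= 1L & vox[, 1L] <= d[1L] &
      vox[, 2L] >= 1L & vox[, 2L] <= d[2L] &
      vox[, 3L] >= 1L & vox[, 3L] <= d[3L]
    vox <- vox[ok, , drop = FALSE]
    if (any(labels[vox] != i) || any(membrane[vox]))
      stop("cells too small to contain a nucleus: nucleus of cell ", i,
           " leaks outside its cell")
    nucleus[vox] <- TRUE
  }
  list(cellLabels = labels, nucleusMask = nucleus, membraneMask = membrane,
       seeds = seeds)
}

# Assign per-z-plane routing modes (TRUE = intracellular/ensheathed) in
# alternating runs whose total matches the target plane count exactly.
.fiberModes <- function(nz, targetFraction) {
  nIn <- round(targetFraction * nz)
  modes <- logical(nz)
  pos <- 1L
  needIn <- nIn
  needOut <- nz - nIn
  mode <- stats::runif(1) < targetFraction
  while (pos <= nz) {
    if (needIn == 0L) mode <- FALSE
    if (needOut == 0L) mode <- TRUE
    avail <- if (mode) needIn else needOut
    len <- min(avail, sample(4:10, 1L))
    modes[pos:(pos + len - 1L)] <- mode
    if (mode) needIn <- needIn - len else needOut <- needOut - len
    pos <- pos + len
    mode <- !mode
  }
  modes
}

#' Lay a tubular nerve fiber through the phantom
#'
#' Routes one (or more) connected tubular fibers through the volume along
#' z as a jittered random walk. Per-plane segments alternate between
#' inter-cell routing - those fiber voxels are painted into the membrane
#' mask (WGA-positive) - and intracellular tunneling - those fiber voxels
#' are cleared from the membrane mask (membrane-negative, ensheathed).
#' Run lengths are drawn so the realized membrane-negative fraction of
#' fiber voxels matches \code{ensheathedFraction} within 0.05.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param cellLabels,membraneMask output of \code{\link{buildCellLabels}}.
#' @param seed optional override of the fiber sub-seed.
#' @return list with \code{fiberMask}, \code{fiberEnsheathedMask},
#'   updated \code{membraneMask}, and \code{realizedFraction}.
#' @export
layFiber <- function(spec, cellLabels, membraneMask, seed = spec@seed + 1L) {
  d <- spec@shape
  vs <- spec@voxelSize
  rvox <- spec@fiberRadius / vs[2:3]
  margin <- ceiling(max(rvox)) + 2L
  discOffs <- .ballOffsets(c(0, rvox))
  for (attempt in 1:6) {
    res <- .withSeed(seed + 101L * (attempt - 1L), {
      fiber <- array(FALSE, d)
      ensh <- array(FALSE, d)
      memb <- membraneMask
      for (f in seq_len(spec@nFibers)) {
        pos <- c(stats::runif(1, margin, d[2L] - margin),
                 stats::runif(1, margin, d[3L] - margin))
        # stratified mode assignment: exact target counts inside the
        # epidermal z-range and in each excluded margin, so the designed
        # fraction holds both overall and inside the epidermal box
        zbox <- phantomEpidermalBox(spec)$z
        modes <- logical(d[1L])
        for (seg in list(seq_len(zbox[1L] - 1L), zbox[1L]:zbox[2L],
                         seq.int(zbox[2L] + 1L, length.out =
                                   d[1L] - zbox[2L]))) {
          if (length(seg))
            modes[seg] <- .fiberModes(length(seg), spec@ensheathedFraction)
        }
        for (z in seq_len(d[1L])) {
          pos <- pos + stats::runif(2, -1.2, 1.2)
          pos <- pmin(pmax(pos, margin), c(d[2L], d[3L]) - margin)
          ctr <- round(pos)
          vox <- cbind(z, discOffs[, 2L] + ctr[1L], discOffs[, 3L] + ctr[2L])
          lin <- vox[, 1L] + (vox[, 2L] - 1L) * d[1L] +
            (vox[, 3L] - 1L) * d[1L] * d[2L]
          fiber[lin] <- TRUE
          if (modes[z]) {
            ensh[lin] <- TRUE
            memb[lin] <- FALSE
          } else {
            ensh[lin] <- FALSE
            memb[lin] <- TRUE
          }
        }
      }
      list(fiberMask = fiber, fiberEnsheathedMask = ensh,
           membraneMask = memb,
           realizedFraction = sum(ensh) / sum(fiber))
    })
    if (abs(res$realizedFraction - spec@ensheathedFraction) <= 0.05)
      return(res)
  }
  stop(sprintf(paste0("could not reach ensheathed fraction %.2f ",
                      "(achieved %.3f) with the given geometry"),
               spec@ensheathedFraction, res$realizedFraction))
}

#' Place Cx43 puncta on membranes
#'
#' Places roughly spherical puncta with diameters drawn uniformly from
#' \code{cx43Diameter}, centered on membrane voxels. A fraction
#' \code{cx43ContactFraction} of the puncta is centered on membrane voxels
#' on or 6-adjacent to the fiber so the punctum overlaps fiber voxels; the
#' remainder is kept at least two punctum diameters away from the fiber.
#' Centers are mutually separated so puncta stay distinct components.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param membraneMask,fiberMask logical masks (post \code{\link{layFiber}}).
#' @param seed optional override of the puncta sub-seed.
#' @return logical \code{cx43Mask}.
#' @export
placeCx43Puncta <- function(spec, membraneMask, fiberMask,
                            seed = spec@seed + 2L) {
  d <- spec@shape
  vs <- spec@voxelSize
  cx43 <- array(FALSE, d)
  n <- spec@cx43Count
  if (n == 0L) return(cx43)
  nContact <- round(spec@cx43ContactFraction * n)
  nearFiber <- dilateMask3D(fiberMask, c(1, 1, 1))
  contactCand <- which(membraneMask & nearFiber)
  if (!length(contactCand)) contactCand <- which(nearFiber & !fiberMask)
  farRadius <- ceiling(2 * spec@cx43Diameter[2L] / min(vs[2:3])) +
    ceiling(max(spec@fiberRadius / vs[2:3]))
  farCand <- which(membraneMask & !dilateMask3D(fiberMask, farRadius))
  # minimum center separation: two max-size puncta plus a two-voxel gap
  # (a one-voxel gap is still diagonally 26-connected), so puncta never
  # merge into one component
  rUnit <- max(ceiling(spec@cx43Diameter[2L] / 2 / min(vs)), 1L)
  minSepVox <- 2L * rUnit + 2L
  .withSeed(seed, {
    chosen <- matrix(0L, 0L, 3L)
    pickCenters <- function(cand, k) {
      if (!k || !length(cand)) return(integer(0))
      cand <- sample(cand)
      out <- integer(0)
      for (lin in cand) {
        if (length(out) == k) break
        co <- arrayInd(lin, d)
        # Chebyshev separation keeps puncta as distinct components
        if (nrow(chosen) == 0L ||
            min(apply(abs(sweep(chosen, 2L, as.integer(co))), 1L, max)) >=
            minSepVox) {
          chosen <<- rbind(chosen, co)
          out <- c(out, lin)
        }
      }
      out
    }
    cContact <- pickCenters(contactCand, nContact)
    if (length(cContact) < nContact) {
      # membrane voxels near the fiber are scarce (e.g. fully ensheathed
      # fibers): top up from the fiber-adjacent shell, where the wrapping
      # keratinocyte membrane lives even if the membrane mask is clear
      shell <- which(nearFiber & !fiberMask)
      cContact <- c(cContact,
                    pickCenters(shell, nContact - length(cContact)))
    }
    cFar <- pickCenters(farCand, n - nContact)
    centers <- c(cContact, cFar)
    isContact <- c(rep(TRUE, length(cContact)), rep(FALSE, length(cFar)))
    if (length(centers) < n)
      warning("placed ", length(centers), " of ", n,
              " Cx43 puncta; geometry too crowded at the minimum ",
              "punctum separation")
    for (i in seq_along(centers)) {
      diam <- stats::runif(1, spec@cx43Diameter[1L], spec@cx43Diameter[2L])
      r <- (diam / 2) / vs
      if (isContact[i]) r <- pmax(r, 1)  # guarantee fiber overlap
      offs <- .ballOffsets(r)
      ctr <- arrayInd(centers[i], d)
      vox <- cbind(offs[, 1L] + ctr[1L], offs[, 2L] + ctr[2L],
                   offs[, 3L] + ctr[3L])
      ok <- vox[, 1L] >= 1L & vox[, 1L] <= d[1L] &
        vox[, 2L] >= 1L & vox[, 2L] <= d[2L] &
        vox[, 3L] >= 1L & vox[, 3L] <= d[3L]
      vox <- vox[ok, , drop = FALSE]
      cx43[vox] <- TRUE
    }
  })
  cx43
}

#' Generate the voxel-level ground truth of a phantom
#'
#' Runs \code{\link{buildCellLabels}}, \code{\link{layFiber}} and
#' \code{\link{placeCx43Puncta}}, derives the epidermal box and evaluates
#' the designed ratio statistics on the truth masks with the same counting
#' code used for real data (\code{\link{countColocalization}}).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomTruth}.
#' @examples
#' truth <- simulatePhantomTruth(phantomSpec(shape = c(16, 48, 48),
#'                                           nCells = 3, seed = 1))
#' truth
#' @export
simulatePhantomTruth <- function(spec) {
  cells <- buildCellLabels(spec)
  fib <- layFiber(spec, cells$cellLabels, cells$membraneMask)
  cx43 <- placeCx43Puncta(spec, fib$membraneMask, fib$fiberMask)
  box <- phantomEpidermalBox(spec)
  truth <- new("PhantomTruth",
               cellLabels = cells$cellLabels,
               nucleusMask = cells$nucleusMask,
               membraneMask = fib$membraneMask,
               fiberMask = fib$fiberMask,
               cx43Mask = cx43,
               fiberEnsheathedMask = fib$fiberEnsheathedMask,
               epidermalBox = unclass(box),
               trueEnsheathmentRatio = NA_real_,
               trueCx43ContactRatio = NA_real_,
               spec = spec)
  r <- truthRatios(truth)
  truth@trueEnsheathmentRatio <- r$ensheathmentRatio
  truth@trueCx43ContactRatio <- r$cx43ContactRatio
  truth
}

#' Designed ratios of a phantom truth
#'
#' Evaluates the ensheathment ratio and Cx43 contact ratio on the truth
#' masks inside the epidermal box, through the same code path as the real
#' pipeline.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @return list with \code{ensheathmentRatio} and \code{cx43ContactRatio}.
#' @export
truthRatios <- function(truth) {
  box <- do.call(epidermalBox, unname(truth@epidermalBox))
  counts <- countColocalization(truth@fiberMask, truth@membraneMask,
                                truth@cx43Mask, box)
  list(ensheathmentRatio = as.numeric(ensheathmentRatio(counts)),
       cx43ContactRatio = as.numeric(cx43ContactRatio(counts)))
}

#' Render a phantom through the forward imaging model
#'
#' Each truth mask (dapi = nuclei, wga = membrane, pgp95 = fiber, cx43 =
#' puncta) becomes an intensity channel: Gaussian PSF blur, addition of a
#' constant pre-gain background, multiplication by a smooth illumination
#' gain field (unit mean), scaling to expected photons, Poisson sampling,
#' Gaussian read noise, clamped at zero.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param spec the generating spec (defaults to \code{truth@spec}).
#' @return a \linkS4class{RenderedPhantom}.
#' @export
renderChannels <- function(truth, spec = truth@spec) {
  d <- spec@shape
  gain <- .withSeed(spec@seed + 3L, {
    if (spec@gainAmplitude > 0) {
      # vignetting-like fields are very low-frequency (near-parabolic
      # across the field of view): smooth white noise at half the image
      # extent
      noise <- array(stats::rnorm(d[2L] * d[3L]), c(1L, d[2L], d[3L]))
      s <- gaussSmooth3D(noise, c(0, d[2L] / 2, d[3L] / 2))
      s <- s / max(abs(s))
      g <- 1 + spec@gainAmplitude * matrix(s, d[2L], d[3L])
      g <- pmax(g, 0.05)
      g / mean(g)
    } else matrix(1, d[2L], d[3L])
  })
  gain3 <- aperm(array(gain, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  masks <- list(dapi = truth@nucleusMask, wga = truth@membraneMask,
                pgp95 = truth@fiberMask, cx43 = truth@cx43Mask)
  sigmaVox <- spec@psfSigma / spec@voxelSize
  out <- array(0, c(d, 4L))
  for (i in seq_along(masks)) {
    intens <- gaussSmooth3D(array(as.numeric(masks[[i]]), d), sigmaVox)
    lambda <- spec@photonScale * (intens + spec@background) * gain3
    ch <- .withSeed(spec@seed + 10L + i, {
      counts <- stats::rpois(length(lambda), lambda)
      counts + stats::rnorm(length(lambda),
                            sd = spec@readNoiseSd * spec@photonScale)
    })
    out[, , , i] <- pmax(array(ch, d), 0)
  }
  stack <- MultichannelStack(out, channelNames = names(masks),
                             voxelSize = spec@voxelSize)
  new("RenderedPhantom", stack = stack, gainField = gain, spec = spec)
}

#' Generate a complete phantom (truth + rendering)
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{truth} (\linkS4class{PhantomTruth}) and
#'   \code{rendered} (\linkS4class{RenderedPhantom}).
#' @export
simulatePhantom <- function(spec) {
  truth <- simulatePhantomTruth(spec)
  list(truth = truth, rendered = renderChannels(truth, spec))
}
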