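# Trainable voxel classification. Stands in for proprietary "neighbors"
# style voxel classifiers: a bank of multi-scale 2D image features per
# z-plane feeds a random-forest probability model, trained on fully
# annotated consecutive z-planes (default five, the training protocol used
# for each channel of the real stacks) with class-balanced subsampling.

# smooth a (z, y, x) volume laterally with an isotropic 2D Gaussian;
# FFT-based per-plane convolution (replicated edges) keeps large kernels
# affordable on full stacks
.smooth2D <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  k <- .gaussKernel(sigma)
  if (length(k) == 1L) return(vol)
  if (length(k) >= min(dim(vol)[2:3])) {
    # kernel wider than the image: separable direct convolution
    return(.convAxis(.convAxis(vol, k, 2L), k, 3L))
  }
  brush <- outer(k, k)
  img <- EBImage::Image(aperm(vol, c(2L, 3L, 1L)))
  sm <- EBImage::filter2(img, brush, boundary = "replicate")
  aperm(EBImage::imageData(sm), c(3L, 1L, 2L))
}

#' Compute the multi-scale voxel feature bank
#'
#' Per z-plane 2D features at scales sigma in \code{scales} (voxels):
#' Gaussian-smoothed intensity, gradient magnitude, Laplacian,
#' difference-of-Gaussians (sigma vs 1.6 sigma), and the two
#' structure-tensor eigenvalues. Deterministic; image edges are handled
#' by reflection.
#'
#' @param vol 3D array (z, y, x).
#' @param scales feature scales, voxels.
#' @return numeric matrix, one row per voxel (column-major voxel order),
#'   named feature columns.
#' @export
computeVoxelFeatures <- function(vol, scales = c(0.5, 1, 2, 4)) {
  stopifnot(length(dim(vol)) == 3L, all(is.finite(vol)))
  nvox <- length(vol)
  feats <- vector("list", 6L * length(scales))
  nms <- character(6L * length(scales))
  k <- 0L
  dky <- c(-0.5, 0, 0.5)
  lap <- c(1, -2, 1)
  for (s in scales) {
    G <- .smooth2D(vol, s)
    gy <- .convAxis(G, dky, 2L)
    gx <- .convAxis(G, dky, 3L)
    gradmag <- sqrt(gy^2 + gx^2)
    laplace <- .convAxis(G, lap, 2L) + .convAxis(G, lap, 3L)
    dog <- G - .smooth2D(G, sqrt((1.6 * s)^2 - s^2))
    j11 <- .smooth2D(gy^2, s)
    j22 <- .smooth2D(gx^2, s)
    j12 <- .smooth2D(gy * gx, s)
    disc <- sqrt(pmax(((j11 - j22) / 2)^2 + j12^2, 0))
    mid <- (j11 + j22) / 2
    for (f in list(G, gradmag, laplace, dog, mid + disc, mid - disc)) {
      k <- k + 1L
      feats[[k]] <- as.numeric(f)
    }
    nms[(k - 5L):k] <- paste0(
      c("gauss", "gradmag", "laplace", "dog", "st_ev1", "st_ev2"), "_s", s)
  }
  out <- do.call(cbind, feats)
  colnames(out) <- nms
  out
}

#' Build plane annotations from a reference mask
#'
#' Encodes full annotations of \code{k} consecutive z-planes in the
#' convention used by \code{\link{fitVoxelClassifier}}: 0 = unlabeled,
#' 1 = background, 2 = foreground.
#'
#' @param mask logical 3D reference (e.g. a phantom truth mask).
#' @param planes z-indices of the annotated planes (must be consecutive).
#' @return integer 3D annotation array.
#' @export
annotationsFromMask <- function(mask, planes) {
  planes <- as.integer(planes)
  stopifnot(all(diff(planes) == 1L), all(planes >= 1L),
            all(planes <= dim(mask)[1L]))
  ann <- array(0L, dim(mask))
  ann[planes, , ] <- 1L + mask[planes, , ]
  ann
}

#' Train a voxel classifier from annotated consecutive z-planes
#'
#' Trains a random-forest probability model on the feature vectors of the
#' annotated voxels only. Annotations must cover exactly \code{nPlanes}
#' consecutive z-planes in full and contain both classes. Training is
#' balanced by subsampling at most \code{maxPerClass} voxels per class;
#' a fixed seed makes the model reproducible.
#'
#' @param features feature matrix from \code{\link{computeVoxelFeatures}}.
#' @param annotations integer 3D array: 0 = unlabeled, 1 = background,
#'   2 = foreground.
#' @param nPlanes required number of annotated consecutive planes
#'   (default 5).
#' @param nTrees random-forest size.
#' @param maxPerClass training-voxel cap per class.
#' @param threshold foreground probability threshold (ties at the
#'   threshold are foreground).
#' @param seed training seed.
#' @param channel channel name recorded in the classifier.
#' @return a \linkS4class{VoxelClassifier}.
#' @export
fitVoxelClassifier <- function(features, annotations, nPlanes = 5L,
                               nTrees = 100L, maxPerClass = 4000L,
                               threshold = 0.5, seed = 1L,
                               channel = "channel") {
  d <- dim(annotations)
  stopifnot(nrow(features) == prod(d))
  planes <- which(apply(annotations != 0L, 1L, any))
  if (length(planes) != nPlanes || any(diff(planes) != 1L))
    stop("annotations must cover exactly ", nPlanes,
         " consecutive z-planes (found ", length(planes), ")")
  if (any(annotations[planes, , ] == 0L))
    stop("annotated planes must be fully labeled")
  idx <- which(annotations != 0L)
  y <- annotations[idx] == 2L
  if (!any(y) || all(y))
    stop("annotations must contain both classes")
  sel <- .withSeed(seed, {
    # balance by subsampling the majority class down to maxPerClass and
    # the minority class up (with replacement) to the same size, so rare
    # structures do not starve the background class of diversity
    nPer <- min(maxPerClass, max(sum(y), sum(!y)))
    c(sample(idx[y], nPer, replace = sum(y) < nPer),
      sample(idx[!y], nPer, replace = sum(!y) < nPer))
  })
  dtrain <- xgboost::xgb.DMatrix(features[sel, , drop = FALSE],
                                 label = as.numeric(annotations[sel] == 2L))
  # random-forest mode: one boosting round of nTrees bagged trees with
  # per-node feature subsampling
  model <- xgboost::xgb.train(
    params = list(booster = "gbtree", objective = "binary:logistic",
                  eta = 1, max_depth = 12, subsample = 0.632,
                  colsample_bynode = 0.3, lambda = 0, alpha = 0,
                  tree_method = "hist", nthread = 1,
                  seed = seed, num_parallel_tree = nTrees),
    data = dtrain, nrounds = 1, verbose = 0)
  new("VoxelClassifier", model = model, channel = channel,
      scales = numeric(0), threshold = threshold,
      trainPlanes = as.integer(planes), seed = as.integer(seed))
}

#' Predict a binary mask with a voxel classifier
#'
#' @param classifier a \linkS4class{VoxelClassifier}.
#' @param features feature matrix of the target volume.
#' @param dim volume dimensions (z, y, x).
#' @return logical 3D mask; probability >= threshold is foreground.
#' @export
predictMask <- function(classifier, features, dim) {
  prob <- stats::predict(classifier@model, features)
  array(prob >= classifier@threshold, dim)
}

#' Smooth a binary mask by morphological opening
#'
#' Erosion followed by dilation with an ellipsoidal element of the given
#' lateral radius; the axial radius is scaled by the voxel-size ratio so
#' the element is isotropic in physical units. Removes specks smaller
#' than the element and is idempotent.
#'
#' @param mask logical 3D mask (z, y, x).
#' @param radius lateral radius, voxels (default 1).
#' @param voxelSize optional (z, y, x) voxel sizes for anisotropy
#'   scaling; isotropic if omitted.
#' @return smoothed logical mask.
#' @export
smoothMask <- function(mask, radius = 1, voxelSize = NULL) {
  d <- dim(mask)
  if (radius >= min(d) / 2)
    stop("smoothing radius must be below half the smallest dimension")
  rz <- if (is.null(voxelSize)) radius else
    radius * voxelSize[2L] / voxelSize[1L]
  openMask3D(mask, c(rz, radius, radius))
}

#' Segment one channel end to end
#'
#' Convenience wrapper for the per-channel segmentation chain: optional
#' illumination correction, feature computation, training on annotated
#' consecutive planes, whole-volume prediction, and opening-based
#' smoothing.
#'
#' @param vol 3D channel volume (z, y, x).
#' @param annotations integer 3D annotation array (see
#'   \code{\link{fitVoxelClassifier}}).
#' @param correctGain estimate and divide out the illumination field
#'   first.
#' @param scales feature scales, voxels.
#' @param smoothRadius opening radius (0 disables smoothing).
#' @param voxelSize (z, y, x) voxel sizes for anisotropy-aware smoothing.
#' @param ... passed to \code{\link{fitVoxelClassifier}}.
#' @return list with \code{mask} (logical 3D), \code{classifier} and
#'   \code{gainField} (or NULL).
#' @export
segmentVolume <- function(vol, annotations, correctGain = FALSE,
                          scales = c(0.5, 1, 2, 4), smoothRadius = 1,
                          voxelSize = NULL, ...) {
  gain <- NULL
  if (correctGain) {
    gain <- estimateGainField(vol)
    vol <- correctIllumination(vol, gain)
  }
  features <- computeVoxelFeatures(vol, scales)
  clf <- fitVoxelClassifier(features, annotations, ...)
  clf@scales <- scales
  mask <- predictMask(clf, features, dim(vol))
  if (smoothRadius > 0)
    mask <- smoothMask(mask, smoothRadius, voxelSize)
  list(mask = mask, classifier = clf, gainField = gain)
}

#' Save / load a voxel classifier
#'
#' Serialization to RDS; a reloaded classifier yields bit-identical
#' predictions.
#'
#' @param classifier a \linkS4class{VoxelClassifier}.
#' @param path RDS path.
#' @return \code{path} invisibly (save); the classifier (load).
#' @export
saveVoxelClassifier <- function(classifier, path) {
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname saveVoxelClassifier
#' @export
loadVoxelClassifier <- function(path) readRDS(path)

#' Choose the most informative annotation block
#'
#' Returns the start of the block of \code{k} consecutive z-planes with
#' the largest foreground voxel count in a reference mask - the block a
#' human annotator would pick for sparse structures such as Cx43 puncta.
#'
#' @param mask logical 3D reference mask.
#' @param k block length (default 5).
#' @return integer vector of \code{k} consecutive plane indices.
#' @export
pickTrainingPlanes <- function(mask, k = 5L) {
  perPlane <- apply(mask, 1L, sum)
  nz <- length(perPlane)
  stopifnot(k <= nz)
  blockSums <- vapply(seq_len(nz - k + 1L),
                      function(s) sum(perPlane[s:(s + k - 1L)]), numeric(1))
  s <- which.max(blockSums)
  seq.int(s, length.out = k)
}
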