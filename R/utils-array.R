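# Low-level 3D array helpers shared by the phantom generator, the feature
# bank and the morphology operators. Arrays are indexed (z, y, x); physical
# sizes are always micrometres in (z, y, x) order.

# Mirror indices into 1..n (reflection without edge repetition).
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  ifelse(j >= n, 2L * n - 2L - j, j) + 1L
}

# Normalized 1D Gaussian kernel; sigma in voxels. sigma <= 0 gives identity.
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with reflective boundary handling.
# Implemented as a sum of weighted shifted copies; kernels are short (<= 6
# sigma + 1) so this stays a handful of vectorized passes over the volume.
.convAxis <- function(vol, kernel, axis) {
  d <- dim(vol)
  if (length(kernel) == 1L) return(vol * kernel)
  n <- d[axis]
  h <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(vol, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    src <- .reflectIndex(seq_len(n) + (j - 1L - h), n)
    out <- out + kernel[j] * m[src, , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# Separable 3D Gaussian smoothing; sigma per axis in voxels (z, y, x).
gaussSmooth3D <- function(vol, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) vol <- .convAxis(vol, .gaussKernel(sigma[ax]), ax)
  }
  vol
}

# Translate array content by integer offset o = (dz, dy, dx), filling
# vacated voxels with `fill`: out[v + o] = a[v].
.shiftArray <- function(a, o, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (o[k] >= 0) {
      if (o[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - o[k])
      dst[[k]] <- src[[k]] + o[k]
    } else {
      if (-o[k] >= d[k]) return(out)
      src[[k]] <- seq.int(1L - o[k], d[k])
      dst[[k]] <- seq_len(d[k] + o[k])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Integer offsets inside an (anisotropic) ellipsoid of radii (rz, ry, rx)
# voxels. radius 0 on an axis restricts offsets to that plane.
.ballOffsets <- function(radius) {
  r <- rep_len(radius, 3L)
  rng <- lapply(r, function(ri) seq.int(-floor(ri), floor(ri)))
  g <- as.matrix(expand.grid(dz = rng[[1L]], dy = rng[[2L]], dx = rng[[3L]]))
  rr <- pmax(r, 1e-9)
  keep <- (g[, 1L] / rr[1L])^2 + (g[, 2L] / rr[2L])^2 +
    (g[, 3L] / rr[3L])^2 <= 1 + 1e-9
  g[keep, , drop = FALSE]
}

#' 3D binary morphology with an ellipsoidal structuring element
#'
#' Dilation, erosion and opening of a 3D logical mask with an ellipsoidal
#' (anisotropy-aware) structuring element given as per-axis radii in voxels
#' (z, y, x). Erosion treats out-of-volume voxels as foreground so that
#' objects touching the border are not eaten from outside the field of view.
#'
#' @param mask 3D logical array, indexed (z, y, x).
#' @param radius numeric radii in voxels, recycled to length 3 (z, y, x).
#' @return logical array of the same dimensions.
#' @export
dilateMask3D <- function(mask, radius) {
  offs <- .ballOffsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | .shiftArray(mask, offs[i, ], FALSE)
  }
  out
}

#' @rdname dilateMask3D
#' @export
erodeMask3D <- function(mask, radius) {
  offs <- .ballOffsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out & .shiftArray(mask, -offs[i, ], TRUE)
  }
  out
}

#' @rdname dilateMask3D
#' @export
openMask3D <- function(mask, radius) {
  dilateMask3D(erodeMask3D(mask, radius), radius)
}

#' Label connected components in a 3D mask
#'
#' Breadth-first 3D connected-component labelling (26- or 6-connectivity),
#' used for plaque persistence filtering and phantom self-checks. EBImage's
#' \code{bwlabel} operates frame-wise in 2D, hence this 3D implementation.
#'
#' @param mask 3D logical array (z, y, x).
#' @param connectivity 26 (default) or 6.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
labelComponents3D <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  d <- dim(mask)
  lin <- which(mask)
  labels <- array(0L, d)
  if (!length(lin)) return(labels)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nz <- rowSums(abs(offs))
  offs <- if (connectivity == 6L) offs[nz == 1L, , drop = FALSE] else
    offs[nz > 0L, , drop = FALSE]
  coord <- arrayInd(lin, d)
  pos <- integer(prod(d))
  pos[lin] <- seq_along(lin)
  comp <- integer(length(lin))
  cur <- 0L
  for (s in seq_along(lin)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fc <- coord[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
        cbind(fc[, 1L] + offs[i, 1L], fc[, 2L] + offs[i, 2L],
              fc[, 3L] + offs[i, 3L])
      }))
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      nlin <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] +
        (nb[, 3L] - 1L) * (d[1L] * d[2L])
      p <- unique(pos[nlin])
      p <- p[p > 0L]
      p <- p[comp[p] == 0L]
      if (length(p)) comp[p] <- cur
      frontier <- p
    }
  }
  labels[lin] <- comp
  labels
}

# Global Otsu threshold of a numeric array (wraps EBImage::otsu on the
# range-normalized data, returning a threshold on the original scale).
.otsuThreshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1L])
  xn <- (as.numeric(x) - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(xn, dim = c(length(xn), 1L)))
  rng[1L] + th * diff(rng)
}
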