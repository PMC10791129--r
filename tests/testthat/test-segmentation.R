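test_that("gain field of a uniform stack is flat and scale-invariant", {
  vol <- array(5, c(8, 32, 32))
  f <- estimateGainField(vol)
  expect_lt(max(abs(f - 1)), 0.01)
  noisy <- array(runif(8 * 32 * 32, 1, 2), c(8, 32, 32))
  expect_equal(estimateGainField(noisy), estimateGainField(2 * noisy))
  expect_warning(f0 <- estimateGainField(array(0, c(8, 16, 16))),
                 "constant-zero")
  expect_true(all(f0 == 1))
  expect_error(estimateGainField(array(1, c(3, 16, 16))), "4 z-planes")
})

test_that("estimated field recovers the phantom's true gain", {
  spec <- phantomSpec(shape = c(32, 96, 96), nCells = 6,
                      gainAmplitude = 0.5, seed = 17)
  ph <- simulatePhantom(spec)
  est <- estimateGainField(getChannel(ph$rendered@stack, "wga"))
  expect_gte(stats::cor(as.numeric(est), as.numeric(ph$rendered@gainField)),
             0.95)
})

test_that("illumination correction flattens gain-distorted backgrounds", {
  spec <- phantomSpec(shape = c(32, 96, 96), nCells = 6,
                      gainAmplitude = 0.5, seed = 18)
  ph <- simulatePhantom(spec)
  vol <- getChannel(ph$rendered@stack, "wga")
  expect_identical(correctIllumination(vol, matrix(1, 96, 96)), vol)
  est <- estimateGainField(vol)
  corrected <- correctIllumination(vol, est)
  bg <- !dilateMask3D(ph$truth@membraneMask, c(1, 2, 2))
  cvD <- stats::sd(vol[bg]) / mean(vol[bg])
  cvC <- stats::sd(corrected[bg]) / mean(corrected[bg])
  expect_lt(cvC, cvD)
  # background means across gain deciles agree after correction
  gain <- ph$rendered@gainField
  bgMean <- function(v, pix) {
    m <- apply(v * bg, c(2, 3), sum) / pmax(apply(bg, c(2, 3), sum), 1)
    mean(m[pix])
  }
  qs <- stats::quantile(gain, c(0.1, 0.9))
  r <- bgMean(corrected, gain >= qs[2]) / bgMean(corrected, gain <= qs[1])
  expect_lt(abs(r - 1), 0.05)
})

test_that("feature bank behaves on constant and shifted inputs", {
  const <- array(3, c(6, 24, 24))
  f <- computeVoxelFeatures(const, scales = c(1, 2))
  derivCols <- grep("gradmag|laplace|dog", colnames(f))
  expect_true(all(abs(f[, derivCols]) < 1e-8))
  expect_true(all(abs(f[, grep("gauss", colnames(f))] - 3) < 1e-8))

  set.seed(1)
  vol <- array(runif(6 * 24 * 24), c(6, 24, 24))
  fv <- computeVoxelFeatures(vol, scales = 1)
  shifted <- array(0, dim(vol))
  shifted[, , 5:24] <- vol[, , 1:20]
  fs <- computeVoxelFeatures(shifted, scales = 1)
  a <- array(fv[, 1], dim(vol))
  b <- array(fs[, 1], dim(vol))
  expect_equal(b[, 8:20, 12:20], a[, 8:20, 8:16], tolerance = 1e-10)

  noisy <- array(rpois(6 * 24 * 24, 50), c(6, 24, 24))
  expect_true(all(is.finite(computeVoxelFeatures(noisy))))
})

test_that("classifier training is reproducible and validates annotations", {
  # noise-free two-region volume: perfectly separable
  vol <- array(0, c(10, 24, 24))
  truth <- array(FALSE, dim(vol))
  truth[, 6:12, 6:12] <- TRUE
  vol[truth] <- 8
  f <- computeVoxelFeatures(vol)
  ann <- annotationsFromMask(truth, 3:7)
  c1 <- fitVoxelClassifier(f, ann, seed = 7)
  c2 <- fitVoxelClassifier(f, ann, seed = 7)
  expect_identical(predictMask(c1, f, dim(vol)),
                   predictMask(c2, f, dim(vol)))
  # linearly separable blob: perfect training-plane accuracy
  m <- predictMask(c1, f, dim(vol))
  expect_identical(m[3:7, , ], truth[3:7, , ])

  expect_error(fitVoxelClassifier(f, annotationsFromMask(truth, 3:6)),
               "consecutive z-planes")
  allBg <- array(0L, dim(vol)); allBg[3:7, , ] <- 1L
  expect_error(fitVoxelClassifier(f, allBg), "both classes")
  holes <- ann; holes[5, 1, 1] <- 0L
  expect_error(fitVoxelClassifier(f, holes), "fully labeled")
})

test_that("a reloaded classifier predicts identically", {
  set.seed(6)
  vol <- array(rnorm(8 * 24 * 24), c(8, 24, 24))
  truth <- array(FALSE, dim(vol)); truth[, 10:15, 10:15] <- TRUE
  vol[truth] <- vol[truth] + 4
  f <- computeVoxelFeatures(vol, scales = c(1, 2))
  clf <- fitVoxelClassifier(f, annotationsFromMask(truth, 2:6), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveVoxelClassifier(clf, tmp)
  expect_identical(predictMask(loadVoxelClassifier(tmp), f, dim(vol)),
                   predictMask(clf, f, dim(vol)))
})

test_that("held-out planes of a rendered phantom segment accurately", {
  spec <- phantomSpec(shape = c(32, 96, 96), nCells = 6,
                      photonScale = 200, seed = 19)
  ph <- simulatePhantom(spec)
  tm <- ph$truth@fiberMask
  planes <- pickTrainingPlanes(tm)
  seg <- segmentVolume(getChannel(ph$rendered@stack, "pgp95"),
                       annotationsFromMask(tm, planes),
                       voxelSize = spec@voxelSize, seed = 23)
  held <- setdiff(seq_len(32), planes)
  expect_gte(diceCoef(seg$mask[held, , ], tm[held, , ]), 0.8)
  expect_identical(dim(seg$mask), dim(tm))
  expect_type(seg$mask, "logical")
})

test_that("fiber segmentation quality rises with photon budget", {
  dices <- vapply(c(50, 200, 1000), function(ps) {
    spec <- phantomSpec(shape = c(32, 96, 96), nCells = 6,
                        photonScale = ps, seed = 20)
    ph <- simulatePhantom(spec)
    tm <- ph$truth@fiberMask
    seg <- segmentVolume(getChannel(ph$rendered@stack, "pgp95"),
                         annotationsFromMask(tm, pickTrainingPlanes(tm)),
                         voxelSize = spec@voxelSize, seed = 23)
    diceCoef(seg$mask, tm)
  }, numeric(1))
  expect_true(all(diff(dices) >= 0))
})

test_that("gain distortion costs little Dice once corrected", {
  segWga <- function(amp) {
    spec <- phantomSpec(shape = c(32, 96, 96), nCells = 6,
                        photonScale = 200, gainAmplitude = amp, seed = 21)
    ph <- simulatePhantom(spec)
    tm <- ph$truth@membraneMask
    seg <- segmentVolume(getChannel(ph$rendered@stack, "wga"),
                         annotationsFromMask(tm, pickTrainingPlanes(tm)),
                         correctGain = amp > 0,
                         voxelSize = spec@voxelSize, seed = 23)
    diceCoef(seg$mask, tm)
  }
  expect_lte(abs(segWga(0.5) - segWga(0)), 0.05)
})

test_that("mask opening removes specks, keeps bodies, and is idempotent", {
  d <- c(24L, 24L, 24L)
  speck <- array(FALSE, d); speck[12, 12, 12] <- TRUE
  expect_identical(sum(smoothMask(speck, 1)), 0L)

  ball <- array(FALSE, d)
  co <- arrayInd(seq_len(prod(d)), d)
  ball[(co[, 1] - 12)^2 + (co[, 2] - 12)^2 + (co[, 3] - 12)^2 <= 100] <- TRUE
  opened <- smoothMask(ball, 1)
  expect_lt(abs(sum(opened) - sum(ball)) / sum(ball), 0.10)
  expect_identical(smoothMask(opened, 1), opened)

  expect_error(smoothMask(ball, 12), "radius")
  # anisotropy: coarse z sampling shrinks the axial radius
  aniso <- smoothMask(ball, 2, voxelSize = c(1, 0.25, 0.25))
  expect_identical(dim(aniso), d)
})
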