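test_that("cell partition tiles the volume with requested cells and nuclei", {
  spec <- smallSpec(seed = 2)
  cells <- buildCellLabels(spec)
  expect_true(all(cells$cellLabels > 0L))
  expect_setequal(unique(as.integer(cells$cellLabels)), 1:4)
  nlab <- labelComponents3D(cells$nucleusMask)
  expect_identical(max(nlab), 4L)
  for (i in 1:4) {
    owner <- unique(as.integer(cells$cellLabels[nlab == i]))
    expect_length(owner, 1L)
  }
  expect_false(any(cells$nucleusMask & cells$membraneMask))
})

test_that("a single-cell phantom has no interior membrane", {
  spec <- phantomSpec(shape = c(24, 48, 48), nCells = 1, nucleusRadius = 1,
                      seed = 1)
  cells <- buildCellLabels(spec)
  expect_true(all(cells$cellLabels == 1L))
  expect_identical(sum(cells$membraneMask), 0L)
})

test_that("phantom generation is deterministic in the seed", {
  a <- simulatePhantom(smallSpec(seed = 5))
  b <- simulatePhantom(smallSpec(seed = 5))
  expect_identical(a$truth@cellLabels, b$truth@cellLabels)
  expect_identical(a$truth@fiberMask, b$truth@fiberMask)
  expect_identical(a$truth@cx43Mask, b$truth@cx43Mask)
  expect_identical(a$rendered@stack@data, b$rendered@stack@data)
  expect_identical(a$rendered@gainField, b$rendered@gainField)
})

test_that("overfull specs are rejected with a sizing error", {
  expect_error(
    buildCellLabels(phantomSpec(shape = c(8, 32, 32), nCells = 2,
                                nucleusRadius = 5, dermisMargin = 1,
                                cornifiedMargin = 1, seed = 1)),
    "too small")
})

test_that("fiber routing hits the ensheathment target", {
  spec0 <- smallSpec(seed = 7, ensheathedFraction = 0)
  cells <- buildCellLabels(spec0)
  f0 <- layFiber(spec0, cells$cellLabels, cells$membraneMask)
  expect_identical(sum(f0$fiberEnsheathedMask), 0L)
  expect_true(all(f0$membraneMask[f0$fiberMask]))

  spec1 <- smallSpec(seed = 7, ensheathedFraction = 1)
  f1 <- layFiber(spec1, cells$cellLabels, cells$membraneMask)
  expect_false(any(f1$fiberMask & f1$membraneMask))

  spec6 <- smallSpec(seed = 7, ensheathedFraction = 0.6)
  f6 <- layFiber(spec6, cells$cellLabels, cells$membraneMask)
  realized <- sum(f6$fiberMask & !f6$membraneMask) / sum(f6$fiberMask)
  expect_lte(abs(realized - 0.6), 0.05)
  expect_equal(f6$realizedFraction, realized)
})

test_that("fiber voxels split exactly into ensheathed and membrane-apposed", {
  for (s in 1:5) {
    truth <- simulatePhantomTruth(smallSpec(seed = s))
    expect_identical(
      sum(truth@fiberEnsheathedMask) +
        sum(truth@fiberMask & truth@membraneMask),
      sum(truth@fiberMask))
    expect_identical(max(labelComponents3D(truth@fiberMask)), 1L)
  }
})

test_that("Cx43 puncta respect count, contact fraction and size bounds", {
  spec <- smallSpec(seed = 3)
  truth0 <- simulatePhantomTruth(smallSpec(seed = 3, cx43Count = 0))
  expect_identical(sum(truth0@cx43Mask), 0L)

  specAll <- phantomSpec(shape = c(64, 64, 64), nCells = 4,
                         nucleusRadius = 1.5, dermisMargin = 3,
                         cornifiedMargin = 3, seed = 3,
                         cx43Count = 10, cx43ContactFraction = 1)
  cells <- buildCellLabels(specAll)
  fib <- layFiber(specAll, cells$cellLabels, cells$membraneMask)
  cx <- placeCx43Puncta(specAll, fib$membraneMask, fib$fiberMask)
  lab <- labelComponents3D(cx)
  expect_identical(max(lab), 10L)
  for (i in seq_len(max(lab))) {
    expect_true(any(fib$fiberMask[lab == i]))
  }

  # size bound: each component extent at most the max diameter + 2 voxels
  truth <- simulatePhantomTruth(spec)
  lab <- labelComponents3D(truth@cx43Mask)
  vs <- spec@voxelSize
  for (i in seq_len(max(lab))) {
    co <- arrayInd(which(lab == i), dim(lab))
    for (ax in 1:3) {
      extent <- (max(co[, ax]) - min(co[, ax]) + 1L) * vs[ax]
      expect_lte(extent, 0.4 + 2 * vs[ax])
    }
  }
})

test_that("noise-free rendering recovers truth masks exactly at threshold", {
  spec <- smallSpec(seed = 4, psfSigma = 0, gainAmplitude = 0,
                    photonScale = 1e6, readNoiseSd = 0)
  ph <- simulatePhantom(spec)
  maskOf <- c(dapi = "nucleusMask", wga = "membraneMask",
              pgp95 = "fiberMask", cx43 = "cx43Mask")
  for (ch in names(maskOf)) {
    vol <- getChannel(ph$rendered@stack, ch)
    th <- mean(range(vol))
    expect_identical(array(vol > th, dim(vol)), slot(ph$truth, maskOf[[ch]]),
                     info = ch)
  }
})

test_that("rendered background tracks the applied gain field", {
  spec <- smallSpec(seed = 9, psfSigma = 0, gainAmplitude = 0.5,
                    photonScale = 1000, readNoiseSd = 0)
  ph <- simulatePhantom(spec)
  gain <- ph$rendered@gainField
  vol <- getChannel(ph$rendered@stack, "dapi")
  bg <- !ph$truth@nucleusMask
  # per-(y,x) background mean over z
  bgMean <- apply(vol * bg, c(2, 3), sum) / apply(bg, c(2, 3), sum)
  qs <- stats::quantile(gain, c(0.1, 0.9))
  lowPix <- gain <= qs[1]
  highPix <- gain >= qs[2]
  measured <- mean(bgMean[highPix]) / mean(bgMean[lowPix])
  expected <- mean(gain[highPix]) / mean(gain[lowPix])
  expect_lt(abs(measured / expected - 1), 0.10)
})

test_that("designed truth ratios come from the shared counting path", {
  truthAll <- simulatePhantomTruth(smallSpec(seed = 6,
                                             ensheathedFraction = 1))
  expect_identical(truthAll@trueEnsheathmentRatio, 1)

  truthNoCx <- simulatePhantomTruth(smallSpec(seed = 6, cx43Count = 0))
  expect_identical(truthNoCx@trueCx43ContactRatio, 0)

  # independent triple-loop voxel counter agrees on a generated phantom
  truth <- simulatePhantomTruth(smallSpec(seed = 8))
  box <- do.call(epidermalBox, unname(truth@epidermalBox))
  bf <- bruteForceCounts(truth@fiberMask, truth@membraneMask,
                         truth@cx43Mask, box)
  expect_identical(truth@trueEnsheathmentRatio,
                   (bf$nPgp - bf$nPgpWga) / bf$nPgp)
  expect_identical(truth@trueCx43ContactRatio, bf$nPgpCx43Wga / bf$nPgp)
})

test_that("a hand-built toy truth yields the hand-counted ratio", {
  d <- c(4L, 6L, 6L)
  fiber <- array(FALSE, d)
  membrane <- array(FALSE, d)
  fiber[2, 2, 1:5] <- TRUE          # 5 voxels
  fiber[3, 4, 1:5] <- TRUE          # 5 voxels -> 10 total
  membrane[2, 2, 1:2] <- TRUE       # overlaps 2
  membrane[3, 4, 3:4] <- TRUE       # overlaps 2 -> 4 total
  membrane[1, 1, 1] <- TRUE         # non-fiber membrane
  truth <- new("PhantomTruth",
               cellLabels = array(1L, d), nucleusMask = array(FALSE, d),
               membraneMask = membrane, fiberMask = fiber,
               cx43Mask = array(FALSE, d),
               fiberEnsheathedMask = fiber & !membrane,
               epidermalBox = list(z = c(1L, 4L), y = c(1L, 6L),
                                   x = c(1L, 6L)),
               trueEnsheathmentRatio = NA_real_,
               trueCx43ContactRatio = NA_real_,
               spec = smallSpec())
  r <- truthRatios(truth)
  expect_identical(r$ensheathmentRatio, 0.6)
  expect_identical(r$cx43ContactRatio, 0)
})
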