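test_that("colocalization counts match hand-placed voxels", {
  d <- c(2L, 4L, 4L)
  pgp <- array(FALSE, d); wga <- array(FALSE, d); cx <- array(FALSE, d)
  pgp[1, 1, 1:4] <- TRUE; pgp[1, 2, 1:4] <- TRUE; pgp[2, 3, 1:2] <- TRUE
  wga[1, 1, 1:2] <- TRUE; wga[1, 2, 3:4] <- TRUE; wga[2, 4, 1] <- TRUE
  cx[1, 1, 1] <- TRUE; cx[2, 3, 1] <- TRUE
  counts <- countColocalization(pgp, wga, cx)
  expect_identical(counts$nPgp, 10L)
  expect_identical(counts$nPgpWga, 4L)
  expect_identical(counts$nPgpCx43Wga, 1L)
  expect_identical(ensheathmentRatio(counts), 0.6)
  expect_identical(cx43ContactRatio(counts), 0.1)
})

test_that("disjoint fiber and membrane give zero overlap, ratio 1", {
  d <- c(3L, 5L, 5L)
  pgp <- array(FALSE, d); pgp[1, , ] <- TRUE
  wga <- array(FALSE, d); wga[3, , ] <- TRUE
  counts <- countColocalization(pgp, wga, NULL)
  expect_identical(counts$nPgpWga, 0L)
  expect_identical(ensheathmentRatio(counts), 1)
})

test_that("vectorized counts equal the brute-force voxel counter", {
  for (s in 1:30) {
    set.seed(s)
    d <- c(16L, 16L, 16L)
    pgp <- array(runif(prod(d)) < 0.2, d)
    wga <- array(runif(prod(d)) < 0.3, d)
    cx <- array(runif(prod(d)) < 0.1, d)
    box <- epidermalBox(c(2, 14), c(3, 15), c(1, 16))
    got <- countColocalization(pgp, wga, cx, box)
    want <- bruteForceCounts(pgp, wga, cx, box)
    expect_identical(got$nPgp, want$nPgp)
    expect_identical(got$nPgpWga, want$nPgpWga)
    expect_identical(got$nPgpCx43Wga, want$nPgpCx43Wga)
  }
})

test_that("epidermal box restricts counting and flags fiber-free boxes", {
  truth <- simulatePhantomTruth(smallSpec(seed = 12))
  full <- epidermalBox(c(1, 24), c(1, 64), c(1, 64))
  c1 <- countColocalization(truth@fiberMask, truth@membraneMask,
                            truth@cx43Mask)
  c2 <- countColocalization(truth@fiberMask, truth@membraneMask,
                            truth@cx43Mask, full)
  expect_identical(c1[1:3], c2[1:3])

  # a box that excludes every fiber voxel -> flagged missing, not 0
  co <- arrayInd(which(truth@fiberMask), dim(truth@fiberMask))
  xmax <- min(co[, 3]) - 1L
  expect_gte(xmax, 1L)  # the fiber walk keeps a lateral margin
  empty <- countColocalization(truth@fiberMask, truth@membraneMask,
                               truth@cx43Mask,
                               epidermalBox(c(1, 24), c(1, 64), c(1, xmax)))
  er <- ensheathmentRatio(empty)
  expect_true(is.na(er))
  expect_identical(attr(er, "qcFlag"), "no_fiber_voxels")

  expect_error(cropBox(truth@fiberMask, epidermalBox(c(1, 99), c(1, 64),
                                                     c(1, 64))),
               "exceeds")
  expect_error(countColocalization(truth@fiberMask,
                                   truth@membraneMask[, 1:10, ]),
               "mismatch")
})

test_that("dermal fiber signal outside the box never enters the counts", {
  truth <- simulatePhantomTruth(smallSpec(seed = 13))
  box <- do.call(epidermalBox, unname(truth@epidermalBox))
  # the fiber crosses the whole z-range, so the dermal stub below the box
  # exists and must be excluded
  stub <- truth@fiberMask
  stub[box$z[1]:box$z[2], , ] <- FALSE
  expect_gt(sum(stub), 0)
  counts <- countColocalization(truth@fiberMask, truth@membraneMask,
                                truth@cx43Mask, box)
  bf <- bruteForceCounts(truth@fiberMask, truth@membraneMask,
                         truth@cx43Mask, box)
  expect_identical(counts$nPgp, bf$nPgp)
  expect_lt(counts$nPgp, sum(truth@fiberMask))
})

test_that("plaque persistence filter drops single-section components", {
  d <- c(10L, 20L, 20L)
  m <- array(FALSE, d)
  m[3, 2, 2] <- TRUE                      # 1 section at 100 nm -> removed
  filtered <- plaquePersistenceFilter(m, 200, 100)
  expect_identical(sum(filtered), 0L)

  m2 <- array(FALSE, d)
  m2[3:5, 2, 2] <- TRUE                   # 3 sections -> kept
  expect_identical(plaquePersistenceFilter(m2, 200, 100), m2)

  # 5 single-section + 2 multi-section components -> exactly 2 survive
  m3 <- array(FALSE, d)
  for (i in 1:5) m3[2, 2 * i, 3] <- TRUE
  m3[4:5, 10, 10] <- TRUE
  m3[7:9, 15, 15] <- TRUE
  surv <- plaquePersistenceFilter(m3, 200, 100)
  expect_identical(max(labelComponents3D(surv)), 2L)
  expect_identical(sum(surv), 5L)
})

test_that("quantifyROI assembles counts, ratios and QC flags", {
  truth <- simulatePhantomTruth(smallSpec(seed = 14))
  box <- do.call(epidermalBox, unname(truth@epidermalBox))
  res <- quantifyROI(truth@fiberMask, truth@membraneMask, truth@cx43Mask,
                     box, sampleId = "HC1", roiId = "roi1", group = "HC")
  expect_identical(res$ensheathmentRatio, truth@trueEnsheathmentRatio)
  expect_identical(res$cx43ContactRatio, truth@trueCx43ContactRatio)
  tab <- resultTable(list(res))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$group, "HC")
  expect_identical(tab$ensheathment_ratio, truth@trueEnsheathmentRatio)
})

test_that("exact Mann-Whitney matches enumeration on the textbook cases", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$U, 0)
  expect_identical(mw$p, 0.1)
  expect_identical(mw$method, "exact")

  mw2 <- mannWhitneyU(1, 2)
  expect_identical(mw2$p, 1)
})

test_that("exact Mann-Whitney agrees with the independent implementation", {
  set.seed(99)
  for (rep in 1:50) {
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    v <- sample(1000, n1 + n2)  # tie-free
    x <- v[seq_len(n1)]
    y <- v[-seq_len(n1)]
    mw <- mannWhitneyU(x, y)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_identical(mw$method, "exact")
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 7, 8)
  y <- c(2, 4, 4, 5, 9, 9, 10)
  mw <- mannWhitneyU(x, y)
  expect_identical(mw$method, "normal-approx-tie-corrected")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
})

test_that("group summaries report descriptives and drop flagged ROIs", {
  vals <- c(0.6, 0.7, 0.8, NA, 0.4, 0.5, 0.3)
  grp <- c("HC", "HC", "HC", "HC", "SFN", "SFN", "SFN")
  gs <- summarizeGroups(vals, grp)
  expect_identical(gs$nDropped, 1L)
  hc <- gs$perGroup[gs$perGroup$group == "HC", ]
  expect_identical(hc$n, 3L)
  expect_equal(hc$mean, 0.7)
  expect_equal(hc$sd, stats::sd(c(0.6, 0.7, 0.8)))
  expect_equal(hc$median, 0.7)
  expect_true(is.finite(gs$p))

  single <- summarizeGroups(c(0.1, 0.2), c("HC", "HC"))
  expect_true(is.na(single$p))
})
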