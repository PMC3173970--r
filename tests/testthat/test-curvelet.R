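test_that("plans follow the depth and angle rules", {
  sys <- curveletPlan(512, 512)
  expect_identical(nscales(sys), 5L)
  expect_identical(nangles(sys), c(1L, 16L, 16L, 32L, 32L))
  # second-coarsest count always >= 8 and a multiple of 4
  for (n in c(64, 100, 256)) {
    na <- nangles(curveletPlan(n, n))
    expect_gte(na[2], 8L)
    expect_identical(na[2] %% 4L, 0L)
  }
  sys2 <- curveletPlan(64, 64, nscales = 2)
  expect_identical(nangles(sys2)[1], 1L)
  expect_error(curveletPlan(64, 64, nanglesCoarse = 6), "multiple of 4")
  expect_error(curveletPlan(16, 16), "at least 32")
  expect_error(curveletPlan(64, 64, nscales = 12), "too small")
})

test_that("windows satisfy the admissibility identities", {
  r <- seq(0.75, 1.5, length.out = 1e4 + 2)[2:(1e4 + 1)]
  radial <- Reduce(`+`, lapply(-4:4, function(j) radialWindow(2^j * r)^2))
  expect_lt(max(abs(radial - 1)), 1e-10)
  t <- seq(-0.5, 0.5, length.out = 1e4 + 2)[2:(1e4 + 1)]
  angular <- Reduce(`+`, lapply(-2:2, function(l) angularWindow(t - l)^2))
  expect_lt(max(abs(angular - 1)), 1e-10)
  # windows are bounded by 1
  expect_true(all(radialWindow(seq(0, 3, by = 0.01)) <= 1 + 1e-12))
  expect_true(all(angularWindow(seq(-1, 1, by = 0.01)) <= 1 + 1e-12))
})

test_that("wedge masks form an exact frequency partition of unity", {
  expect_lt(partitionDeviation(curveletPlan(128, 128)), 1e-10)
  expect_lt(partitionDeviation(curveletPlan(64, 96)), 1e-10)
})

test_that("wedges have the stated geometry", {
  sys <- curveletPlan(128, 128)
  # coarsest tile is nondirectional: angularly symmetric mask
  t1 <- wedgeWindow(sys, 1, 1)
  m <- t1@mask
  expect_lt(max(abs(m - m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))])),
            1e-12)
  # masks real-valued in [0, 1]
  for (j in seq_len(nscales(sys))) {
    tl <- wedgeWindow(sys, j, 1)
    expect_true(all(tl@mask >= 0 & tl@mask <= 1 + 1e-12))
  }
  expect_error(wedgeWindow(sys, 99, 1), "scale")
  expect_error(wedgeWindow(sys, 2, 99), "orientation")
})

test_that("wrapped rectangles get more elongated toward fine scales", {
  # parabolic scaling: angle count doubles every other scale while the
  # radial extent doubles every scale, so anisotropy grows toward fine
  sys <- curveletPlan(128, 128, nscales = 4)
  aspect <- vapply(seq_len(4), function(j) {
    max(vapply(seq_len(nangles(sys)[j]), function(l) {
      d <- dim(wedgeWindow(sys, j, l)@mask)
      max(d) / min(d)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aspect) >= -1e-9))          # non-decreasing
  expect_gt(aspect[4], aspect[2])                  # strict overall growth
})

test_that("the transform is a tight frame: energy identity and exact inversion", {
  set.seed(31)
  for (n in c(64, 100, 128)) {
    x <- matrix(rnorm(n * n), n)
    sys <- curveletPlan(n, n)
    co <- fdctForward(x, sys)
    expect_lt(abs(curveletEnergy(co) / sum(x^2) - 1), 1e-6)
    rec <- pixels(fdctInverse(co))
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-6)
  }
  # zero image maps to zero coefficients and back
  co0 <- fdctForward(matrix(0, 64, 64))
  expect_equal(curveletEnergy(co0), 0)
  expect_true(all(pixels(fdctInverse(co0)) == 0))
})

test_that("the phantom round trips through the curvelet transform", {
  img <- generatePhantom(PhantomSpec())
  co <- fdctForward(img)
  rec <- pixels(fdctInverse(co))
  expect_lt(max(abs(rec - pixels(img))) / max(pixels(img)), 1e-6)
})

test_that("the transform is linear", {
  set.seed(32)
  x <- matrix(rnorm(64 * 64), 64); y <- matrix(rnorm(64 * 64), 64)
  sys <- curveletPlan(64, 64)
  cx <- fdctForward(x, sys); cy <- fdctForward(y, sys)
  cz <- fdctForward(1.5 * x - 2 * y, sys)
  for (j in seq_len(nscales(sys))) {
    for (l in seq_len(nangles(sys)[j])) {
      expect_lt(max(Mod(cz@bands[[j]][[l]] -
                        (1.5 * cx@bands[[j]][[l]] - 2 * cy@bands[[j]][[l]]))),
                1e-10 * max(Mod(cz@bands[[j]][[l]]), 1))
    }
  }
})

test_that("coefficient thresholding spares the coarsest band and is monotone", {
  set.seed(33)
  img <- Image2D(matrix(rnorm(64 * 64), 64))
  co <- fdctForward(img)
  expect_identical(thresholdCurvelet(co, 0), co)
  nSurvive <- function(c) sum(vapply(c@bands, function(s) {
    sum(vapply(s, function(b) sum(Mod(b) > 0), numeric(1)))
  }, numeric(1)))
  ts <- c(0.001, 0.01, 0.05, 0.2, 1)
  counts <- vapply(ts, function(t) nSurvive(thresholdCurvelet(co, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # a huge threshold leaves only the coarsest band
  tmax <- max(vapply(seq_len(nscales(co@system))[-1], function(j) {
    max(vapply(co@bands[[j]], function(b) max(Mod(b)), numeric(1)))
  }, numeric(1))) + 1
  only1 <- thresholdCurvelet(co, tmax)
  expect_identical(only1@bands[[1]][[1]], co@bands[[1]][[1]])
  expect_true(all(vapply(seq_len(nscales(co@system))[-1], function(j) {
    all(vapply(only1@bands[[j]], function(b) all(Mod(b) == 0), logical(1)))
  }, logical(1))))
  expect_error(thresholdCurvelet(co, -1), ">= 0")
})

test_that("curvelet denoising recovers a clean image at t = 0 and improves PSNR", {
  img <- generatePhantom(PhantomSpec())
  rec <- denoiseCurvelet(img, t = 0)
  expect_lt(max(abs(pixels(rec) - pixels(img))) / max(pixels(img)), 1e-6)
  noisy <- addGaussianNoise(img, sigmaFraction = 0.2, seed = 34)
  den <- denoiseCurvelet(noisy, t = 3 * 40)
  expect_gt(imagePSNR(img, den), imagePSNR(img, noisy))
})

test_that("the coefficient mosaic keeps every band in a disjoint panel", {
  sys <- curveletPlan(64, 64)
  lay <- coefficientLayout(sys)
  occ <- matrix(0L, lay$canvasDim[1], lay$canvasDim[2])
  for (i in seq_len(nrow(lay$panels))) {
    p <- lay$panels[i, ]
    rr <- p$row0 + seq_len(p$rows) - 1L
    cc <- p$col0 + seq_len(p$cols) - 1L
    occ[rr, cc] <- occ[rr, cc] + 1L
  }
  expect_lte(max(occ), 1L)                          # disjoint
  totalCoef <- sum(lay$panels$rows * lay$panels$cols)
  expect_identical(nrow(lay$panels), sum(nangles(sys)))  # none dropped
  expect_gte(prod(lay$canvasDim), totalCoef)
  # coarse band at the centre: its panel contains the canvas midpoint
  p1 <- lay$panels[lay$panels$scale == 1, ]
  mid <- lay$canvasDim / 2
  expect_true(p1$row0 <= mid[1] && mid[1] <= p1$row0 + p1$rows &&
              p1$col0 <= mid[2] && mid[2] <= p1$col0 + p1$cols)
  # zero coefficients give a zero mosaic
  disp <- coefficientDisplay(fdctForward(matrix(0, 64, 64), sys))
  expect_true(all(pixels(disp) == 0))
})
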