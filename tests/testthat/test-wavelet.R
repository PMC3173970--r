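test_that("filter banks satisfy the orthonormality identities", {
  for (nm in c("haar", "db2")) {
    f <- waveletFilter(nm)
    expect_equal(sqrt(sum(f@lowpass^2)), 1, tolerance = 1e-13)
    expect_equal(sum(f@lowpass), sqrt(2), tolerance = 1e-13)
    L <- length(f@lowpass)
    expect_equal(f@highpass, (-1)^(0:(L - 1)) * rev(f@lowpass))
  }
})

test_that("single Haar steps match the hand-computed cases", {
  r <- dwtStep(c(1, 1), "haar")
  expect_equal(r$approx, sqrt(2))
  expect_equal(r$detail, 0)
  r <- dwtStep(c(1, 0), "haar")
  expect_equal(r$approx, 1 / sqrt(2))
  expect_equal(r$detail, 1 / sqrt(2))
})

test_that("analysis steps conserve energy (Parseval)", {
  set.seed(3)
  for (nm in c("haar", "db2")) {
    x <- rnorm(16)
    r <- dwtStep(x, nm)
    expect_equal(sum(r$approx^2) + sum(r$detail^2), sum(x^2),
                 tolerance = 1e-10)
    # odd length: last sample carried (scaled); exact inversion, count kept
    y <- rnorm(13)
    d <- dwt1d(y, nm, 3)
    expect_length(c(unlist(d$details), d$approx), 13)
    expect_equal(idwt1d(d), y, tolerance = 1e-10)
    # a constant signal keeps zero details at every level
    dc <- dwt1d(rep(4, 13), nm, 3)
    expect_lt(max(abs(unlist(dc$details))), 1e-12)
    expect_lt(diff(range(dc$approx / sqrt(2)^dc$levels - 4)), 1e-12)
  }
})

test_that("2D transform matches the frozen independent reference", {
  X <- dwtReferenceFixture()
  for (nm in c("haar", "db2")) {
    pyr <- dwt2d(X, nm, 1)
    ref <- function(b) get(paste0("dwtReference_", nm, "_", b))
    expect_lt(max(abs(pyr@approx - ref("LL"))), 1e-8)
    expect_lt(max(abs(pyr@details[[1]]$LH - ref("LH"))), 1e-8)
    expect_lt(max(abs(pyr@details[[1]]$HL - ref("HL"))), 1e-8)
    expect_lt(max(abs(pyr@details[[1]]$HH - ref("HH"))), 1e-8)
  }
})

test_that("2D decomposition has the documented structural properties", {
  # constant image: all details vanish
  pyr <- dwt2d(matrix(5, 8, 8), "haar", 3)
  expect_true(all(vapply(pyr@details,
                         function(l) max(abs(unlist(l))), numeric(1)) == 0))
  # 4x4, 2 Haar levels: LL_2 is 1x1 holding 4x the mean
  m <- matrix(runif(16), 4)
  pyr <- dwt2d(m, "haar", 2)
  expect_identical(dim(pyr@approx), c(1L, 1L))
  expect_equal(as.numeric(pyr@approx), 4 * mean(m), tolerance = 1e-12)
  # Parseval at depth 3 on random input
  set.seed(4)
  img <- matrix(rnorm(32 * 32), 32)
  pyr <- dwt2d(img, "haar", 3)
  expect_equal(pyramidEnergy(pyr), sum(img^2), tolerance = 1e-10)
  # level cap enforced
  expect_error(dwt2d(img, "haar", 99), "levels")
})

test_that("round trips are exact for dyadic and non-dyadic sizes", {
  set.seed(5)
  for (nm in c("haar", "db2")) {
    for (n in c(64L, 20L, 37L)) {
      img <- matrix(rnorm(n * n), n)
      lev <- min(3L, maxDwtLevels(n, n))
      rec <- pixels(idwt2d(dwt2d(img, nm, lev)))
      expect_lt(max(abs(rec - img)), 1e-8)
    }
  }
})

test_that("the transform pair is linear", {
  set.seed(6)
  x <- matrix(rnorm(256), 16); y <- matrix(rnorm(256), 16)
  a <- 2.3; b <- -0.7
  p1 <- dwt2d(a * x + b * y, "db2", 2)
  px <- dwt2d(x, "db2", 2); py <- dwt2d(y, "db2", 2)
  expect_equal(p1@approx, a * px@approx + b * py@approx, tolerance = 1e-10)
  expect_equal(p1@details[[1]]$HH,
               a * px@details[[1]]$HH + b * py@details[[1]]$HH,
               tolerance = 1e-10)
})

test_that("pyramid thresholding spares the approximation band", {
  set.seed(7)
  pyr <- dwt2d(matrix(rnorm(64), 8), "haar", 2)
  expect_identical(thresholdPyramid(pyr, 0), pyr)
  tmax <- max(abs(unlist(lapply(pyr@details, unlist)))) + 1
  only_ll <- thresholdPyramid(pyr, tmax)
  expect_true(all(unlist(lapply(only_ll@details, unlist)) == 0))
  expect_identical(only_ll@approx, pyr@approx)
  # forced small case
  d <- c(-5, 2, 9)
  expect_equal(d * (abs(d) >= 3), c(-5, 0, 9))
  expect_error(thresholdPyramid(pyr, -2), ">= 0")
})

test_that("wavelet denoising recovers a clean image at t = 0 and improves PSNR on noise", {
  img <- generatePhantom(PhantomSpec())
  expect_lt(max(abs(pixels(denoiseWavelet(img, "haar", 2, 0)) -
                    pixels(img))), 1e-8)
  noisy <- addGaussianNoise(img, sigmaFraction = 0.2, seed = 9)
  den <- denoiseWavelet(noisy, "haar", 2, t = 3 * 40)
  expect_gt(imagePSNR(img, den), imagePSNR(img, noisy))
  # constant image unchanged for any t
  const <- Image2D(matrix(9, 16, 16))
  expect_lt(max(abs(pixels(denoiseWavelet(const, "db2", 2, 100)) - 9)), 1e-8)
})
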