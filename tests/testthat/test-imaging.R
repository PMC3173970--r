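test_that("Image2D enforces its invariants", {
  expect_error(Image2D(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(Image2D(matrix(1), pixelSizeMm = 0), "positive")
  img <- Image2D(matrix(1:6, 2, 3), pixelSizeMm = 2)
  expect_identical(dim(img), c(2L, 3L))
  expect_identical(pixelSizeMm(img), 2)
})

test_that("PNG and TIFF round trips are lossless for in-range integer images", {
  img8 <- Image2D(matrix(sample(0:255, 16, replace = TRUE), 4, 4))
  p <- tempfile(fileext = ".png")
  writeImage2D(img8, p, 8L)
  expect_equal(pixels(readImage2D(p)), pixels(img8))

  img16 <- Image2D(matrix(c(0, 300, 40000, 65535), 2, 2),
                   intensityMax = 65535)
  tf <- tempfile(fileext = ".tiff")
  writeImage2D(img16, tf, 16L)
  back <- readImage2D(tf)
  expect_equal(pixels(back), pixels(img16))
  expect_identical(intensityMax(back), 65535)
})

test_that("constant 8-bit image reads back as written", {
  p <- tempfile(fileext = ".png")
  writeImage2D(Image2D(matrix(7, 4, 4)), p, 8L)
  img <- readImage2D(p)
  expect_true(all(pixels(img) == 7))
  expect_identical(dim(img), c(4L, 4L))
})

test_that("write rejects out-of-range values unless clipping is enabled", {
  img <- Image2D(matrix(c(0, 300, 10, 20), 2, 2))
  expect_error(writeImage2D(img, tempfile(fileext = ".png"), 8L), "clip")
  p <- tempfile(fileext = ".png")
  writeImage2D(img, p, 8L, clip = TRUE)
  expect_equal(max(pixels(readImage2D(p))), 255)
  # value 300 is representable at 16 bit
  p16 <- tempfile(fileext = ".tiff")
  writeImage2D(img, p16, 16L)
  expect_equal(sort(unique(as.vector(pixels(readImage2D(p16))))),
               c(0, 10, 20, 300))
})

test_that("RGB input is rejected without luminance conversion", {
  p <- tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), p)
  expect_error(readImage2D(p), "multi-channel")
  expect_silent(readImage2D(p, toLuminance = TRUE))
})

test_that("hard intensity threshold follows the strict-below rule", {
  img <- Image2D(matrix(c(3, 7, 35, 200), 2, 2))
  expect_equal(as.vector(pixels(hardThresholdIntensity(img, 35))),
               c(0, 0, 35, 200))
  expect_equal(pixels(hardThresholdIntensity(img, 0)), pixels(img))
  expect_true(all(pixels(hardThresholdIntensity(img, 1000)) == 0))
  expect_error(hardThresholdIntensity(img, -1), ">= 0")
  # idempotent
  once <- hardThresholdIntensity(img, 10)
  expect_equal(pixels(hardThresholdIntensity(once, 10)), pixels(once))
})

test_that("MSE matches direct summation and is a proper metric", {
  set.seed(11)
  a <- randomImage(8, seed = 11)
  b <- randomImage(8, seed = 12)
  brute <- sum((pixels(a) - pixels(b))^2) / 64
  expect_equal(imageMSE(a, b), brute)
  expect_equal(imageMSE(a, b), imageMSE(b, a))
  expect_equal(imageMSE(a, a), 0)
  expect_equal(imageMSE(Image2D(matrix(0, 2, 2)), Image2D(matrix(1, 2, 2))),
               1)
  expect_error(imageMSE(a, Image2D(matrix(0, 2, 2))), "shape")
})

test_that("PSNR has the closed-form values and monotonicity", {
  a <- Image2D(matrix(0, 4, 4))
  b <- Image2D(matrix(c(2, rep(0, 15)), 4, 4) * 2)  # mse = 1
  expect_equal(imageMSE(a, b), 1)
  expect_equal(imagePSNR(a, b, peak = 255), 20 * log10(255))
  expect_equal(imagePSNR(a, b, peak = 510) - imagePSNR(a, b, peak = 255),
               20 * log10(2))
  expect_identical(imagePSNR(a, a), Inf)
  expect_error(imagePSNR(a, b, peak = 0), "positive")
  # strictly decreasing in mse at fixed peak
  c2 <- Image2D(pixels(b) * 2)
  expect_lt(imagePSNR(a, c2, peak = 255), imagePSNR(a, b, peak = 255))
})

test_that("SNR follows the reference-difference convention", {
  sig <- Image2D(matrix(c(10, 0, 0, 0), 2, 2))   # energy 100
  noisy <- Image2D(matrix(c(10, 1, 0, 0), 2, 2)) # residual energy 1
  expect_equal(imageSNR(sig, noisy), 20)
  expect_identical(imageSNR(sig, sig), Inf)
  expect_error(imageSNR(Image2D(matrix(0, 2, 2)), sig), "zero energy")
  # joint scale invariance
  expect_equal(imageSNR(Image2D(pixels(sig) * 3.7),
                        Image2D(pixels(noisy) * 3.7)),
               imageSNR(sig, noisy))
})

test_that("metrics reports serialise as flat key-value text and JSON", {
  rep <- qualityReport(Image2D(matrix(0:3, 2, 2)), Image2D(matrix(c(0:2, 5), 2, 2)))
  pj <- tempfile(fileext = ".json")
  pt <- tempfile(fileext = ".txt")
  writeMetricsReport(rep, pj, "json")
  writeMetricsReport(rep, pt, "text")
  back <- jsonlite::read_json(pj)
  expect_equal(back$mse, rep$mse)
  expect_match(readLines(pt)[1], "^mse = ")
  # non-finite values survive as strings in JSON
  writeMetricsReport(list(psnr_db = Inf), pj, "json")
  expect_identical(jsonlite::read_json(pj)$psnr_db, "Inf")
})
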