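test_that("equivalent diameter follows the closed form", {
  expect_equal(measureEquivalentDiameter(1, 1), 2 / sqrt(pi))
  expect_equal(measureEquivalentDiameter(4, 1),
               2 * measureEquivalentDiameter(1, 1))
  expect_error(measureEquivalentDiameter(0), ">= 1")
  # rasterised 37 mm disc at 0.5 mm pixels measures within 1%
  px <- 0.5
  g <- expand.grid(x = seq(-25, 25, by = px), y = seq(-25, 25, by = px))
  inside <- sum(g$x^2 + g$y^2 <= (37 / 2)^2)
  expect_lt(abs(measureEquivalentDiameter(inside, px) / 37 - 1), 0.01)
})

test_that("diameter error and area accuracy match their definitions", {
  expect_equal(diameterErrorPct(10, 10), 0)
  expect_equal(diameterErrorPct(11, 10), 10)
  expect_equal(diameterErrorPct(8.8, 10), -12)
  # antisymmetric around the actual value
  expect_equal(diameterErrorPct(10 + 1.3, 10), -diameterErrorPct(10 - 1.3, 10))
  expect_error(diameterErrorPct(5, 0), "positive")

  expect_equal(areaAccuracyPct(50, 50), 100)
  expect_equal(areaAccuracyPct(0, 50), 0)
  expect_equal(areaAccuracyPct(55, 50), 90)
  expect_equal(areaAccuracyPct(500, 50), 0)  # floored
  expect_error(areaAccuracyPct(1, 0), "positive")
})

test_that("an empty image yields zero regions, not an error", {
  res <- segmentImage(Image2D(matrix(0, 64, 64)), SegmentationConfig())
  expect_identical(nrow(res$rois), 0L)
  expect_true(all(res$labels == 0L))
})

test_that("the noise-free phantom segments into exactly six inserts", {
  img <- phantom512()
  res <- segmentImage(img, SegmentationConfig())
  expect_identical(nrow(res$rois), 6L)
  m <- matchRoisToSpheres(res$rois, PhantomSpec(grid = c(512L, 512L),
                                                pixelSizeMm = 4.6875 / 4))
  expect_identical(nrow(m$matches), 6L)
  expect_length(m$spurious, 0)
  expect_length(m$missed, 0)
  # equivalent diameters within one pixel width of the true diameters
  expect_lt(max(abs(m$matches$measuredDiameterMm -
                    m$matches$actualDiameterMm)), 4.6875 / 4)
})

test_that("a curvelet round trip in the pipeline leaves the measurement unchanged", {
  img <- generatePhantom(PhantomSpec())
  plain <- segmentImage(img, SegmentationConfig())
  curv <- segmentImage(img, SegmentationConfig(transform = "curvelet",
                                               tCoef = 0))
  expect_identical(nrow(curv$rois), nrow(plain$rois))
  # diameters agree within one pixel-equivalent
  o1 <- plain$rois[order(plain$rois$pixelArea), ]
  o2 <- curv$rois[order(curv$rois$pixelArea), ]
  expect_lt(max(abs(o1$equivalentDiameterMm - o2$equivalentDiameterMm)),
            4.6875)
})

test_that("ROI matching flags spurious and missed regions", {
  spec <- PhantomSpec(grid = c(512L, 512L), pixelSizeMm = 4.6875 / 4)
  res <- segmentImage(phantom512(), SegmentationConfig())
  rois <- res$rois
  # an extra blob far from every insert centre is spurious
  extra <- rois[1, ]
  extra$label <- 99L
  extra$centroidRow <- 5; extra$centroidCol <- 5
  m <- matchRoisToSpheres(rbind(rois, extra), spec)
  expect_identical(m$spurious, 99L)
  expect_length(m$missed, 0)
  # dropping a region leaves its insert missed
  m2 <- matchRoisToSpheres(rois[-1, ], spec)
  expect_length(m2$missed, 1)
})

test_that("raising the post-threshold never grows a region", {
  img <- generatePhantom(PhantomSpec(supersample = 4L))
  areas <- vapply(c(7, 50, 120, 190), function(tp) {
    res <- segmentImage(img, SegmentationConfig(tPost = tp))
    sum(res$rois$pixelArea)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("border-touching components are excluded as background", {
  m <- matrix(0, 64, 64)
  m[1:64, 1:3] <- 100          # touches the border
  m[30:34, 30:34] <- 200       # interior ROI
  img <- Image2D(m)
  res <- segmentImage(img, SegmentationConfig())
  expect_identical(nrow(res$rois), 1L)
  expect_identical(res$rois$pixelArea, 25L)
  resKeep <- segmentImage(img, SegmentationConfig(excludeBorder = FALSE))
  expect_identical(nrow(resKeep$rois), 2L)
  resLargest <- segmentImage(img, SegmentationConfig(excludeBorder = FALSE,
                                                     excludeLargest = TRUE))
  expect_identical(nrow(resLargest$rois), 1L)
})

test_that("evaluation reports are consistent and deterministic", {
  clean <- generatePhantom(PhantomSpec())
  noisy <- addGaussianNoise(clean, sigmaFraction = 0.2, seed = 41)
  perfect <- evaluateDenoising(clean, noisy, clean)
  expect_equal(perfect$denoised$mse, 0)
  expect_identical(perfect$denoised$psnr_db, Inf)
  same <- evaluateDenoising(clean, noisy, noisy)
  expect_equal(same$denoised, same$noisy)
  # determinism: identical inputs, identical report
  again <- evaluateDenoising(clean, noisy, clean)
  expect_identical(perfect, again)
  # data-loss flag reacts to the bound
  flagged <- evaluateDenoising(clean, noisy, noisy, dataLossMseBound = 1)
  expect_identical(flagged$dataLoss, "High")
})
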