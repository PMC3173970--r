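#' Create a segmentation configuration
#'
#' @param tPre intensity pre-threshold (default 35 on the 8-bit scale:
#'   removes scanner artefacts before the transform).
#' @param tPost intensity post-threshold (default 7: removes residual noise
#'   after reconstruction).
#' @param transform "none", "wavelet", "ridgelet" or "curvelet".
#' @param tCoef hard threshold applied to transform detail coefficients.
#' @param filterName wavelet filter for the wavelet/ridgelet transforms.
#' @param levels wavelet decomposition depth.
#' @param blockSize prime ridgelet block size.
#' @param nscales curvelet scale count (NA = default depth rule).
#' @param minRoiPixels discard components smaller than this.
#' @param excludeBorder drop components touching the image border (the
#'   surviving background of a clinical scan).
#' @param excludeLargest additionally drop the single largest component.
#' @param intensityScale multiplier applied to tPre/tPost for data on wider
#'   scales (e.g. 257 maps the 8-bit defaults onto 16-bit data).
#' @return a validated [SegmentationConfig-class].
#' @export
SegmentationConfig <- function(tPre = 35, tPost = 7, transform = "none",
                               tCoef = 0, filterName = "haar", levels = 2L,
                               blockSize = 13L, nscales = NA_integer_,
                               minRoiPixels = 4L, excludeBorder = TRUE,
                               excludeLargest = FALSE, intensityScale = 1) {
  new("SegmentationConfig", tPre = tPre, tPost = tPost, transform = transform,
      tCoef = tCoef, filterName = filterName, levels = as.integer(levels),
      blockSize = as.integer(blockSize), nscales = as.integer(nscales),
      minRoiPixels = as.integer(minRoiPixels), excludeBorder = excludeBorder,
      excludeLargest = excludeLargest, intensityScale = intensityScale)
}

# Transform-domain denoising dispatch used by the pipeline.
applyTransformDenoise <- function(img, config) {
  switch(config@transform,
    none = img,
    wavelet = denoiseWavelet(img, config@filterName, config@levels,
                             config@tCoef),
    ridgelet = denoiseRidgelet(img, p = config@blockSize,
                               filter = config@filterName, t = config@tCoef,
                               levels = config@levels),
    curvelet = {
      sys <- if (is.na(config@nscales)) NULL else {
        curveletPlan(nrow(img@pixels), ncol(img@pixels), config@nscales)
      }
      denoiseCurvelet(img, sys, config@tCoef)
    }
  )
}

#' Equivalent-circle diameter from pixel area
#'
#' Diameter of the circle whose area equals the measured region area:
#' \code{2 * sqrt(area / pi)}. Robust to ragged region boundaries, which is
#' why it is the primary diameter estimate.
#'
#' @param pixelArea number of pixels in the region (>= 1).
#' @param pixelSizeMm isotropic pixel size, mm.
#' @return diameter in mm.
#' @export
measureEquivalentDiameter <- function(pixelArea, pixelSizeMm = 1) {
  if (any(pixelArea < 1)) stop("pixel area must be >= 1", call. = FALSE)
  2 * sqrt(pixelArea * pixelSizeMm^2 / pi)
}

#' Signed diameter error percentage
#'
#' \code{100 * (measured - actual) / actual}; negative values mean
#' underestimation.
#'
#' @param measuredMm,actualMm diameters in mm; \code{actualMm > 0}.
#' @export
diameterErrorPct <- function(measuredMm, actualMm) {
  if (any(actualMm <= 0)) stop("actual diameter must be positive",
                               call. = FALSE)
  100 * (measuredMm - actualMm) / actualMm
}

#' Area accuracy percentage
#'
#' \code{100 * (1 - |measured - reference| / reference)}, floored at 0.
#'
#' @param measuredAreaMm2,referenceAreaMm2 areas in mm^2; reference > 0.
#' @export
areaAccuracyPct <- function(measuredAreaMm2, referenceAreaMm2) {
  if (any(referenceAreaMm2 <= 0)) stop("reference area must be positive",
                                       call. = FALSE)
  pmax(0, 100 * (1 - abs(measuredAreaMm2 - referenceAreaMm2) /
                   referenceAreaMm2))
}

# Max Feret (caliper) diameter of a pixel set, in mm: the largest pairwise
# distance between pixel centres plus one pixel width, computed on the
# convex hull.
feretDiameterMm <- function(rows, cols, pixelSizeMm) {
  pts <- cbind(cols, rows)
  if (nrow(pts) > 2L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- 0
  if (nrow(pts) > 1L) d2 <- max(stats::dist(pts))
  (d2 + 1) * pixelSizeMm
}

#' Segment an image into regions of interest
#'
#' The end-to-end pipeline: intensity pre-threshold, transform-domain
#' denoising at \code{tCoef} (skipped when \code{transform = "none"}),
#' intensity post-threshold, 4-connected component labelling of the nonzero
#' pixels, and region measurement. Components smaller than
#' \code{minRoiPixels} are dropped; components touching the image border
#' (the surviving background of a clinical scan) are excluded when
#' \code{excludeBorder}, and the single largest component additionally when
#' \code{excludeLargest}.
#'
#' @param img an [Image2D-class].
#' @param config a [SegmentationConfig-class].
#' @return list with \code{labels} (integer label matrix; 0 = background),
#'   \code{rois} (data frame: label, pixelArea, areaMm2, centroidRow,
#'   centroidCol, equivalentDiameterMm, feretDiameterMm), and
#'   \code{denoised} (the image after the full pipeline).
#' @export
segmentImage <- function(img, config = SegmentationConfig()) {
  stopifnot(is(img, "Image2D"), is(config, "SegmentationConfig"))
  validObject(config)
  sc <- config@intensityScale
  work <- hardThresholdIntensity(img, config@tPre * sc)
  work <- applyTransformDenoise(work, config)
  work <- hardThresholdIntensity(work, config@tPost * sc)
  lab <- EBImage::bwlabel((work@pixels != 0) * 1)
  lab <- matrix(as.integer(lab), nrow(work@pixels), ncol(work@pixels))
  keep <- integer(0)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- sizes < config@minRoiPixels
    if (config@excludeBorder) {
      border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                         lab[, ncol(lab)]))
      drop[border[border > 0L]] <- TRUE
    }
    if (config@excludeLargest && any(!drop)) {
      drop[which(!drop)[which.max(sizes[!drop])]] <- TRUE
    }
    fg <- lab > 0L
    fg[fg] <- drop[lab[fg]]
    lab[fg] <- 0L
    keep <- which(!drop)
  }
  # relabel 1..n in raster order of first appearance
  rois <- data.frame(label = integer(0), pixelArea = integer(0),
                     areaMm2 = numeric(0), centroidRow = numeric(0),
                     centroidCol = numeric(0),
                     equivalentDiameterMm = numeric(0),
                     feretDiameterMm = numeric(0))
  newLab <- matrix(0L, nrow(lab), ncol(lab))
  ps <- img@pixelSizeMm
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    newLab[idx] <- i
    n <- nrow(idx)
    rois[i, ] <- list(i, n, n * ps^2, mean(idx[, 1L]), mean(idx[, 2L]),
                      measureEquivalentDiameter(n, ps),
                      feretDiameterMm(idx[, 1L], idx[, 2L], ps))
  }
  list(labels = newLab, rois = rois, denoised = work)
}

#' Match segmented regions to phantom inserts
#'
#' Assigns each region to the nearest insert centre, accepting a match only
#' within half the minimal inter-centre distance. Unmatched regions are
#' spurious; unmatched inserts are missed.
#'
#' @param rois the region table from [segmentImage()].
#' @param spec the [PhantomSpec-class] that generated the image.
#' @return list with \code{matches} (data frame: label, sphere,
#'   actualDiameterMm, measuredDiameterMm, errorPct, areaAccuracyPct),
#'   \code{spurious} (labels) and \code{missed} (sphere indices).
#' @export
matchRoisToSpheres <- function(rois, spec) {
  stopifnot(is(spec, "PhantomSpec"))
  ctr <- sphereCentres(spec)
  d <- spec@sphereDiametersMm
  M <- spec@grid[1L]; N <- spec@grid[2L]; ps <- spec@pixelSizeMm
  if (nrow(ctr) > 1L) {
    radius <- min(stats::dist(ctr)) / 2
  } else {
    radius <- Inf
  }
  matches <- data.frame(label = integer(0), sphere = integer(0),
                        actualDiameterMm = numeric(0),
                        measuredDiameterMm = numeric(0),
                        errorPct = numeric(0), areaAccuracyPct = numeric(0))
  spurious <- integer(0)
  taken <- rep(FALSE, nrow(ctr))
  for (i in seq_len(nrow(rois))) {
    # region centroid in phantom mm coordinates
    x <- (rois$centroidCol[i] - (N + 1) / 2) * ps
    y <- (rois$centroidRow[i] - (M + 1) / 2) * ps
    dist2 <- sqrt((ctr[, 1L] - x)^2 + (ctr[, 2L] - y)^2)
    s <- which.min(dist2)
    if (length(s) && dist2[s] <= radius && !taken[s]) {
      taken[s] <- TRUE
      matches[nrow(matches) + 1L, ] <- list(
        rois$label[i], s, d[s], rois$equivalentDiameterMm[i],
        diameterErrorPct(rois$equivalentDiameterMm[i], d[s]),
        areaAccuracyPct(rois$areaMm2[i], pi * (d[s] / 2)^2))
    } else {
      spurious <- c(spurious, rois$label[i])
    }
  }
  list(matches = matches, spurious = spurious,
       missed = which(!taken))
}

#' Evaluate a denoising result against a clean reference
#'
#' @param clean,noisy,denoised [Image2D-class] objects of one shape.
#' @param dataLossMseBound reconstruction-fidelity bound: the report's
#'   \code{dataLoss} flag is "High" when the denoised-vs-clean MSE exceeds
#'   it, else "Normal".
#' @return list with \code{denoised} and \code{noisy} metric sub-reports
#'   (mse, psnr_db, snr_db), \code{psnrGainDb} and \code{dataLoss}.
#' @export
evaluateDenoising <- function(clean, noisy, denoised,
                              dataLossMseBound = Inf) {
  checkSameShape(clean, noisy)
  checkSameShape(clean, denoised)
  den <- qualityReport(clean, denoised)
  noi <- qualityReport(clean, noisy)
  list(denoised = den, noisy = noi,
       psnrGainDb = den$psnr_db - noi$psnr_db,
       dataLoss = if (den$mse > dataLossMseBound) "High" else "Normal")
}

#' Denoise with a named transform at a noise-calibrated threshold
#'
#' Convenience front end used by the comparison protocol: applies the chosen
#' transform's hard-threshold denoiser at \code{t = k * sigma} (all three
#' transforms are normalised so white pixel noise keeps its standard
#' deviation in the coefficient domain; curvelet bands are additionally
#' scaled by their per-band noise gain).
#'
#' @param img the noisy [Image2D-class].
#' @param method "wavelet", "ridgelet" or "curvelet".
#' @param sigma noise standard deviation in intensity units.
#' @param k threshold multiple of sigma (default 3).
#' @param filter wavelet filter name.
#' @param levels wavelet depth.
#' @param p ridgelet block size.
#' @param system optional precomputed [CurveletSystem-class].
#' @return the denoised [Image2D-class].
#' @export
mraDenoise <- function(img, method = c("curvelet", "wavelet", "ridgelet"),
                       sigma, k = 3, filter = "haar", levels = 2L, p = 13L,
                       system = NULL) {
  method <- match.arg(method)
  t <- k * sigma
  switch(method,
    wavelet = denoiseWavelet(img, filter, levels, t),
    ridgelet = denoiseRidgelet(img, p = p, filter = filter, t = t,
                               levels = 3L),
    curvelet = denoiseCurvelet(img, system, t, perBandNoise = TRUE)
  )
}
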