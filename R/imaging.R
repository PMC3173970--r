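#' Construct an Image2D
#'
#' @param pixels numeric matrix (or vector with \code{dim} set) of
#'   intensities.
#' @param pixelSizeMm isotropic physical pixel size in millimetres.
#' @param intensityMax nominal peak intensity (255 for 8-bit data); used as
#'   the default PSNR peak.
#' @return an [Image2D-class] object.
#' @examples
#' img <- Image2D(matrix(0:24, 5, 5), pixelSizeMm = 2)
#' dim(img)
#' @export
Image2D <- function(pixels, pixelSizeMm = 1, intensityMax = 255) {
  new("Image2D", pixels = as.matrix(pixels) * 1.0,
      pixelSizeMm = as.numeric(pixelSizeMm),
      intensityMax = as.numeric(intensityMax))
}

#' @describeIn Image2D pixel matrix accessor.
#' @param img,x an Image2D.
#' @export
pixels <- function(img) img@pixels

#' @describeIn Image2D pixel size accessor (mm).
#' @export
pixelSizeMm <- function(img) img@pixelSizeMm

#' @describeIn Image2D nominal intensity peak accessor.
#' @export
intensityMax <- function(img) img@intensityMax

#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

setMethod("show", "Image2D", function(object) {
  p <- object@pixels
  cat(sprintf("Image2D: %d x %d pixels, %.4f mm/pixel, peak %g\n",
              nrow(p), ncol(p), object@pixelSizeMm, object@intensityMax))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(p), max(p)))
})

#' Read a grayscale PNG or TIFF image
#'
#' Pixel values are rescaled from the file's [0, 1] representation to the
#' nominal integer scale (0-255 for 8-bit, 0-65535 for 16-bit). Multi-channel
#' images are rejected unless \code{toLuminance = TRUE}, in which case the
#' Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B) is taken.
#'
#' DICOM input is not supported; convert single slices to 16-bit PNG/TIFF
#' first.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param pixelSizeMm physical pixel size to attach (not stored in PNG).
#' @param toLuminance convert RGB input to luminance instead of failing.
#' @return an [Image2D-class].
#' @export
readImage2D <- function(path, pixelSizeMm = 1, toLuminance = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 8L  # png::readPNG scales to [0,1]; assume 8-bit
  if (ext == "png") {
    # readPNG does not expose depth; infer 16-bit from value granularity
    v <- raw[raw > 0]
    bits <- if (length(v) && any(abs(v * 255 - round(v * 255)) > 1e-9)) 16L else 8L
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 2L) {        # gray + alpha: drop alpha
      raw <- raw[, , 1L]
    } else if (!toLuminance) {
      stop("multi-channel image; set toLuminance = TRUE to convert",
           call. = FALSE)
    } else {
      raw <- 0.299 * raw[, , 1L] + 0.587 * raw[, , 2L] + 0.114 * raw[, , 3L]
    }
  }
  peak <- 2^bits - 1
  raw <- matrix(as.numeric(raw), nrow(raw), ncol(raw))  # drop file metadata
  Image2D(raw * peak, pixelSizeMm = pixelSizeMm, intensityMax = peak)
}

#' Write an Image2D as grayscale PNG or TIFF
#'
#' Intensities are rounded to integers on the requested bit depth and, when
#' \code{clip = TRUE}, clamped into range first; out-of-range values with
#' clipping disabled raise an error. Integer-valued in-range images round
#' trip losslessly.
#'
#' @param img an [Image2D-class].
#' @param path output path (.png, .tif, .tiff).
#' @param bitDepth 8 or 16.
#' @param clip clamp values into the representable range before writing.
#' @return invisibly, the path.
#' @export
writeImage2D <- function(img, path, bitDepth = 8L, clip = FALSE) {
  stopifnot(is(img, "Image2D"))
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16", call. = FALSE)
  peak <- 2^bitDepth - 1
  p <- img@pixels
  if (clip) p <- pmin(pmax(p, 0), peak)
  if (min(p) < 0 || max(p) > peak) {
    stop(sprintf("intensities outside [0, %d]; enable clip or rescale", peak),
         call. = FALSE)
  }
  v <- round(p) / peak
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = as.integer(bitDepth)),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Hard intensity threshold
#'
#' Sets pixels strictly below \code{t} to zero and leaves pixels at or above
#' \code{t} unchanged, so \code{t = 0} is an exact identity. This is the
#' pre-/post-processing step of the segmentation pipeline (defaults 35 and 7
#' on the 8-bit scale).
#'
#' @param img an [Image2D-class].
#' @param t threshold, >= 0.
#' @return an [Image2D-class] of the same shape.
#' @export
hardThresholdIntensity <- function(img, t) {
  stopifnot(is(img, "Image2D"))
  stopUnlessScalarGe0(t)
  p <- img@pixels
  p[p < t] <- 0
  Image2D(p, img@pixelSizeMm, img@intensityMax)
}

checkSameShape <- function(a, b) {
  if (!identical(dim(a@pixels), dim(b@pixels))) {
    stop("images must have the same shape", call. = FALSE)
  }
}

#' Mean squared error between two images
#'
#' @param a,b [Image2D-class] objects of the same shape.
#' @return mean of squared pixel differences.
#' @export
imageMSE <- function(a, b) {
  checkSameShape(a, b)
  mean((a@pixels - b@pixels)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \code{10 log10(peak^2 / MSE)}; returns \code{Inf} when the images are
#' identical. The peak defaults to the nominal intensity maximum of the
#' reference image.
#'
#' @param a reference [Image2D-class].
#' @param b test image, same shape.
#' @param peak positive peak intensity.
#' @export
imagePSNR <- function(a, b, peak = intensityMax(a)) {
  if (!is.numeric(peak) || length(peak) != 1L || peak <= 0) {
    stop("peak must be a single positive number", call. = FALSE)
  }
  m <- imageMSE(a, b)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Signal-to-noise ratio (dB), reference-difference convention
#'
#' \code{10 log10(sum(signal^2) / sum((noisy - signal)^2))}: the energy of
#' the clean reference over the energy of the residual. Returns \code{Inf}
#' for identical inputs; a reference with zero energy is a degenerate input.
#' Invariant under joint positive scaling of both images.
#'
#' @param signal clean reference [Image2D-class].
#' @param noisy degraded image, same shape.
#' @export
imageSNR <- function(signal, noisy) {
  checkSameShape(signal, noisy)
  es <- sum(signal@pixels^2)
  if (es == 0) stop("reference signal has zero energy", call. = FALSE)
  en <- sum((noisy@pixels - signal@pixels)^2)
  if (en == 0) return(Inf)
  10 * log10(es / en)
}

#' Fidelity metrics as a flat report
#'
#' @param reference clean reference image.
#' @param test degraded or processed image, same shape.
#' @param peak PSNR peak (defaults to the reference's nominal maximum).
#' @return named list with \code{mse}, \code{psnr_db}, \code{snr_db}.
#' @export
qualityReport <- function(reference, test, peak = intensityMax(reference)) {
  list(mse = imageMSE(reference, test),
       psnr_db = imagePSNR(reference, test, peak),
       snr_db = imageSNR(reference, test))
}

#' Write a flat key-value metrics report
#'
#' @param report named list of scalars (e.g. from [qualityReport()]).
#' @param path output path.
#' @param format "json" or "text". Non-finite values are written as strings
#'   ("Inf") in JSON.
#' @export
writeMetricsReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    rep <- lapply(report, function(v) {
      if (is.numeric(v) && length(v) == 1L && !is.finite(v)) as.character(v) else v
    })
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(names(report), function(k) {
      paste0(k, " = ", format(report[[k]], digits = 10))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
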