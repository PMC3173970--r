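#' Create a phantom specification
#'
#' Defaults render the equatorial slice of a NEMA-IEC-style body phantom on
#' the reference acquisition grid: 128 x 128 pixels of 4.6875 mm, six disc
#' inserts of diameters 10, 13, 17, 22, 28, 37 mm on a 57 mm ring inside an
#' elliptical cavity of semi-axes 150 x 115 mm. Intensities (background,
#' cavity, sphere) default to 0, 20, 200 on the 8-bit scale, mimicking a
#' scan in which the water cavity is faint relative to the hot inserts so
#' that the standard pre-threshold (t = 35) isolates the inserts.
#'
#' @param grid integer (rows, cols).
#' @param pixelSizeMm isotropic pixel size, mm.
#' @param cavitySemiAxesMm ellipse semi-axes (a along columns, b along rows).
#' @param sphereDiametersMm insert diameters, mm.
#' @param sphereRingRadiusMm placement ring radius, mm.
#' @param intensities named numeric (background, cavity, sphere).
#' @param supersample 1 for centre-point membership, k > 1 for k x k
#'   area-fraction antialiasing.
#' @return a validated [PhantomSpec-class].
#' @export
PhantomSpec <- function(grid = c(128L, 128L), pixelSizeMm = 4.6875,
                        cavitySemiAxesMm = c(150, 115),
                        sphereDiametersMm = c(10, 13, 17, 22, 28, 37),
                        sphereRingRadiusMm = 57,
                        intensities = c(background = 0, cavity = 20,
                                        sphere = 200),
                        supersample = 1L) {
  new("PhantomSpec", grid = as.integer(grid), pixelSizeMm = pixelSizeMm,
      cavitySemiAxesMm = cavitySemiAxesMm,
      sphereDiametersMm = sphereDiametersMm,
      sphereRingRadiusMm = sphereRingRadiusMm,
      intensities = intensities, supersample = as.integer(supersample))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d grid at %.4f mm/pixel\n",
              object@grid[1L], object@grid[2L], object@pixelSizeMm))
  cat("  cavity semi-axes (mm):",
      paste(object@cavitySemiAxesMm, collapse = " x "), "\n")
  cat("  insert diameters (mm):",
      paste(object@sphereDiametersMm, collapse = ", "), "\n")
})

#' Render a phantom image
#'
#' Deterministic rasterisation of the phantom slice: a pixel takes the
#' sphere intensity if its centre lies inside any disc, else the cavity
#' intensity if inside the ellipse, else the background. With
#' \code{supersample > 1} each pixel is the mean over a subgrid instead
#' (area-fraction antialiasing).
#'
#' @param spec a [PhantomSpec-class].
#' @return an [Image2D-class].
#' @export
generatePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  M <- spec@grid[1L]; N <- spec@grid[2L]; ps <- spec@pixelSizeMm
  ss <- spec@supersample
  a <- spec@cavitySemiAxesMm[1L]; b <- spec@cavitySemiAxesMm[2L]
  ints <- spec@intensities
  ctr <- sphereCentres(spec)
  rad <- spec@sphereDiametersMm / 2
  # subpixel offsets (mm) relative to the pixel centre
  off <- (seq_len(ss) - (ss + 1) / 2) / ss * ps
  acc <- matrix(0, M, N)
  rowc <- (seq_len(M) - (M + 1) / 2) * ps   # y, along rows
  colc <- (seq_len(N) - (N + 1) / 2) * ps   # x, along columns
  for (oy in off) {
    y <- rowc + oy
    for (ox in off) {
      x <- colc + ox
      X <- matrix(x, M, N, byrow = TRUE)
      Y <- matrix(y, M, N)
      val <- matrix(ints[["background"]], M, N)
      inCav <- (X / a)^2 + (Y / b)^2 <= 1
      val[inCav] <- ints[["cavity"]]
      if (nrow(ctr)) {
        inSph <- matrix(FALSE, M, N)
        for (s in seq_len(nrow(ctr))) {
          inSph <- inSph |
            ((X - ctr[s, 1L])^2 + (Y - ctr[s, 2L])^2 <= rad[s]^2)
        }
        val[inSph] <- ints[["sphere"]]
      }
      acc <- acc + val
    }
  }
  Image2D(acc / ss^2, pixelSizeMm = ps, intensityMax = 255)
}

#' Contaminate an image with Gaussian white noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' \code{sigmaFraction * max(img)} — the evaluation protocol uses 20% of the
#' maximum intensity. The output is not clipped: metrics and transforms
#' operate on real-valued arrays, and clamping happens only when writing
#' integer image files.
#'
#' @param img an [Image2D-class].
#' @param model a [NoiseModel-class]; or use \code{sigmaFraction}/\code{seed}.
#' @param sigmaFraction shortcut when \code{model} is missing.
#' @param seed integer seed for reproducibility (NA = current RNG stream).
#' @return an [Image2D-class] of the same shape.
#' @export
addGaussianNoise <- function(img, model = NULL, sigmaFraction = 0.2,
                             seed = NA_integer_) {
  stopifnot(is(img, "Image2D"))
  if (is.null(model)) {
    model <- new("NoiseModel", sigmaFraction = sigmaFraction,
                 seed = as.integer(seed))
  }
  validObject(model)
  sg <- model@sigmaFraction * max(img@pixels)
  if (sg == 0) return(img)
  if (!is.na(model@seed)) set.seed(model@seed)
  p <- img@pixels + stats::rnorm(length(img@pixels), sd = sg)
  Image2D(p, img@pixelSizeMm, img@intensityMax)
}

#' Total cross-sectional insert area
#'
#' \code{sum(pi * (d/2)^2)} over the diameter list. For the standard insert
#' set \{10, 13, 17, 22, 28, 37\} mm this is 2509.17 mm^2, giving a
#' spheres-to-background ratio of 0.702% on the default grid.
#'
#' @param diametersMm numeric vector of disc diameters, mm.
#' @return area in mm^2.
#' @export
sphereAreaTotal <- function(diametersMm) {
  if (length(diametersMm) && any(diametersMm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  sum(pi * (diametersMm / 2)^2)
}

#' Physical area of a slice
#'
#' @param M,N grid dimensions.
#' @param pixelSizeMm isotropic pixel size, mm.
#' @return \code{M * N * pixelSizeMm^2} in mm^2 (360000 for the default
#'   128 x 128 grid of 4.6875 mm pixels).
#' @export
sliceArea <- function(M, N, pixelSizeMm) {
  stopifnot(M >= 1, N >= 1, pixelSizeMm > 0)
  M * N * pixelSizeMm^2
}

#' Spheres-to-background ratio (percent)
#'
#' \code{100 * S / (A - S)} with S the total insert area and A the slice
#' area; 0.702% for the default phantom geometry.
#'
#' @inheritParams sphereAreaTotal
#' @inheritParams sliceArea
#' @export
sbr <- function(diametersMm, M, N, pixelSizeMm) {
  S <- sphereAreaTotal(diametersMm)
  A <- sliceArea(M, N, pixelSizeMm)
  if (S >= A) stop("insert area must be smaller than the slice area",
                   call. = FALSE)
  100 * S / (A - S)
}
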