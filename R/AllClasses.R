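#' @import methods
NULL

#' Image2D: a 2D grayscale raster with physical pixel size
#'
#' The central container of the package: a real-valued matrix of intensities
#' \code{f[m, n]} together with the isotropic physical pixel size in
#' millimetres and the nominal intensity peak (255 for 8-bit data).
#' Intensities are kept as doubles throughout; quantisation happens only when
#' writing integer image files.
#'
#' @slot pixels numeric matrix of intensities (rows M, columns N).
#' @slot pixelSizeMm positive scalar, physical edge length of one pixel (mm).
#' @slot intensityMax nominal peak intensity (used as the default PSNR peak).
#'
#' @seealso [Image2D()], [readImage2D()], [writeImage2D()]
#' @export
setClass("Image2D",
  representation(
    pixels = "matrix",
    pixelSizeMm = "numeric",
    intensityMax = "numeric"
  ),
  prototype(pixelSizeMm = 1, intensityMax = 255)
)

setValidity("Image2D", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (!all(is.finite(p))) return("all intensities must be finite")
  if (length(object@pixelSizeMm) != 1L || !is.finite(object@pixelSizeMm) ||
      object@pixelSizeMm <= 0) {
    return("pixelSizeMm must be a single positive number")
  }
  if (length(object@intensityMax) != 1L || !is.finite(object@intensityMax) ||
      object@intensityMax <= 0) {
    return("intensityMax must be a single positive number")
  }
  TRUE
})

#' Wavelet filter bank (orthonormal conjugate pair)
#'
#' Low-pass coefficients \code{l(i)} with unit Euclidean norm and sum
#' \code{sqrt(2)}; the high-pass is the quadrature mirror
#' \code{h(i) = (-1)^i l(L-1-i)}.
#'
#' @slot name filter identifier ("haar", "db2").
#' @slot lowpass numeric vector of low-pass coefficients.
#' @slot highpass numeric vector of high-pass coefficients.
#' @export
setClass("WaveletFilter",
  representation(name = "character", lowpass = "numeric", highpass = "numeric")
)

setValidity("WaveletFilter", function(object) {
  lp <- object@lowpass; hp <- object@highpass
  if (length(lp) < 2L || length(lp) %% 2L != 0L) {
    return("lowpass must have even length >= 2")
  }
  if (abs(sqrt(sum(lp^2)) - 1) > 1e-12) return("lowpass must have unit norm")
  if (abs(sum(lp) - sqrt(2)) > 1e-12) return("lowpass must sum to sqrt(2)")
  L <- length(lp)
  qm <- (-1)^(0:(L - 1L)) * rev(lp)
  if (max(abs(hp - qm)) > 1e-12) {
    return("highpass must be the quadrature mirror of lowpass")
  }
  TRUE
})

#' Multilevel 2D wavelet pyramid
#'
#' Non-redundant Mallat decomposition: per level the three detail subbands
#' (LH, HL, HH) plus the final approximation LL_J. Subband dimensions halve
#' by ceiling division at each level (odd lengths carry their last sample
#' into the approximation, scaled by sqrt(2) so constants stay constant), and
#' the total coefficient count equals the original pixel count.
#'
#' @slot filterName character, name of the filter used.
#' @slot levels integer, number of decomposition levels J.
#' @slot details list of length J; element j is a list with matrices
#'   \code{LH}, \code{HL}, \code{HH} at level j (1 = finest).
#' @slot approx matrix, the approximation LL_J.
#' @slot originalDim integer vector (M, N) of the decomposed image.
#' @slot pixelSizeMm,intensityMax carried over from the source image so that
#'   reconstruction restores a full [Image2D-class].
#' @export
setClass("WaveletPyramid",
  representation(
    filterName = "character",
    levels = "integer",
    details = "list",
    approx = "matrix",
    originalDim = "integer",
    pixelSizeMm = "numeric",
    intensityMax = "numeric"
  )
)

setValidity("WaveletPyramid", function(object) {
  J <- object@levels
  if (J < 1L) return("levels must be >= 1")
  if (length(object@details) != J) return("details must have one entry per level")
  d <- object@originalDim
  if (length(d) != 2L) return("originalDim must have length 2")
  m <- d[1L]; n <- d[2L]
  total <- 0L
  for (j in seq_len(J)) {
    ma <- as.integer(ceiling(m / 2)); md <- m - ma
    na <- as.integer(ceiling(n / 2)); nd <- n - na
    lvl <- object@details[[j]]
    if (!setequal(names(lvl), c("LH", "HL", "HH"))) {
      return("each level must hold subbands LH, HL, HH")
    }
    if (!identical(dim(lvl$LH), c(ma, nd)) ||
        !identical(dim(lvl$HL), c(md, na)) ||
        !identical(dim(lvl$HH), c(md, nd))) {
      return(sprintf("subband dimensions at level %d are inconsistent", j))
    }
    total <- total + ma * nd + md * na + md * nd
    m <- ma; n <- na
  }
  if (!identical(dim(object@approx), c(m, n))) {
    return("approximation dimensions inconsistent with levels")
  }
  if (total + m * n != prod(object@originalDim)) {
    return("pyramid is not non-redundant")
  }
  TRUE
})

#' Finite Radon projections over a prime grid
#'
#' The (p+1) x p array of projections r_k[l] of a p x p block over the finite
#' geometry Z_p^2: row k (k = 0..p-1) sums the lines j = k*i + l (mod p), row
#' p sums the lines of constant first index. Normalisation is 1/sqrt(p) per
#' line sum. The block mean is stored alongside so coefficient thresholding
#' can never shift the DC level.
#'
#' @slot p prime block size.
#' @slot values (p+1) x p numeric matrix; row k+1 is projection r_k.
#' @slot meanOffset the mean of the transformed block.
#' @export
setClass("RadonProjections",
  representation(p = "integer", values = "matrix", meanOffset = "numeric")
)

setValidity("RadonProjections", function(object) {
  p <- object@p
  if (!isPrime(p)) return("p must be prime")
  if (!identical(dim(object@values), c(p + 1L, p))) {
    return("values must be (p+1) x p")
  }
  TRUE
})

#' Finite ridgelet coefficients of one block
#'
#' A multilevel 1D wavelet decomposition of each of the p+1 finite-Radon
#' projections of a p x p block. Each direction keeps exactly p coefficients
#' (odd lengths carry the last sample into the approximation), so the
#' representation over all directions has (p+1) x p values like the Radon
#' array it came from.
#'
#' @slot p prime block size.
#' @slot filterName wavelet filter used along each projection.
#' @slot levels decomposition depth actually applied.
#' @slot rows list of p+1 per-direction decompositions (as returned by
#'   [dwt1d()]).
#' @slot meanOffset block mean, carried from [RadonProjections-class].
#' @export
setClass("RidgeletCoefficients",
  representation(
    p = "integer",
    filterName = "character",
    levels = "integer",
    rows = "list",
    meanOffset = "numeric"
  )
)

setValidity("RidgeletCoefficients", function(object) {
  if (!isPrime(object@p)) return("p must be prime")
  if (length(object@rows) != object@p + 1L) {
    return("one decomposition per direction (p+1) required")
  }
  TRUE
})

#' Curvelet system: scales, angles and frequency-wedge geometry
#'
#' The plan for a wrapping-based fast discrete curvelet transform of an
#' M x N image: number of scales J, angles per scale (1 nondirectional band
#' at the coarsest scale; at least 8 and a multiple of 4 at the second
#' coarsest; doubling every other scale toward fine), and the Meyer-type
#' radial/angular window parameters. Wedge masks are constructed lazily and
#' cached in an environment slot, so planning is cheap even for large images.
#'
#' @slot dim integer (M, N) image dimensions.
#' @slot nscales integer J.
#' @slot nangles integer vector of length J; \code{nangles[1] == 1}.
#' @slot angularOverlap half-width of the angular transition band as a
#'   fraction of the wedge spacing.
#' @slot cache environment holding lazily built [FrequencyTile-class]s.
#' @export
setClass("CurveletSystem",
  representation(
    dim = "integer",
    nscales = "integer",
    nangles = "integer",
    angularOverlap = "numeric",
    cache = "environment"
  )
)

setValidity("CurveletSystem", function(object) {
  if (length(object@dim) != 2L || any(object@dim < 32L)) {
    return("image dimensions must be at least 32 x 32")
  }
  J <- object@nscales
  if (J < 2L) return("at least 2 scales required")
  na <- object@nangles
  if (length(na) != J) return("nangles must have one entry per scale")
  if (na[1L] != 1L) return("coarsest scale must have exactly 1 band")
  if (J >= 2L && (na[2L] < 8L || na[2L] %% 4L != 0L)) {
    return("second-coarsest angle count must be >= 8 and a multiple of 4")
  }
  TRUE
})

#' One frequency wedge of a curvelet system
#'
#' The sampled wedge mask U_{j,l} restricted to its bounding rectangle on the
#' centred frequency grid, plus the offsets needed to wrap the windowed
#' spectrum into that rectangle by periodic index folding. Masks are real,
#' lie in [0, 1], and over all (j, l) their squares sum to one at every
#' frequency sample, which makes the transform a tight frame.
#'
#' @slot scale,angle indices (j, l).
#' @slot mask numeric matrix of window values on the bounding rectangle.
#' @slot rowOffset,colOffset position of the rectangle's first row/column in
#'   centred frequency coordinates (DC at 0).
#' @export
setClass("FrequencyTile",
  representation(
    scale = "integer",
    angle = "integer",
    mask = "matrix",
    rowOffset = "integer",
    colOffset = "integer"
  )
)

#' Curvelet coefficients
#'
#' Nested scale -> angle -> complex coefficient arrays produced by the
#' wrapping transform, linked to the [CurveletSystem-class] that generated
#' them. For a tight frame the total coefficient energy equals the image
#' energy.
#'
#' @slot system the generating [CurveletSystem-class].
#' @slot bands list of J lists; \code{bands[[j]][[l]]} is the complex
#'   coefficient matrix at scale j, orientation l.
#' @slot pixelSizeMm,intensityMax metadata carried from the source image.
#' @export
setClass("CurveletCoefficients",
  representation(
    system = "CurveletSystem",
    bands = "list",
    pixelSizeMm = "numeric",
    intensityMax = "numeric"
  )
)

setValidity("CurveletCoefficients", function(object) {
  sys <- object@system
  if (length(object@bands) != sys@nscales) {
    return("one band list per scale required")
  }
  for (j in seq_len(sys@nscales)) {
    if (length(object@bands[[j]]) != sys@nangles[j]) {
      return(sprintf("scale %d must hold %d bands", j, sys@nangles[j]))
    }
  }
  TRUE
})

#' Synthetic NEMA-IEC-style phantom specification
#'
#' Geometry and intensity levels of the equatorial slice of a body phantom:
#' an elliptical water-filled cavity containing six discs (the spherical
#' inserts at their maximal diameter) placed angularly equispaced on a ring.
#'
#' Defaults follow the reference acquisition: a 128 x 128 grid of
#' 4.6875 mm pixels and insert diameters 10, 13, 17, 22, 28, 37 mm.
#'
#' @slot grid integer (M, N).
#' @slot pixelSizeMm isotropic pixel size in mm.
#' @slot cavitySemiAxesMm semi-axes (a, b) of the elliptical cavity in mm.
#' @slot sphereDiametersMm diameters of the disc inserts in mm.
#' @slot sphereRingRadiusMm placement radius of the disc centres in mm.
#' @slot intensities named numeric: background, cavity, sphere levels on the
#'   8-bit scale.
#' @slot supersample integer; 1 = centre-point membership test, k > 1 = k x k
#'   subsampled area-fraction rendering.
#' @export
setClass("PhantomSpec",
  representation(
    grid = "integer",
    pixelSizeMm = "numeric",
    cavitySemiAxesMm = "numeric",
    sphereDiametersMm = "numeric",
    sphereRingRadiusMm = "numeric",
    intensities = "numeric",
    supersample = "integer"
  ),
  prototype(
    grid = c(128L, 128L),
    pixelSizeMm = 4.6875,
    cavitySemiAxesMm = c(150, 115),
    sphereDiametersMm = c(10, 13, 17, 22, 28, 37),
    sphereRingRadiusMm = 57,
    intensities = c(background = 0, cavity = 20, sphere = 200),
    supersample = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@grid) != 2L || any(object@grid < 1L)) {
    return("grid must be two positive integers")
  }
  if (object@pixelSizeMm <= 0) return("pixelSizeMm must be positive")
  ab <- object@cavitySemiAxesMm
  if (length(ab) != 2L || any(ab <= 0)) {
    return("cavity semi-axes must be two positive numbers")
  }
  d <- object@sphereDiametersMm
  if (length(d) && any(d <= 0)) return("sphere diameters must be positive")
  if (!setequal(names(object@intensities),
                c("background", "cavity", "sphere"))) {
    return("intensities must be named background, cavity, sphere")
  }
  if (object@supersample < 1L) return("supersample must be >= 1")
  # cavity inside grid
  half <- object@grid * object@pixelSizeMm / 2
  if (ab[1] > half[2L] || ab[2] > half[1L]) {
    return("cavity does not fit inside the grid")
  }
  if (length(d)) {
    ctr <- sphereCentres(object)
    # discs inside cavity: scaled distance of farthest disc point
    for (s in seq_along(d)) {
      r <- d[s] / 2
      # conservative check: centre scaled-distance plus radius over min axis
      sc <- sqrt((ctr[s, 1] / ab[1])^2 + (ctr[s, 2] / ab[2])^2)
      if (sc + r / min(ab) > 1) return("a disc extends outside the cavity")
    }
    if (length(d) > 1L) {
      dd <- as.matrix(stats::dist(ctr))
      rr <- outer(d / 2, d / 2, "+")
      diag(dd) <- Inf
      if (any(dd <= rr)) return("discs overlap")
    }
  }
  TRUE
})

#' Gaussian noise model
#'
#' Additive i.i.d. zero-mean Gaussian noise with standard deviation
#' \code{sigmaFraction} times the maximum intensity of the target image,
#' the contamination protocol used for the denoising comparisons.
#'
#' @slot sigmaFraction noise level as a fraction of max intensity.
#' @slot seed integer seed (NA = leave the RNG stream alone).
#' @export
setClass("NoiseModel",
  representation(sigmaFraction = "numeric", seed = "integer"),
  prototype(sigmaFraction = 0.2, seed = NA_integer_)
)

setValidity("NoiseModel", function(object) {
  if (object@sigmaFraction < 0) return("sigmaFraction must be >= 0")
  TRUE
})

#' Segmentation pipeline configuration
#'
#' Parameters of the threshold -> transform-denoise -> threshold pipeline:
#' an intensity pre-threshold (default 35 on the 8-bit scale, removing
#' scanner artefacts), a transform-domain hard threshold, an intensity
#' post-threshold (default 7, removing residual noise), and the
#' connected-component extraction rules.
#'
#' @slot tPre,tPost intensity thresholds (8-bit scale; use
#'   \code{intensityScale} to adapt to 16-bit data).
#' @slot transform one of "none", "wavelet", "ridgelet", "curvelet".
#' @slot tCoef hard threshold applied to transform detail coefficients.
#' @slot filterName wavelet filter (wavelet/ridgelet transforms).
#' @slot levels wavelet decomposition depth.
#' @slot blockSize prime block size p for the ridgelet transform.
#' @slot nscales curvelet scale count (NA = default depth rule).
#' @slot minRoiPixels components smaller than this are discarded.
#' @slot excludeBorder drop components touching the image border.
#' @slot excludeLargest additionally drop the single largest component.
#' @slot intensityScale multiplier applied to tPre/tPost (e.g. 257 for
#'   16-bit data expressed on a 0-65535 scale).
#' @export
setClass("SegmentationConfig",
  representation(
    tPre = "numeric",
    tPost = "numeric",
    transform = "character",
    tCoef = "numeric",
    filterName = "character",
    levels = "integer",
    blockSize = "integer",
    nscales = "integer",
    minRoiPixels = "integer",
    excludeBorder = "logical",
    excludeLargest = "logical",
    intensityScale = "numeric"
  ),
  prototype(
    tPre = 35, tPost = 7, transform = "none", tCoef = 0,
    filterName = "haar", levels = 2L, blockSize = 13L, nscales = NA_integer_,
    minRoiPixels = 4L, excludeBorder = TRUE, excludeLargest = FALSE,
    intensityScale = 1
  )
)

setValidity("SegmentationConfig", function(object) {
  if (object@tPre < 0 || object@tPost < 0 || object@tCoef < 0) {
    return("thresholds must be >= 0")
  }
  if (!object@transform %in% c("none", "wavelet", "ridgelet", "curvelet")) {
    return("transform must be none, wavelet, ridgelet or curvelet")
  }
  if (object@transform == "ridgelet" && !isPrime(object@blockSize)) {
    return("ridgelet block size must be prime")
  }
  if (object@minRoiPixels < 1L) return("minRoiPixels must be >= 1")
  if (object@intensityScale <= 0) return("intensityScale must be positive")
  TRUE
})
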