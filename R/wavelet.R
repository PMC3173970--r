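#' Built-in orthonormal wavelet filters
#'
#' "haar" is the 2-tap averaging/differencing pair; "db2" is the 4-tap
#' Daubechies filter with two vanishing moments. The high-pass is always the
#' quadrature mirror of the low-pass.
#'
#' @param name "haar" or "db2".
#' @return a [WaveletFilter-class].
#' @examples
#' waveletFilter("haar")@lowpass
#' @export
waveletFilter <- function(name = c("haar", "db2")) {
  name <- match.arg(name)
  lp <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  L <- length(lp)
  hp <- (-1)^(0:(L - 1L)) * rev(lp)
  new("WaveletFilter", name = name, lowpass = lp, highpass = hp)
}

resolveFilter <- function(filter) {
  if (is(filter, "WaveletFilter")) filter else waveletFilter(filter)
}

# One analysis step on the columns of a matrix (each row is a signal of
# length n): a(k) = sum_i l(i) x(2k - i mod n), periodic extension. The step
# is orthonormal for even n. Odd n carries its last sample into the
# approximation scaled by sqrt(2): the transform stays exactly invertible,
# and a constant signal keeps a constant approximation with zero details at
# every level (so thresholding can never shift the DC level), at the cost of
# exact energy preservation in that one coordinate.
dwtStepRows <- function(X, filter) {
  n <- ncol(X)
  if (n < 2L) stop("signal too short for a decomposition step", call. = FALSE)
  tailCol <- NULL
  if (n %% 2L == 1L) {
    tailCol <- X[, n, drop = FALSE] * sqrt(2)
    X <- X[, -n, drop = FALSE]
    n <- n - 1L
  }
  lp <- filter@lowpass; hp <- filter@highpass
  half <- n %/% 2L
  A <- matrix(0, nrow(X), half)
  D <- matrix(0, nrow(X), half)
  ks <- 2L * (seq_len(half) - 1L)
  for (i in seq_along(lp)) {
    idx <- ((ks - (i - 1L)) %% n) + 1L
    A <- A + lp[i] * X[, idx, drop = FALSE]
    D <- D + hp[i] * X[, idx, drop = FALSE]
  }
  if (!is.null(tailCol)) A <- cbind(A, tailCol)
  list(approx = A, detail = D)
}

# Inverse of dwtStepRows (the adjoint on the even part, with the carried
# sample unscaled).
idwtStepRows <- function(A, D, filter, n) {
  tailCol <- NULL
  if (n %% 2L == 1L) {
    tailCol <- A[, ncol(A), drop = FALSE] / sqrt(2)
    A <- A[, -ncol(A), drop = FALSE]
  }
  ne <- 2L * ncol(A)
  lp <- filter@lowpass; hp <- filter@highpass
  X <- matrix(0, nrow(A), ne)
  ks <- 2L * (seq_len(ncol(A)) - 1L)
  for (i in seq_along(lp)) {
    idx <- ((ks - (i - 1L)) %% ne) + 1L
    X[, idx] <- X[, idx] + lp[i] * A + hp[i] * D
  }
  if (!is.null(tailCol)) X <- cbind(X, tailCol)
  X
}

#' One 1D analysis step
#'
#' Splits a signal into half-length approximation and detail using periodic
#' (circular) extension: \code{a(k) = sum_i l(i) x(2k - i mod n)} and
#' likewise with the high-pass. For even lengths the step is orthonormal, so
#' \code{||a||^2 + ||d||^2 = ||x||^2}.
#'
#' @param x numeric vector, length >= 2. Odd lengths carry their last sample
#'   into the approximation scaled by \code{sqrt(2)} (exactly invertible and
#'   DC-preserving, at the cost of exact energy preservation in that one
#'   coordinate).
#' @param filter a [WaveletFilter-class] or filter name.
#' @return list with \code{approx} and \code{detail} vectors.
#' @export
dwtStep <- function(x, filter = "haar") {
  filter <- resolveFilter(filter)
  r <- dwtStepRows(matrix(x, 1L), filter)
  list(approx = drop(r$approx), detail = drop(r$detail))
}

#' Multilevel 1D wavelet decomposition and reconstruction
#'
#' Repeated application of [dwtStep()] to the approximation. The depth is
#' capped at \code{floor(log2(length(x)))} and stops when the approximation
#' would drop below 2 samples. The output keeps exactly \code{length(x)}
#' coefficients.
#'
#' @param x numeric vector.
#' @param filter a [WaveletFilter-class] or name.
#' @param levels requested depth.
#' @return for \code{dwt1d}, a list with \code{filterName}, \code{levels},
#'   \code{lengths} (input length at each level), \code{details} (finest
#'   first) and \code{approx}; \code{idwt1d} inverts it exactly.
#' @export
dwt1d <- function(x, filter = "haar", levels = 3L) {
  filter <- resolveFilter(filter)
  n0 <- length(x)
  levels <- min(as.integer(levels), floor(log2(max(n0, 1L))))
  details <- list()
  lengths <- integer(0)
  a <- x
  j <- 0L
  while (j < levels && length(a) >= 2L) {
    lengths <- c(lengths, length(a))
    r <- dwtStep(a, filter)
    details[[length(details) + 1L]] <- r$detail
    a <- r$approx
    j <- j + 1L
  }
  list(filterName = filter@name, levels = j, lengths = lengths,
       details = details, approx = a)
}

#' @rdname dwt1d
#' @param dec a decomposition produced by \code{dwt1d}.
#' @export
idwt1d <- function(dec) {
  filter <- waveletFilter(dec$filterName)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- drop(idwtStepRows(matrix(a, 1L), matrix(dec$details[[j]], 1L),
                           filter, dec$lengths[j]))
  }
  a
}

#' Maximum decomposition depth for an image
#'
#' @param M,N image dimensions.
#' @return \code{floor(log2(min(M, N)))}.
#' @export
maxDwtLevels <- function(M, N) as.integer(floor(log2(min(M, N))))

#' 2D discrete wavelet transform (Mallat decomposition)
#'
#' At each level one filtering pass along the rows then one along the
#' columns, recursing on the LL band only. Boundary handling is periodic,
#' which keeps the transform orthonormal (Parseval holds exactly) whenever
#' every processed dimension is even; odd dimensions carry their last
#' row/column sample into the approximation scaled by \code{sqrt(2)}
#' (exactly invertible, DC-preserving).
#' Subband naming: the first letter is the filter applied along the rows
#' (vertical direction), the second along the columns, so LH holds
#' horizontal detail, HL vertical detail and HH diagonal detail.
#'
#' @param img an [Image2D-class] (or plain matrix).
#' @param filter a [WaveletFilter-class] or name ("haar", "db2").
#' @param levels decomposition depth, at most \code{floor(log2(min(M, N)))}.
#' @return a [WaveletPyramid-class].
#' @export
dwt2d <- function(img, filter = "haar", levels = 1L) {
  if (is.matrix(img)) img <- Image2D(img)
  stopifnot(is(img, "Image2D"))
  filter <- resolveFilter(filter)
  X <- img@pixels
  levels <- as.integer(levels)
  if (levels < 1L || levels > maxDwtLevels(nrow(X), ncol(X))) {
    stop("levels must be between 1 and floor(log2(min(M, N)))", call. = FALSE)
  }
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    r <- dwtStepRows(X, filter)                   # along rows (columns dim)
    cl <- dwtStepRows(t(r$approx), filter)        # along columns
    ch <- dwtStepRows(t(r$detail), filter)
    LL <- t(cl$approx); HL <- t(cl$detail)
    LH <- t(ch$approx); HH <- t(ch$detail)
    details[[j]] <- list(LH = LH, HL = HL, HH = HH)
    X <- LL
  }
  new("WaveletPyramid", filterName = filter@name, levels = levels,
      details = details, approx = X, originalDim = dim(img@pixels),
      pixelSizeMm = img@pixelSizeMm, intensityMax = img@intensityMax)
}

#' Inverse 2D discrete wavelet transform
#'
#' Exact inverse of [dwt2d()]; round-trip error is at floating-point level
#' for every supported size and filter.
#'
#' @param pyr a [WaveletPyramid-class].
#' @return the reconstructed [Image2D-class].
#' @export
idwt2d <- function(pyr) {
  stopifnot(is(pyr, "WaveletPyramid"))
  validObject(pyr)
  filter <- waveletFilter(pyr@filterName)
  dims <- vector("list", pyr@levels)
  m <- pyr@originalDim[1L]; n <- pyr@originalDim[2L]
  for (j in seq_len(pyr@levels)) {
    dims[[j]] <- c(m, n)
    m <- as.integer(ceiling(m / 2)); n <- as.integer(ceiling(n / 2))
  }
  X <- pyr@approx
  for (j in rev(seq_len(pyr@levels))) {
    d <- pyr@details[[j]]
    m <- dims[[j]][1L]; n <- dims[[j]][2L]
    L <- t(idwtStepRows(t(X), t(d$HL), filter, m))       # undo column pass
    H <- t(idwtStepRows(t(d$LH), t(d$HH), filter, m))
    X <- idwtStepRows(L, H, filter, n)                   # undo row pass
  }
  Image2D(X, pyr@pixelSizeMm, pyr@intensityMax)
}

#' Hard-threshold the detail subbands of a pyramid
#'
#' Coefficients with \code{|c| < t} in the LH/HL/HH subbands are zeroed; the
#' approximation band is never touched (thresholding the DC band would
#' destroy the segmentable foreground).
#'
#' @param pyr a [WaveletPyramid-class].
#' @param t threshold, >= 0.
#' @return a thresholded [WaveletPyramid-class].
#' @export
thresholdPyramid <- function(pyr, t) {
  stopifnot(is(pyr, "WaveletPyramid"))
  stopUnlessScalarGe0(t)
  if (t == 0) return(pyr)
  pyr@details <- lapply(pyr@details, function(lvl) {
    lapply(lvl, function(b) { b[abs(b) < t] <- 0; b })
  })
  pyr
}

#' Wavelet denoising by coefficient hard thresholding
#'
#' The decompose -> threshold details -> reconstruct composition.
#'
#' @inheritParams dwt2d
#' @param t coefficient threshold (for Gaussian noise of known standard
#'   deviation sigma, \code{3 * sigma} is a standard choice; the transform
#'   is orthonormal so coefficient noise has the same sigma as the pixels).
#' @return the denoised [Image2D-class].
#' @export
denoiseWavelet <- function(img, filter = "haar", levels = 2L, t = 0) {
  idwt2d(thresholdPyramid(dwt2d(img, filter, levels), t))
}

#' Total energy of a pyramid
#'
#' Sum of squared coefficients over all subbands; equals the image energy
#' for these orthonormal filters.
#'
#' @param pyr a [WaveletPyramid-class].
#' @export
pyramidEnergy <- function(pyr) {
  sum(pyr@approx^2) +
    sum(vapply(pyr@details,
               function(lvl) sum(lvl$LH^2) + sum(lvl$HL^2) + sum(lvl$HH^2),
               numeric(1)))
}

setMethod("show", "WaveletPyramid", function(object) {
  cat(sprintf("WaveletPyramid: %s filter, %d level(s), source %d x %d\n",
              object@filterName, object@levels,
              object@originalDim[1L], object@originalDim[2L]))
  cat(sprintf("  approximation %d x %d, energy %.6g\n",
              nrow(object@approx), ncol(object@approx),
              pyramidEnergy(object)))
})
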