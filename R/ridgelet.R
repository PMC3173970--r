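# Line index helper: for direction k (0..p-1) and row i, the column hit at
# offset l is j = (k*i + l) mod p; direction p collects the rows of constant
# first index. Everything is 0-based in the maths, 1-based in the arrays.

#' Finite Radon transform of a prime-sized block
#'
#' Sums the block over the p+1 families of modular lines of the finite
#' geometry Z_p^2: for direction k < p the lines
#' \code{j = k i + l (mod p)}, and for direction p the lines of constant
#' first index. Each line holds exactly p points and each family partitions
#' the grid, so the per-direction totals are all equal. The normalisation is
#' \code{1/sqrt(p)} per line sum, which makes the subsequent ridgelet
#' transform nearly norm-preserving (an alternative normalisation of the transform uses
#' 1/p; the constant is recorded in coefficient manifests).
#'
#' @param block numeric p x p matrix, p prime.
#' @return a [RadonProjections-class]: row k+1 of \code{values} is r_k.
#' @export
frat <- function(block) {
  block <- as.matrix(block)
  p <- nrow(block)
  if (ncol(block) != p) stop("block must be square", call. = FALSE)
  if (!isPrime(p)) stop("block size must be prime", call. = FALSE)
  r <- matrix(0, p + 1L, p)
  ls <- 0:(p - 1L)
  for (k in 0:(p - 1L)) {
    for (i in 0:(p - 1L)) {
      j <- (k * i + ls) %% p
      r[k + 1L, ] <- r[k + 1L, ] + block[i + 1L, j + 1L]
    }
  }
  r[p + 1L, ] <- rowSums(block)        # L(p, l) = {(l, j) : j in Z_p}
  new("RadonProjections", p = p, values = r / sqrt(p),
      meanOffset = mean(block))
}

#' Inverse finite Radon transform
#'
#' Exact closed-form back-projection: every pair of distinct grid points
#' shares exactly one line, so summing the p+1 projections through a point
#' counts that point p+1 times and every other point once, giving
#' \code{f(i,j) = (sqrt(p) * sum_k r_k[l_k(i,j)] - S) / p} with S the block
#' total.
#'
#' @param proj a [RadonProjections-class].
#' @return the reconstructed p x p matrix.
#' @export
ifrat <- function(proj) {
  stopifnot(is(proj, "RadonProjections"))
  validObject(proj)
  p <- proj@p
  r <- proj@values * sqrt(p)
  S <- sum(r[p + 1L, ])
  f <- matrix(0, p, p)
  is <- 0:(p - 1L)
  for (j in 0:(p - 1L)) {
    acc <- r[p + 1L, is + 1L] * 0
    for (k in 0:(p - 1L)) {
      l <- (j - k * is) %% p
      acc <- acc + r[k + 1L, l + 1L]
    }
    acc <- acc + r[p + 1L, is + 1L]    # direction p hits line l = i
    f[, j + 1L] <- (acc - S) / p
  }
  f
}

setMethod("show", "RadonProjections", function(object) {
  cat(sprintf("RadonProjections: p = %d (%d directions x %d offsets)\n",
              object@p, object@p + 1L, object@p))
})

#' Finite ridgelet transform of a block
#'
#' [frat()] followed by a multilevel 1D wavelet decomposition of each
#' projection (default 3 levels, capped at \code{floor(log2(p))}), mapping
#' line singularities in the block to point singularities along each
#' direction. Each direction keeps exactly p coefficients.
#'
#' @param block numeric p x p matrix, p prime.
#' @param filter a [WaveletFilter-class] or name.
#' @param levels wavelet depth along each projection.
#' @return a [RidgeletCoefficients-class].
#' @export
frit <- function(block, filter = "haar", levels = 3L) {
  filter <- resolveFilter(filter)
  proj <- frat(block)
  rows <- lapply(seq_len(proj@p + 1L), function(k) {
    dwt1d(proj@values[k, ], filter, levels)
  })
  new("RidgeletCoefficients", p = proj@p, filterName = filter@name,
      levels = rows[[1L]]$levels, rows = rows, meanOffset = proj@meanOffset)
}

#' Inverse finite ridgelet transform
#'
#' Inverse 1D wavelet transform per direction, then [ifrat()]. Exact.
#'
#' @param coeffs a [RidgeletCoefficients-class].
#' @return the reconstructed p x p matrix.
#' @export
ifrit <- function(coeffs) {
  stopifnot(is(coeffs, "RidgeletCoefficients"))
  validObject(coeffs)
  p <- coeffs@p
  vals <- t(vapply(coeffs@rows, idwt1d, numeric(p)))
  ifrat(new("RadonProjections", p = p, values = vals,
            meanOffset = coeffs@meanOffset))
}

#' Hard-threshold ridgelet detail coefficients
#'
#' Zeroes wavelet detail coefficients with \code{|c| < t} in every
#' direction; approximation coefficients are untouched, so the DC level of
#' the block can never shift.
#'
#' @param coeffs a [RidgeletCoefficients-class].
#' @param t threshold, >= 0.
#' @export
thresholdRidgelet <- function(coeffs, t) {
  stopifnot(is(coeffs, "RidgeletCoefficients"))
  stopUnlessScalarGe0(t)
  if (t == 0) return(coeffs)
  coeffs@rows <- lapply(coeffs@rows, function(dec) {
    dec$details <- lapply(dec$details, function(d) { d[abs(d) < t] <- 0; d })
    dec
  })
  coeffs
}

# Pad a matrix to multiples of p by symmetric edge replication (zero padding
# would create sharp artificial edges at block borders).
padToBlocks <- function(X, p) {
  padTo <- function(n) as.integer(ceiling(n / p) * p)
  m2 <- padTo(nrow(X)); n2 <- padTo(ncol(X))
  if (m2 > nrow(X)) {
    extra <- m2 - nrow(X)
    idx <- nrow(X) - (seq_len(extra) - 1L)      # mirror the last rows
    X <- rbind(X, X[idx, , drop = FALSE])
  }
  if (n2 > ncol(X)) {
    extra <- n2 - ncol(X)
    idx <- ncol(X) - (seq_len(extra) - 1L)
    X <- cbind(X, X[, idx, drop = FALSE])
  }
  X
}

#' Block-based ridgelet processing of an image
#'
#' Tiles the image with non-overlapping p x p blocks (padding by symmetric
#' edge replication to the next multiple of p), applies
#' [frit()] -> [thresholdRidgelet()] -> [ifrit()] per block, and un-pads.
#' With \code{t = 0} this reproduces the input to floating-point accuracy.
#'
#' @param img an [Image2D-class].
#' @param p prime block size (>= 3); the evaluation grids use 3, 5, 7, 11,
#'   13 and 31.
#' @param filter a [WaveletFilter-class] or name.
#' @param t detail-coefficient threshold.
#' @param levels wavelet depth along projections.
#' @return the processed [Image2D-class].
#' @export
ridgeletProcess <- function(img, p = 13L, filter = "haar", t = 0,
                            levels = 3L) {
  stopifnot(is(img, "Image2D"))
  p <- as.integer(p)
  if (!isPrime(p) || p < 3L) {
    stop("block size p must be a prime >= 3", call. = FALSE)
  }
  stopUnlessScalarGe0(t)
  X <- padToBlocks(img@pixels, p)
  out <- X
  for (bi in seq_len(nrow(X) %/% p)) {
    ri <- (bi - 1L) * p + seq_len(p)
    for (bj in seq_len(ncol(X) %/% p)) {
      cj <- (bj - 1L) * p + seq_len(p)
      blk <- X[ri, cj]
      out[ri, cj] <- ifrit(thresholdRidgelet(frit(blk, filter, levels), t))
    }
  }
  Image2D(out[seq_len(nrow(img@pixels)), seq_len(ncol(img@pixels))],
          img@pixelSizeMm, img@intensityMax)
}

#' Ridgelet denoising
#'
#' Convenience wrapper over [ridgeletProcess()] named for symmetry with the
#' wavelet and curvelet denoisers. The 1/sqrt(p) Radon normalisation keeps
#' white noise at its pixel-domain standard deviation in the coefficient
#' domain, so \code{t = 3 * sigma} is a standard choice.
#'
#' @inheritParams ridgeletProcess
#' @export
denoiseRidgelet <- function(img, p = 13L, filter = "haar", t = 0,
                            levels = 3L) {
  ridgeletProcess(img, p = p, filter = filter, t = t, levels = levels)
}
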