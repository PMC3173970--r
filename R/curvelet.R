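# Wrapping-based fast discrete curvelet transform.
#
# Construction: Meyer-type radial and angular windows on the centred
# frequency grid form wedge masks U_{j,l} whose squares sum to exactly one
# at every frequency sample, so analysis (window, wrap, inverse FFT per
# wedge) and its adjoint give a tight frame with exact reconstruction.

# Smooth step: nu rises from 0 at 0 to 1 at 1 with vanishing derivatives at
# both ends; nu(t) + nu(1 - t) = 1, which is what makes squared windows
# complementary across transitions.
meyerNu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  # clamp: the polynomial overshoots [0, 1] by ~1e-15 near t = 1, which
  # would push cos(pi/2 nu) below zero
  pmin(pmax(t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3), 0), 1)
}

# Low-pass profile: 1 below a, smooth cosine fall to 0 at b.
meyerLow <- function(r, a, b) {
  out <- numeric(length(r))
  out[r <= a] <- 1
  tr <- r > a & r < b
  out[tr] <- cos(pi / 2 * meyerNu((r[tr] - a) / (b - a)))
  out
}

#' Radial curvelet window
#'
#' The dyadic radial window W with \code{sum_j W(2^j r)^2 = 1} for every
#' r > 0 (in particular on (3/4, 3/2)): the square root of the difference of
#' two Meyer low-pass profiles an octave apart (transition on [1/2, 1]).
#'
#' @param r radius values (>= 0).
#' @return window values in [0, 1].
#' @export
radialWindow <- function(r) {
  sqrt(pmax(meyerLow(r / 2, 0.5, 1)^2 - meyerLow(r, 0.5, 1)^2, 0))
}

#' Angular curvelet window
#'
#' Periodised smooth bump V with \code{sum_l V(t - l)^2 = 1} for every t (in
#' particular on (-1/2, 1/2)): flat on |t| <= 1/4 with complementary
#' sine/cosine transitions of half-width 1/4 around |t| = 1/2.
#'
#' @param t angular offset in units of the wedge spacing.
#' @param overlap transition half-width as a fraction of the spacing.
#' @return window values in [0, 1].
#' @export
angularWindow <- function(t, overlap = 0.25) {
  a <- abs(t)
  out <- numeric(length(t))
  out[a <= 0.5 - overlap] <- 1
  tr <- a > 0.5 - overlap & a < 0.5 + overlap
  out[tr] <- cos(pi / 2 * meyerNu((a[tr] - (0.5 - overlap)) / (2 * overlap)))
  out
}

#' Plan a curvelet system
#'
#' Chooses the scale count and per-scale angle counts for an M x N image.
#' The coarsest scale is a single nondirectional band; the second-coarsest
#' has \code{nanglesCoarse} wedges (at least 8 and a multiple of 4; default
#' 16), and the count doubles every other scale toward fine. The default
#' depth rule \code{ceiling(log2(min(M, N))) - 4} counts the nondirectional
#' band as a level and yields 5 scales for a 512 x 512 image; override it
#' with \code{nscales}.
#'
#' Wedge masks are built lazily on first use and cached, so planning is
#' cheap for any size.
#'
#' @param M,N image dimensions (>= 32).
#' @param nscales optional scale count J >= 2.
#' @param nanglesCoarse angle count at the second-coarsest scale.
#' @return a [CurveletSystem-class].
#' @examples
#' nscales(curveletPlan(512, 512))  # 5
#' @export
curveletPlan <- function(M, N, nscales = NULL, nanglesCoarse = 16L) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 32L || N < 32L) stop("image must be at least 32 x 32", call. = FALSE)
  nanglesCoarse <- as.integer(nanglesCoarse)
  if (nanglesCoarse < 8L || nanglesCoarse %% 4L != 0L) {
    stop("angle count at the second-coarsest scale must be >= 8 and a ",
         "multiple of 4", call. = FALSE)
  }
  if (is.null(nscales) || is.na(nscales)) {
    nscales <- max(2L, as.integer(ceiling(log2(min(M, N)))) - 4L)
  }
  nscales <- as.integer(nscales)
  if (nscales < 2L) stop("nscales must be >= 2", call. = FALSE)
  if (nscales > as.integer(floor(log2(min(M, N)))) - 2L) {
    stop("image too small for the requested number of scales", call. = FALSE)
  }
  na <- c(1L, as.integer(nanglesCoarse *
               2^(floor((seq_len(nscales - 1L) - 1L) / 2))))
  new("CurveletSystem", dim = c(M, N), nscales = nscales,
      nangles = na, angularOverlap = 0.25, cache = new.env(parent = emptyenv()))
}

#' @describeIn curveletPlan number of scales of a system.
#' @param system a [CurveletSystem-class].
#' @export
nscales <- function(system) system@nscales

#' @describeIn curveletPlan angle counts per scale.
#' @export
nangles <- function(system) system@nangles

setMethod("show", "CurveletSystem", function(object) {
  cat(sprintf("CurveletSystem: %d x %d image, %d scales\n",
              object@dim[1L], object@dim[2L], object@nscales))
  cat("  bands per scale (coarse to fine):",
      paste(object@nangles, collapse = ", "), "\n")
})

# Radial breakpoints in normalised radius units (Nyquist edge = 1): the
# low-pass L_j cuts at b_j = 2^(j - J), transition over [b_j/2, b_j]; the
# finest band extends past the corner of the square spectrum.
radialCut <- function(j, J) 2^(j - J)

# Centred-grid geometry shared by all wedges of a system (cached).
systemGrid <- function(system) {
  cache <- system@cache
  if (!is.null(cache$grid)) return(cache$grid)
  M <- system@dim[1L]; N <- system@dim[2L]
  gr <- (seq_len(M) - 1L) - floor(M / 2)       # centred integer frequencies
  gc <- (seq_len(N) - 1L) - floor(N / 2)
  YR <- matrix(gr / (M / 2), M, N)             # normalised, rows
  XC <- matrix(gc / (N / 2), M, N, byrow = TRUE)
  cache$grid <- list(rho = sqrt(XC^2 + YR^2), theta = atan2(YR, XC),
                     rowCoord = gr, colCoord = gc)
  cache$grid
}

# Full-grid mask of one wedge, centred layout.
wedgeMaskFull <- function(system, j, l) {
  g <- systemGrid(system)
  J <- system@nscales
  rho <- g$rho
  Lj <- function(jj) meyerLow(rho, radialCut(jj, J) / 2, radialCut(jj, J))
  radial <- if (j == 1L) {
    Lj(1L)
  } else if (j == J) {
    sqrt(pmax(1 - Lj(J - 1L)^2, 0))
  } else {
    sqrt(pmax(Lj(j)^2 - Lj(j - 1L)^2, 0))
  }
  if (j == 1L) return(matrix(radial, nrow(rho), ncol(rho)))
  nAng <- system@nangles[j]
  delta <- 2 * pi / nAng
  centre <- -pi + (l - 0.5) * delta
  d <- (g$theta - centre + pi) %% (2 * pi) - pi   # wrapped angular distance
  matrix(radial * angularWindow(d / delta, system@angularOverlap),
         nrow(rho), ncol(rho))
}

#' Frequency wedge of a curvelet system
#'
#' Builds (and caches) the sampled wedge mask U_{j,l}: the product of the
#' scale-j radial annulus window and the orientation-l angular window,
#' cropped to its bounding rectangle on the centred frequency grid. Masks
#' are real, lie in [0, 1] and over all (j, l) their squares sum to one at
#' every frequency sample.
#'
#' @param system a [CurveletSystem-class].
#' @param j scale index (1 = coarsest, nondirectional).
#' @param l orientation index within scale j.
#' @return a [FrequencyTile-class].
#' @export
wedgeWindow <- function(system, j, l = 1L) {
  j <- as.integer(j); l <- as.integer(l)
  if (j < 1L || j > system@nscales) stop("invalid scale index", call. = FALSE)
  if (l < 1L || l > system@nangles[j]) {
    stop("invalid orientation index", call. = FALSE)
  }
  key <- sprintf("tile_%d_%d", j, l)
  cache <- system@cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  full <- wedgeMaskFull(system, j, l)
  nz <- which(full != 0, arr.ind = TRUE)
  r0 <- min(nz[, 1L]); r1 <- max(nz[, 1L])
  c0 <- min(nz[, 2L]); c1 <- max(nz[, 2L])
  g <- systemGrid(system)
  tile <- new("FrequencyTile", scale = j, angle = l,
              mask = full[r0:r1, c0:c1, drop = FALSE],
              rowOffset = as.integer(g$rowCoord[r0]),
              colOffset = as.integer(g$colCoord[c0]))
  cache[[key]] <- tile
  tile
}

setMethod("show", "FrequencyTile", function(object) {
  cat(sprintf("FrequencyTile: scale %d, angle %d, rectangle %d x %d\n",
              object@scale, object@angle,
              nrow(object@mask), ncol(object@mask)))
})

# All tiles of a system.
systemTiles <- function(system) {
  lapply(seq_len(system@nscales), function(j) {
    lapply(seq_len(system@nangles[j]), function(l) wedgeWindow(system, j, l))
  })
}

# Row/column index ranges of a tile within the centred full-grid layout.
tileIndexRanges <- function(system, tile) {
  M <- system@dim[1L]; N <- system@dim[2L]
  r0 <- tile@rowOffset + floor(M / 2) + 1L
  c0 <- tile@colOffset + floor(N / 2) + 1L
  list(rows = r0:(r0 + nrow(tile@mask) - 1L),
       cols = c0:(c0 + ncol(tile@mask) - 1L))
}

#' Forward fast discrete curvelet transform (wrapping)
#'
#' The four-step wrapping algorithm: (1) 2D FFT of the image; (2) multiply
#' the spectrum by each wedge window U_{j,l}; (3) wrap the supported data
#' into the wedge's rectangle by periodic index folding (the rectangle is
#' sized to the wedge support, so the folding is collision-free); (4)
#' inverse 2D FFT per wedge. All FFTs are unitary, so total coefficient
#' energy equals image energy exactly (tight frame).
#'
#' @param img an [Image2D-class] (or matrix) matching the system's shape.
#' @param system a [CurveletSystem-class]; planned automatically if NULL.
#' @return a [CurveletCoefficients-class].
#' @export
fdctForward <- function(img, system = NULL) {
  if (is.matrix(img)) img <- Image2D(img)
  stopifnot(is(img, "Image2D"))
  if (is.null(system)) {
    system <- curveletPlan(nrow(img@pixels), ncol(img@pixels))
  }
  if (!identical(dim(img@pixels), system@dim)) {
    stop("image shape does not match the curvelet system", call. = FALSE)
  }
  Fs <- fftshift2(fft2u(img@pixels))
  tiles <- systemTiles(system)
  bands <- lapply(seq_len(system@nscales), function(j) {
    lapply(seq_len(system@nangles[j]), function(l) {
      tile <- tiles[[j]][[l]]
      idx <- tileIndexRanges(system, tile)
      ifft2u(tile@mask * Fs[idx$rows, idx$cols, drop = FALSE])
    })
  })
  new("CurveletCoefficients", system = system, bands = bands,
      pixelSizeMm = img@pixelSizeMm, intensityMax = img@intensityMax)
}

#' Inverse fast discrete curvelet transform
#'
#' The adjoint of [fdctForward()], which is an exact inverse because the
#' wedge masks form a frequency partition of unity: per band, forward FFT of
#' the coefficients, unwrap onto the wedge support, multiply by the (real)
#' mask, accumulate over bands, and inverse FFT. Real inputs reconstruct to
#' real outputs; the floating-point imaginary residue is checked and
#' dropped.
#'
#' @param coeffs a [CurveletCoefficients-class].
#' @return the reconstructed [Image2D-class].
#' @export
fdctInverse <- function(coeffs) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  validObject(coeffs)
  system <- coeffs@system
  M <- system@dim[1L]; N <- system@dim[2L]
  Fs <- matrix(0 + 0i, M, N)
  for (j in seq_len(system@nscales)) {
    for (l in seq_len(system@nangles[j])) {
      tile <- wedgeWindow(system, j, l)
      band <- coeffs@bands[[j]][[l]]
      if (!identical(dim(band), dim(tile@mask))) {
        stop("coefficient band shape does not match its wedge", call. = FALSE)
      }
      idx <- tileIndexRanges(system, tile)
      Fs[idx$rows, idx$cols] <- Fs[idx$rows, idx$cols] +
        tile@mask * fft2u(band)
    }
  }
  # enforce conjugate symmetry so real inputs reconstruct to real outputs
  # (coefficient-domain edits such as thresholding need not preserve the
  # Hermitian pairing of opposite wedges exactly)
  G <- ifftshift2(Fs)
  rev1 <- c(1L, M:2L); rev2 <- c(1L, N:2L)
  G <- (G + Conj(G[rev1, rev2])) / 2
  x <- ifft2u(G)
  relIm <- max(abs(Im(x))) / max(max(abs(Re(x))), .Machine$double.eps)
  if (relIm > 1e-9) {
    warning("large imaginary residue in curvelet reconstruction: ",
            format(relIm))
  }
  Image2D(Re(x), coeffs@pixelSizeMm, coeffs@intensityMax)
}

#' Total curvelet coefficient energy
#'
#' @param coeffs a [CurveletCoefficients-class].
#' @return sum of squared coefficient moduli; equals the image energy.
#' @export
curveletEnergy <- function(coeffs) {
  sum(vapply(coeffs@bands, function(scale) {
    sum(vapply(scale, function(b) sum(Mod(b)^2), numeric(1)))
  }, numeric(1)))
}

# Per-band white-noise gain: unit-variance pixel noise yields coefficient
# standard deviation sqrt(sum(U^2) / (R1 R2)) in band (j, l).
bandNoiseGain <- function(system, j, l) {
  tile <- wedgeWindow(system, j, l)
  sqrt(sum(tile@mask^2) / length(tile@mask))
}

#' Hard-threshold curvelet coefficients
#'
#' Zeroes coefficients with modulus below the threshold in every band except
#' the coarsest (thresholding the nondirectional DC band would destroy the
#' foreground). With \code{perBandNoise = TRUE} the threshold for band
#' (j, l) is scaled by that band's white-noise gain
#' \code{sqrt(sum(U^2) / (R1 R2))}, so a single \code{t = k * sigma} treats
#' all orientations equitably.
#'
#' @param coeffs a [CurveletCoefficients-class].
#' @param t threshold, >= 0.
#' @param perBandNoise scale the threshold by each band's noise gain.
#' @export
thresholdCurvelet <- function(coeffs, t, perBandNoise = FALSE) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  stopUnlessScalarGe0(t)
  if (t == 0) return(coeffs)
  system <- coeffs@system
  for (j in seq_len(system@nscales)[-1L]) {
    for (l in seq_len(system@nangles[j])) {
      tj <- if (perBandNoise) t * bandNoiseGain(system, j, l) else t
      b <- coeffs@bands[[j]][[l]]
      b[Mod(b) < tj] <- 0 + 0i
      coeffs@bands[[j]][[l]] <- b
    }
  }
  coeffs
}

#' Curvelet denoising by coefficient hard thresholding
#'
#' Forward transform, hard threshold of all directional bands, inverse
#' transform. For Gaussian noise of known standard deviation sigma,
#' \code{t = 3 * sigma} with \code{perBandNoise = TRUE} is a standard
#' choice.
#'
#' @inheritParams fdctForward
#' @inheritParams thresholdCurvelet
#' @export
denoiseCurvelet <- function(img, system = NULL, t = 0, perBandNoise = TRUE) {
  if (is.matrix(img)) img <- Image2D(img)
  if (is.null(system)) {
    system <- curveletPlan(nrow(img@pixels), ncol(img@pixels))
  }
  fdctInverse(thresholdCurvelet(fdctForward(img, system), t, perBandNoise))
}

#' Mosaic display of curvelet coefficients
#'
#' Lays the coefficient moduli out as a single image with the coarsest
#' (nondirectional) band at the centre and one concentric annulus of angular
#' panels per finer scale: each scale's bands are split into four groups
#' placed above, to the right of, below and to the left of the previous
#' canvas. Panels are disjoint and none is dropped, so the mosaic has at
#' least as many pixels as there are coefficients.
#'
#' @param coeffs a [CurveletCoefficients-class].
#' @return an [Image2D-class] mosaic.
#' @seealso [coefficientLayout()] for the panel geometry.
#' @export
coefficientDisplay <- function(coeffs) {
  lay <- coefficientLayout(coeffs@system)
  canvas <- matrix(0, lay$canvasDim[1L], lay$canvasDim[2L])
  for (i in seq_len(nrow(lay$panels))) {
    p <- lay$panels[i, ]
    band <- Mod(coeffs@bands[[p$scale]][[p$angle]])
    canvas[p$row0 + seq_len(p$rows) - 1L, p$col0 + seq_len(p$cols) - 1L] <-
      band
  }
  Image2D(canvas, pixelSizeMm = 1, intensityMax = coeffs@intensityMax)
}

#' Panel geometry of the coefficient mosaic
#'
#' @param system a [CurveletSystem-class].
#' @return list with \code{canvasDim} and a data frame \code{panels}
#'   (scale, angle, row0, col0, rows, cols) of disjoint panel placements.
#' @export
coefficientLayout <- function(system) {
  tiles <- systemTiles(system)
  dims <- lapply(tiles, function(scale) {
    t(vapply(scale, function(tl) dim(tl@mask), integer(2)))
  })
  # start with the coarse band
  panels <- data.frame(scale = 1L, angle = 1L, row0 = 1L, col0 = 1L,
                       rows = dims[[1L]][1L, 1L], cols = dims[[1L]][1L, 2L])
  H <- panels$rows; W <- panels$cols
  for (j in seq_len(system@nscales)[-1L]) {
    d <- dims[[j]]
    n <- nrow(d)
    q <- n %/% 4L
    groups <- split(seq_len(n), rep(1:4, each = q))
    strip <- function(idx, horizontal) {
      if (horizontal) {
        list(thick = max(d[idx, 1L]), len = sum(d[idx, 2L]))
      } else {
        list(thick = max(d[idx, 2L]), len = sum(d[idx, 1L]))
      }
    }
    top <- strip(groups[[1L]], TRUE); right <- strip(groups[[2L]], FALSE)
    bottom <- strip(groups[[3L]], TRUE); left <- strip(groups[[4L]], FALSE)
    newW <- max(W + left$thick + right$thick, top$len, bottom$len)
    newH <- top$thick + bottom$thick +
      max(H, right$len, left$len)
    midH <- max(H, right$len, left$len)
    # reposition existing panels: previous canvas goes centre-left-of-centre
    rowShift <- top$thick + (midH - H) %/% 2L
    colShift <- left$thick + (newW - left$thick - right$thick - W) %/% 2L
    panels$row0 <- panels$row0 + rowShift
    panels$col0 <- panels$col0 + colShift
    addPanel <- function(jj, ll, r0, c0) {
      panels[nrow(panels) + 1L, ] <<- list(jj, ll, as.integer(r0),
                                           as.integer(c0),
                                           dims[[jj]][ll, 1L],
                                           dims[[jj]][ll, 2L])
    }
    c0 <- 1L
    for (ll in groups[[1L]]) {                 # top strip, left to right
      addPanel(j, ll, 1L, c0); c0 <- c0 + d[ll, 2L]
    }
    r0 <- top$thick + 1L
    for (ll in groups[[2L]]) {                 # right strip, top to bottom
      addPanel(j, ll, r0, newW - right$thick + 1L); r0 <- r0 + d[ll, 1L]
    }
    c0 <- 1L
    for (ll in groups[[3L]]) {                 # bottom strip
      addPanel(j, ll, top$thick + midH + 1L, c0); c0 <- c0 + d[ll, 2L]
    }
    r0 <- top$thick + 1L
    for (ll in groups[[4L]]) {                 # left strip
      addPanel(j, ll, r0, 1L); r0 <- r0 + d[ll, 1L]
    }
    H <- newH; W <- newW
  }
  list(canvasDim = c(H, W), panels = panels)
}

setMethod("show", "CurveletCoefficients", function(object) {
  sys <- object@system
  cat(sprintf("CurveletCoefficients: %d scales on a %d x %d image\n",
              sys@nscales, sys@dim[1L], sys@dim[2L]))
  cat(sprintf("  bands per scale: %s; total energy %.6g\n",
              paste(sys@nangles, collapse = ", "), curveletEnergy(object)))
})
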