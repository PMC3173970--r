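# Small shared helpers. Internal.

isPrime <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) return(FALSE)
  if (n < 4L) return(TRUE)
  if (n %% 2L == 0L) return(FALSE)
  k <- 3L
  while (k * k <= n) {
    if (n %% k == 0L) return(FALSE)
    k <- k + 2L
  }
  TRUE
}

# Physical coordinates (mm) of disc centres, x along columns, y along rows,
# origin at the grid centre; inserts angularly equispaced on the ring.
sphereCentres <- function(spec) {
  d <- spec@sphereDiametersMm
  if (!length(d)) return(matrix(numeric(0), 0L, 2L))
  ang <- 2 * pi * (seq_along(d) - 1L) / length(d)
  cbind(x = spec@sphereRingRadiusMm * cos(ang),
        y = spec@sphereRingRadiusMm * sin(ang))
}

# Move the zero frequency to position floor(n/2)+1 (centred layout), and back.
fftshift2 <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c((floor(m / 2) + 1L):m, seq_len(floor(m / 2))),
    c((floor(n / 2) + 1L):n, seq_len(floor(n / 2))), drop = FALSE]
}

ifftshift2 <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c((ceiling(m / 2) + 1L):m, seq_len(ceiling(m / 2))),
    c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2))), drop = FALSE]
}

# Unitary 2D FFT pair.
fft2u <- function(x) stats::fft(x) / sqrt(length(x))
ifft2u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

stopUnlessScalarGe0 <- function(t, what = "t") {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop(what, " must be a single number >= 0", call. = FALSE)
  }
}
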