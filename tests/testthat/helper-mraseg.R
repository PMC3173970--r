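# Shared fixtures, built in code.

randomImage <- function(n, seed = 1, pixelSizeMm = 1) {
  set.seed(seed)
  Image2D(matrix(rnorm(n * n), n, n), pixelSizeMm = pixelSizeMm)
}

# Small phantom spec rendered quickly (32 x 32), two inserts.
tinyPhantomSpec <- function() {
  PhantomSpec(grid = c(32L, 32L), pixelSizeMm = 10,
              cavitySemiAxesMm = c(140, 110),
              sphereDiametersMm = c(30, 40), sphereRingRadiusMm = 60)
}

# The reference insert diameters.
defaultDiameters <- c(10, 13, 17, 22, 28, 37)

# Independent brute-force enumeration of the finite-geometry lines: for
# direction k < p the set {(i, j) : j = k i + l mod p}, and for direction p
# the rows of constant first index. Oracle for frat().
enumerateLines <- function(p) {
  lines <- list()
  for (k in 0:(p - 1)) {
    for (l in 0:(p - 1)) {
      lines[[sprintf("%d_%d", k, l)]] <-
        cbind(i = 0:(p - 1), j = (k * (0:(p - 1)) + l) %% p)
    }
  }
  for (l in 0:(p - 1)) {
    lines[[sprintf("%d_%d", p, l)]] <- cbind(i = l, j = 0:(p - 1))
  }
  lines
}

bruteFrat <- function(block) {
  p <- nrow(block)
  lines <- enumerateLines(p)
  r <- matrix(0, p + 1, p)
  for (k in 0:p) {
    for (l in 0:(p - 1)) {
      pts <- lines[[sprintf("%d_%d", k, l)]]
      r[k + 1, l + 1] <- sum(block[cbind(pts[, "i"] + 1, pts[, "j"] + 1)])
    }
  }
  r / sqrt(p)
}

# Maximum deviation of sum_{j,l} U_{j,l}^2 from 1 over the full grid.
partitionDeviation <- function(sys) {
  M <- sys@dim[1]; N <- sys@dim[2]
  tot <- matrix(0, M, N)
  for (j in seq_len(nscales(sys))) {
    for (l in seq_len(nangles(sys)[j])) {
      tile <- wedgeWindow(sys, j, l)
      idx <- mraseg:::tileIndexRanges(sys, tile)
      tot[idx$rows, idx$cols] <- tot[idx$rows, idx$cols] + tile@mask^2
    }
  }
  max(abs(tot - 1))
}

# High-resolution rendering of the default phantom used by the pipeline
# tests (512 x 512 at 4.6875 / 4 mm).
phantom512 <- local({
  img <- NULL
  function() {
    if (is.null(img)) {
      img <<- generatePhantom(PhantomSpec(grid = c(512L, 512L),
                                          pixelSizeMm = 4.6875 / 4))
    }
    img
  }
})
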