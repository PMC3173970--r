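# Coefficient containers: a directory with a JSON manifest describing the
# transform conventions plus one portable little-endian binary array file per
# subband (complex bands store interleaved re/im). Round trips are bit-exact.

writeArrayBin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.complex(x)) {
    v <- as.vector(rbind(as.vector(Re(x)), as.vector(Im(x))))
  } else {
    v <- as.vector(x)
  }
  writeBin(as.numeric(v), con, size = 8L, endian = "little")
}

readArrayBin <- function(path, dim, complex = FALSE) {
  n <- prod(dim) * (if (complex) 2L else 1L)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (complex) v <- complex(real = v[c(TRUE, FALSE)],
                            imaginary = v[c(FALSE, TRUE)])
  array(v, dim = dim)
}

#' Write and read a wavelet pyramid container
#'
#' @param pyr a [WaveletPyramid-class].
#' @param dir directory to create.
#' @return \code{readWaveletPyramid} returns the restored pyramid,
#'   bit-exact.
#' @export
writeWaveletPyramid <- function(pyr, dir) {
  stopifnot(is(pyr, "WaveletPyramid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    container = "wavelet-pyramid", version = 1L,
    filter = pyr@filterName, levels = pyr@levels,
    originalDim = pyr@originalDim,
    pixelSizeMm = pyr@pixelSizeMm, intensityMax = pyr@intensityMax,
    conventions = list(boundary = "periodic",
                       subbandOrder = c("LL", "LH", "HL", "HH"),
                       indexing = "a(n) = sum_i l(i) x(2n - i mod N)"),
    subbandDims = lapply(seq_len(pyr@levels), function(j) {
      lapply(pyr@details[[j]], dim)
    }),
    approxDim = dim(pyr@approx)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_len(pyr@levels)) {
    for (b in c("LH", "HL", "HH")) {
      writeArrayBin(pyr@details[[j]][[b]],
                    file.path(dir, sprintf("level%d_%s.bin", j, b)))
    }
  }
  writeArrayBin(pyr@approx, file.path(dir, "approx.bin"))
  invisible(dir)
}

#' @rdname writeWaveletPyramid
#' @param dir container directory.
#' @export
readWaveletPyramid <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(man$container, "wavelet-pyramid")) {
    stop("not a wavelet pyramid container", call. = FALSE)
  }
  details <- lapply(seq_len(man$levels), function(j) {
    lapply(stats::setNames(c("LH", "HL", "HH"), c("LH", "HL", "HH")),
           function(b) {
             readArrayBin(file.path(dir, sprintf("level%d_%s.bin", j, b)),
                          unlist(man$subbandDims[[j]][[b]]))
           })
  })
  new("WaveletPyramid", filterName = man$filter,
      levels = as.integer(man$levels), details = details,
      approx = readArrayBin(file.path(dir, "approx.bin"),
                            unlist(man$approxDim)),
      originalDim = as.integer(man$originalDim),
      pixelSizeMm = man$pixelSizeMm, intensityMax = man$intensityMax)
}

#' Write and read a curvelet coefficient container
#'
#' @param coeffs a [CurveletCoefficients-class].
#' @param dir directory to create.
#' @export
writeCurveletCoefficients <- function(coeffs, dir) {
  stopifnot(is(coeffs, "CurveletCoefficients"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sys <- coeffs@system
  manifest <- list(
    container = "curvelet-coefficients", version = 1L,
    dim = sys@dim, nscales = sys@nscales, nangles = sys@nangles,
    angularOverlap = sys@angularOverlap,
    pixelSizeMm = coeffs@pixelSizeMm, intensityMax = coeffs@intensityMax,
    conventions = list(
      windows = "Meyer-type, smooth-step polynomial t^4(35-84t+70t^2-20t^3)",
      origin = "frequency DC at array centre",
      wrapping = "periodic folding into the wedge support bounding box",
      fft = "unitary"),
    bandDims = lapply(seq_len(sys@nscales), function(j) {
      lapply(seq_len(sys@nangles[j]), function(l) {
        dim(coeffs@bands[[j]][[l]])
      })
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_len(sys@nscales)) {
    for (l in seq_len(sys@nangles[j])) {
      writeArrayBin(coeffs@bands[[j]][[l]],
                    file.path(dir, sprintf("band_s%d_a%d.bin", j, l)))
    }
  }
  invisible(dir)
}

#' @rdname writeCurveletCoefficients
#' @export
readCurveletCoefficients <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(man$container, "curvelet-coefficients")) {
    stop("not a curvelet coefficient container", call. = FALSE)
  }
  dims <- as.integer(unlist(man$dim))
  nang <- as.integer(unlist(man$nangles))
  sys <- curveletPlan(dims[1L], dims[2L], nscales = man$nscales,
                      nanglesCoarse = nang[2L])
  bands <- lapply(seq_len(sys@nscales), function(j) {
    lapply(seq_len(sys@nangles[j]), function(l) {
      readArrayBin(file.path(dir, sprintf("band_s%d_a%d.bin", j, l)),
                   unlist(man$bandDims[[j]][[l]]), complex = TRUE)
    })
  })
  new("CurveletCoefficients", system = sys, bands = bands,
      pixelSizeMm = man$pixelSizeMm, intensityMax = man$intensityMax)
}

#' Write and read a per-block ridgelet coefficient container
#'
#' Stores the (p+1) x p coefficient array of each direction-wise wavelet
#' decomposition for one block, with the transform conventions in the
#' manifest.
#'
#' @param coeffs a [RidgeletCoefficients-class].
#' @param dir directory to create.
#' @export
writeRidgeletCoefficients <- function(coeffs, dir) {
  stopifnot(is(coeffs, "RidgeletCoefficients"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    container = "ridgelet-coefficients", version = 1L,
    p = coeffs@p, filter = coeffs@filterName, levels = coeffs@levels,
    meanOffset = coeffs@meanOffset,
    conventions = list(radonNormalization = "1/sqrt(p)",
                       padding = "symmetric edge replication",
                       waveletBoundary = "periodic, odd tail carried"),
    rowLengths = lapply(coeffs@rows, function(r) r$lengths)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(coeffs@rows)) {
    dec <- coeffs@rows[[k]]
    writeArrayBin(c(unlist(dec$details), dec$approx),
                  file.path(dir, sprintf("direction%d.bin", k)))
  }
  invisible(dir)
}

#' @rdname writeRidgeletCoefficients
#' @export
readRidgeletCoefficients <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(man$container, "ridgelet-coefficients")) {
    stop("not a ridgelet coefficient container", call. = FALSE)
  }
  p <- as.integer(man$p)
  rows <- lapply(seq_len(p + 1L), function(k) {
    v <- as.vector(readArrayBin(file.path(dir, sprintf("direction%d.bin", k)),
                                p))
    lengths <- as.integer(unlist(man$rowLengths[[k]]))
    details <- list()
    pos <- 0L
    for (n in lengths) {
      nd <- n %/% 2L
      details[[length(details) + 1L]] <- v[pos + seq_len(nd)]
      pos <- pos + nd
    }
    list(filterName = man$filter, levels = as.integer(man$levels),
         lengths = lengths, details = details,
         approx = v[(pos + 1L):p])
  })
  new("RidgeletCoefficients", p = p, filterName = man$filter,
      levels = as.integer(man$levels), rows = rows,
      meanOffset = man$meanOffset)
}
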