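#' @name wavelet
#' @title Wavelet multiresolution analysis for fNIRS denoising
#'
#' @description
#' Physiological noise in continuous-wave fNIRS (cardiac pulsation near
#' 0.8 Hz, respiration near 0.2 Hz, Mayer waves near 0.1 Hz and very-low
#' frequency oscillations near 0.03 Hz) is removed by decomposing each
#' channel with a discrete wavelet transform into per-level detail
#' components and re-assembling only the details whose dyadic bands cover
#' the hemodynamic response.  At a sampling rate of 25.7 Hz the details
#' d8 and d9 of a 10-level Daubechies-5 decomposition jointly occupy
#' roughly 0.025 to 0.1 Hz, so `band_reconstruct(decomp, c(8, 9))`
#' implements the band-pass used throughout this package.
#'
#' The transform is the standard periodized orthogonal DWT.  Signals whose
#' length is not a multiple of `2^levels` are extended periodically up to
#' the next multiple before analysis and every reconstructed component is
#' cropped back, so the additive identity
#' `approximation + sum(details) == signal` holds exactly (to floating
#' point) for arbitrary lengths.
NULL

# Orthonormal Daubechies scaling (low-pass) filters, sum = sqrt(2).
# Coefficients from the standard published tables.
.wavelet_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278),
  db5 = c(0.160102397974125, 0.6038292697974729, 0.7243085284385744,
          0.13842814590110342, -0.24229488706619015, -0.03224486958502952,
          0.07757149384006515, -0.006241490213011705,
          -0.012580751999015526, 0.003335725285001549)
)

.scaling_filter <- function(mother) {
  h <- .wavelet_filters[[tolower(mother)]]
  if (is.null(h)) {
    stop("unknown or non-orthogonal wavelet '", mother, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  h
}

# Quadrature-mirror high-pass from the scaling filter.
.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

#' Wavelet configuration
#'
#' @param mother Orthogonal Daubechies family name; default `"db5"`.
#' @param levels Decomposition depth J; default 10.
#' @param keep_details Detail levels summed by [band_reconstruct()] when
#'   denoising; default `c(8, 9)`.
#' @param boundary_mode Extension rule; only `"periodic"` is implemented.
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(mother = "db5", levels = 10L,
                           keep_details = c(8L, 9L),
                           boundary_mode = "periodic") {
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  keep_details <- as.integer(keep_details)
  if (length(keep_details) &&
      (any(keep_details < 1L) || any(keep_details > levels))) {
    stop("keep_details must lie in 1..levels", call. = FALSE)
  }
  if (!identical(boundary_mode, "periodic")) {
    stop("only boundary_mode = 'periodic' is implemented", call. = FALSE)
  }
  .scaling_filter(mother)  # validates the name
  structure(list(mother = mother, levels = levels,
                 keep_details = keep_details,
                 boundary_mode = boundary_mode),
            class = "wavelet_config")
}

# One periodized analysis step on the columns of x (nrow(x) even).
# Returns list(a, d), each nrow(x)/2 rows.
.dwt_step <- function(x, h, g) {
  n <- nrow(x)
  n2 <- n %/% 2L
  a <- matrix(0, n2, ncol(x))
  d <- matrix(0, n2, ncol(x))
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    xs <- x[idx, , drop = FALSE]
    a <- a + h[m] * xs
    d <- d + g[m] * xs
  }
  list(a = a, d = d)
}

# Inverse of .dwt_step (transpose of the orthogonal analysis operator).
.idwt_step <- function(a, d, h, g) {
  n2 <- nrow(a)
  n <- 2L * n2
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx, ] <- x[idx, ] + h[m] * a + g[m] * d
  }
  x
}

# Full periodized pyramid on a matrix whose row count is a multiple of
# 2^levels.  Returns list(approx = matrix, details = list of matrices).
.dwt_pyramid <- function(x, h, g, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, h, g)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

# Inverse pyramid from approximation + detail coefficient matrices.
.idwt_pyramid <- function(approx, details, h, g) {
  a <- approx
  for (j in rev(seq_along(details))) {
    a <- .idwt_step(a, details[[j]], h, g)
  }
  a
}

.zero_like <- function(m) matrix(0, nrow(m), ncol(m))

# Matrix MRA shared by the vector API and the record-level denoiser.
# x: numeric matrix (time x channel).  Returns list(approximation =
# matrix n x C, details = list of J matrices n x C).
.mra_matrix <- function(x, config) {
  n <- nrow(x)
  J <- config$levels
  min_n <- 2L^J
  if (n < min_n) {
    stop("signal of length ", n, " is too short for a ", J,
         "-level decomposition; at least ", min_n, " samples are required",
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop("signal contains non-finite values",
                               call. = FALSE)
  h <- .scaling_filter(config$mother)
  g <- .qmf(h)
  n_pad <- as.integer(ceiling(n / min_n) * min_n)
  xp <- if (n_pad > n) rbind(x, x[seq_len(n_pad - n), , drop = FALSE]) else x
  pyr <- .dwt_pyramid(xp, h, g, J)
  zero_details <- lapply(pyr$details, .zero_like)
  comp <- function(approx, details) {
    .idwt_pyramid(approx, details, h, g)[seq_len(n), , drop = FALSE]
  }
  details_out <- vector("list", J)
  for (j in seq_len(J)) {
    dj <- zero_details
    dj[[j]] <- pyr$details[[j]]
    details_out[[j]] <- comp(.zero_like(pyr$approx), dj)
  }
  approx_out <- comp(pyr$approx, zero_details)
  list(approximation = approx_out, details = details_out)
}

#' Multiresolution decomposition of a signal
#'
#' Decomposes `signal` into a coarse approximation `a_J` plus per-level
#' detail components `d_1 ... d_J`, each reconstructed to the full signal
#' length, such that `approximation + Reduce("+", details)` reproduces the
#' input (additive perfect reconstruction).
#'
#' @param signal Numeric vector, length at least `2^config$levels`.
#' @param config A [wavelet_config()].
#' @return An `mra_decomposition` with elements `approximation` (numeric
#'   vector), `details` (list of numeric vectors, level 1 = finest),
#'   `config`, and `n`.
#' @examples
#' x <- sin(2 * pi * 0.05 * (0:2047) / 25.7)
#' dec <- mra_decompose(x, wavelet_config())
#' max(abs(dec$approximation + Reduce(`+`, dec$details) - x))
#' @export
mra_decompose <- function(signal, config = wavelet_config()) {
  stopifnot(is.numeric(signal))
  res <- .mra_matrix(matrix(signal, ncol = 1L), config)
  structure(list(approximation = drop(res$approximation),
                 details = lapply(res$details, drop),
                 config = config, n = length(signal)),
            class = "mra_decomposition")
}

#' Band-limited reconstruction from an MRA decomposition
#'
#' Sums the requested detail components; with `keep_details = c(8, 9)` at
#' 25.7 Hz this retains roughly the 0.025-0.1 Hz band where the task-evoked
#' hemodynamic response lives and suppresses cardiac, respiratory and
#' high-frequency noise.
#'
#' @param decomp An [mra_decompose()] result.
#' @param keep_details Integer levels to keep; may be empty (zero signal).
#' @param include_approximation Also add the approximation component
#'   (keeping everything returns the original signal).
#' @return Numeric vector of the same length as the decomposed signal.
#' @export
band_reconstruct <- function(decomp, keep_details = decomp$config$keep_details,
                             include_approximation = FALSE) {
  stopifnot(inherits(decomp, "mra_decomposition"))
  keep_details <- as.integer(keep_details)
  J <- length(decomp$details)
  if (length(keep_details) && (any(keep_details < 1L) ||
                               any(keep_details > J))) {
    stop("requested detail level outside 1..", J, call. = FALSE)
  }
  out <- numeric(decomp$n)
  for (j in keep_details) out <- out + decomp$details[[j]]
  if (include_approximation) out <- out + decomp$approximation
  out
}

#' Nominal dyadic frequency band of a detail level
#'
#' Detail level `j` of a dyadic DWT nominally occupies
#' `(fs / 2^(j+1), fs / 2^j)` Hz.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param level Detail level (>= 1).
#' @return Numeric `c(low_hz, high_hz)`.
#' @examples
#' band_edges(25.7, 8)  # ~ (0.050, 0.100) Hz
#' @export
band_edges <- function(fs_hz, level) {
  stopifnot(fs_hz > 0, level >= 1)
  c(low_hz = fs_hz / 2^(level + 1), high_hz = fs_hz / 2^level)
}

#' Normalize a signal into the unit interval
#'
#' Subtracts the mean and rescales/offsets so the minimum maps to 0 and
#' the maximum to 1.  Order-preserving; constant input is rejected.
#'
#' @param signal Non-constant numeric vector.
#' @return Numeric vector with `min == 0`, `max == 1`.
#' @export
normalize_unit_interval <- function(signal) {
  stopifnot(is.numeric(signal), length(signal) >= 2L)
  if (any(!is.finite(signal))) stop("signal contains non-finite values",
                                    call. = FALSE)
  centred <- signal - mean(signal)
  rng <- range(centred)
  if (rng[2] == rng[1]) {
    stop("constant signal cannot be normalized to (0,1)", call. = FALSE)
  }
  (centred - rng[1]) / (rng[2] - rng[1])
}

#' Denoise a hemodynamic record
#'
#' Applies the MRA band-pass (`keep_details`, default d8+d9) to every
#' channel of the continuous recording and then normalizes each channel
#' into [0, 1].  The full-session signal is filtered before any trial
#' segmentation: a 10-level dyadic decomposition needs at least 1024
#' samples, which a single 10-s block cannot supply.
#'
#' @param record A [hemodynamic_record()].
#' @param config A [wavelet_config()].
#' @param normalize Rescale each filtered channel into [0, 1]; default TRUE.
#' @return A new `hemodynamic_record`.
#' @export
denoise_record <- function(record, config = wavelet_config(),
                           normalize = TRUE) {
  stopifnot(inherits(record, "hemodynamic_record"))
  filt <- function(mat) {
    res <- .mra_matrix(mat, config)
    out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    for (j in config$keep_details) out <- out + res$details[[j]]
    if (normalize) out <- apply(out, 2L, normalize_unit_interval)
    dimnames(out) <- dimnames(mat)
    out
  }
  hemodynamic_record(hbo = filt(record$hbo), hbr = filt(record$hbr),
                     fs_hz = record$fs_hz, layout = record$layout)
}
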