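#' Continuous hemodynamic recording
#'
#' Holds the concentration-change time series Delta[HbO] and Delta[HbR]
#' (time x channel, arbitrary concentration units such as mM.cm) together
#' with the sampling rate and the probe layout.
#'
#' @param hbo,hbr Numeric matrices of identical dimension, one column per
#'   channel in ascending channel-id order.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param layout A [channel_layout()] whose channel count matches.
#' @return A `hemodynamic_record`.
#' @export
hemodynamic_record <- function(hbo, hbr, fs_hz, layout) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr))) {
    stop("hbo and hbr must have identical dimensions", call. = FALSE)
  }
  if (ncol(hbo) < 1L) stop("record has no channels", call. = FALSE)
  if (anyNA(hbo) || anyNA(hbr) || any(!is.finite(hbo)) ||
      any(!is.finite(hbr))) {
    stop("record contains missing or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("fs_hz must be a positive scalar", call. = FALSE)
  }
  stopifnot(inherits(layout, "channel_layout"))
  if (length(layout$channel_ids) != ncol(hbo)) {
    stop("layout lists ", length(layout$channel_ids),
         " channels but the matrices have ", ncol(hbo), " columns",
         call. = FALSE)
  }
  colnames(hbo) <- paste0("hbo_ch", layout$channel_ids)
  colnames(hbr) <- paste0("hbr_ch", layout$channel_ids)
  structure(list(hbo = hbo, hbr = hbr, fs_hz = fs_hz, layout = layout),
            class = "hemodynamic_record")
}

#' @export
print.hemodynamic_record <- function(x, ...) {
  cat(sprintf("hemodynamic_record: %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs_hz, nrow(x$hbo) / x$fs_hz))
  invisible(x)
}

#' Per-wavelength optical-density recording
#'
#' Delta-OD time series for each (channel, wavelength) pair, ordered
#' channel-major (all wavelengths of channel 1, then channel 2, ...).
#'
#' @param od Numeric matrix, time x (channel x wavelength).
#' @param wavelengths_nm Numeric vector of at least two wavelengths.
#' @param fs_hz Sampling rate in Hz.
#' @param layout A [channel_layout()].
#' @return An `optical_density_record`.
#' @export
optical_density_record <- function(od, wavelengths_nm, fs_hz, layout) {
  od <- as.matrix(od)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) < 2L || any(wavelengths_nm <= 0)) {
    stop("at least two positive wavelengths are required", call. = FALSE)
  }
  stopifnot(inherits(layout, "channel_layout"))
  n_ch <- length(layout$channel_ids)
  if (ncol(od) != n_ch * length(wavelengths_nm)) {
    stop("od must have channel-count x wavelength-count columns (",
         n_ch * length(wavelengths_nm), "), got ", ncol(od), call. = FALSE)
  }
  if (anyNA(od) || any(!is.finite(od))) {
    stop("od contains missing or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("fs_hz must be a positive scalar", call. = FALSE)
  }
  colnames(od) <- as.vector(t(outer(layout$channel_ids, wavelengths_nm,
                                    function(ch, wl)
                                      sprintf("od_ch%d_%gnm", ch, wl))))
  structure(list(od = od, wavelengths_nm = wavelengths_nm, fs_hz = fs_hz,
                 layout = layout),
            class = "optical_density_record")
}

#' @export
print.optical_density_record <- function(x, ...) {
  cat(sprintf("optical_density_record: %d samples x %d channels x %d wavelengths at %g Hz\n",
              nrow(x$od), length(x$layout$channel_ids),
              length(x$wavelengths_nm), x$fs_hz))
  invisible(x)
}

#' Segmented trial set
#'
#' Fixed-length task blocks stacked into a 3-D array
#' `(trial, time, column)` where the columns are the HbO channels followed
#' by the HbR channels (2N columns for N measurement channels).
#'
#' @param x Numeric 3-D array `(n_trials, M, 2N)` or list of M x 2N
#'   matrices.
#' @param labels Factor or character vector of trial labels, levels
#'   `rest`, `right`, `left`.
#' @param fs_hz Sampling rate in Hz.
#' @param block_duration_s Block length in seconds; default 10.
#' @return A `trial_set`.
#' @export
trial_set <- function(x, labels, fs_hz, block_duration_s = 10) {
  if (is.list(x)) {
    if (length(x)) {
      dims <- vapply(x, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
        stop("all trials must have identical shape", call. = FALSE)
      }
      arr <- array(0, c(length(x), dims[1, 1], dims[2, 1]))
      for (i in seq_along(x)) arr[i, , ] <- x[[i]]
      x <- arr
    } else {
      x <- array(0, c(0L, 0L, 0L))
    }
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  labels <- factor(as.character(labels), levels = task_levels())
  if (anyNA(labels) && length(labels)) {
    stop("labels must be one of ", paste(task_levels(), collapse = ", "),
         call. = FALSE)
  }
  if (dim(x)[1] != length(labels)) {
    stop("number of trials and labels differ", call. = FALSE)
  }
  M <- round(block_duration_s * fs_hz)
  if (dim(x)[1] > 0L && dim(x)[2] != M) {
    stop("trial length ", dim(x)[2], " != round(block_duration_s * fs_hz) = ",
         M, call. = FALSE)
  }
  structure(list(x = x, labels = labels, fs_hz = fs_hz,
                 block_duration_s = block_duration_s),
            class = "trial_set")
}

#' Task label levels used throughout the package
#' @return `c("rest", "right", "left")`
#' @export
task_levels <- function() c("rest", "right", "left")

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("trial_set: %d trials of %d samples x %d columns (%s)\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of trials
#' @param trials A [trial_set()].
#' @return Integer count.
#' @export
n_trials <- function(trials) dim(trials$x)[1]

#' Segment a continuous recording into task blocks
#'
#' Each block of `block_duration_s` seconds starting at an onset becomes
#' one trial matrix with `M = round(block_duration_s * fs_hz)` rows and
#' `2N` columns (HbO channels then HbR channels).  Intervals are half-open
#' `[onset, onset + duration)` with 0-based time `row / fs`.
#'
#' @param record A [hemodynamic_record()].
#' @param onsets_s Numeric block onsets in seconds.
#' @param labels Labels parallel to `onsets_s`.
#' @param block_duration_s Block length in seconds; default 10.
#' @return A [trial_set()].
#' @examples
#' # 10-s blocks at 25.7 Hz give 257-row trials
#' @export
segment_trials <- function(record, onsets_s, labels, block_duration_s = 10) {
  stopifnot(inherits(record, "hemodynamic_record"))
  if (length(onsets_s) != length(labels)) {
    stop("onsets and labels must have the same length", call. = FALSE)
  }
  fs <- record$fs_hz
  M <- round(block_duration_s * fs)
  n_time <- nrow(record$hbo)
  n_ch <- ncol(record$hbo)
  if (length(onsets_s) == 0L) {
    return(trial_set(array(0, c(0L, M, 2L * n_ch)), character(0), fs,
                     block_duration_s))
  }
  arr <- array(0, c(length(onsets_s), M, 2L * n_ch))
  for (i in seq_along(onsets_s)) {
    start <- round(onsets_s[i] * fs) + 1L
    if (start < 1L || start + M - 1L > n_time) {
      stop("block at onset ", onsets_s[i], " s (rows ", start, "..",
           start + M - 1L, ") overruns the ", n_time, "-row record",
           call. = FALSE)
    }
    rows <- start:(start + M - 1L)
    arr[i, , ] <- cbind(record$hbo[rows, , drop = FALSE],
                        record$hbr[rows, , drop = FALSE])
  }
  trial_set(arr, labels, fs, block_duration_s)
}
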