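#' Time-domain statistical features of one trace
#'
#' The six conventional fNIRS-BCI features of a single-channel trace:
#' mean, population variance (divisor N), non-excess kurtosis
#' (Gaussian -> 3), skewness, peak (maximum of the signed trace) and slope
#' (ordinary-least-squares slope against the 1-based sample index, i.e.
#' amplitude units per sample).  Kurtosis and skewness use population
#' moments without bias correction.
#'
#' @param x Numeric vector, length >= 2; non-constant (kurtosis and
#'   skewness are undefined for constant traces).
#' @return Named numeric vector
#'   `c(mean, variance, kurtosis, skewness, peak, slope)`.
#' @examples
#' stat_features(c(1, 2, 3, 4))
#' @export
stat_features <- function(x) {
  if (length(x) < 2L) stop("trace must contain at least two samples",
                           call. = FALSE)
  if (any(!is.finite(x))) stop("trace contains non-finite values",
                               call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  dev <- x - mu
  v <- mean(dev^2)
  if (v == 0) {
    stop("kurtosis and skewness are undefined for a constant trace",
         call. = FALSE)
  }
  idx <- seq_len(n)
  slope <- sum((idx - mean(idx)) * dev) / sum((idx - mean(idx))^2)
  c(mean = mu,
    variance = v,
    kurtosis = mean(dev^4) / v^2,
    skewness = mean(dev^3) / v^(3 / 2),
    peak = max(x),
    slope = slope)
}

.feature_names <- function(channel_ids) {
  feats <- c("mean", "variance", "kurtosis", "skewness", "peak", "slope")
  out <- character(0)
  for (f in feats) {
    for (chrom in c("hbo", "hbr")) {
      out <- c(out, sprintf("%s_%s_ch%d", f, chrom, channel_ids))
    }
  }
  out
}

#' Extract the conventional feature table from a trial set
#'
#' One row per trial; 6 features x 2 chromophores x N channels columns
#' (408 for the default 34-channel montage), ordered feature-major with
#' names `<feature>_<chromophore>_ch<k>`.
#'
#' @param trials A [trial_set()].
#' @return Numeric matrix `n_trials x (12 * n_channels)` with named
#'   columns; trial labels remain in `trials$labels`.
#' @export
extract_feature_table <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$x)
  if (d[3] %% 2L != 0L) stop("trial columns must pair HbO and HbR",
                             call. = FALSE)
  n_ch <- d[3] %/% 2L
  nms <- .feature_names(seq_len(n_ch))
  out <- matrix(0, d[1], length(nms), dimnames = list(NULL, nms))
  feats <- c("mean", "variance", "kurtosis", "skewness", "peak", "slope")
  for (i in seq_len(d[1])) {
    per_col <- apply(trials$x[i, , , drop = TRUE], 2L, function(tr) {
      tryCatch(stat_features(tr), error = function(e)
        stop("trial ", i, ": ", conditionMessage(e), call. = FALSE))
    })  # 6 x 2N, columns = [hbo 1..N, hbr 1..N]
    for (fi in seq_along(feats)) {
      out[i, ((fi - 1L) * 2L * n_ch) + seq_len(2L * n_ch)] <- per_col[fi, ]
    }
  }
  out
}

#' Min-max normalization of a feature table
#'
#' `fit_minmax()` learns per-column minima and maxima (training rows
#' only); `apply_minmax()` rescales columns into [0, 1], clipping values
#' outside the fitted range.  A constant training column maps to 0.5 with
#' a warning.
#'
#' @param table Numeric feature matrix (rows = trials).
#' @return `fit_minmax`: a `minmax_fit`; `apply_minmax`: rescaled matrix.
#' @export
fit_minmax <- function(table) {
  table <- as.matrix(table)
  mins <- apply(table, 2L, min)
  maxs <- apply(table, 2L, max)
  const <- maxs == mins
  if (any(const)) {
    warning(sum(const), " constant feature column(s) will map to 0.5")
  }
  structure(list(min = mins, max = maxs, constant = const),
            class = "minmax_fit")
}

#' @rdname fit_minmax
#' @param fitted A `minmax_fit` from [fit_minmax()].
#' @export
apply_minmax <- function(table, fitted) {
  stopifnot(inherits(fitted, "minmax_fit"))
  table <- as.matrix(table)
  if (ncol(table) != length(fitted$min)) {
    stop("table has ", ncol(table), " columns; fit expects ",
         length(fitted$min), call. = FALSE)
  }
  span <- fitted$max - fitted$min
  span[fitted$constant] <- 1
  out <- sweep(sweep(table, 2L, fitted$min), 2L, span, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[, fitted$constant] <- 0.5
  out
}
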