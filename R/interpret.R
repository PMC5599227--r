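#' Two-component PCA scatter of a representation
#'
#' Projects any per-trial representation - raw trial matrices flattened
#' row-major, the conventional feature table, or first-layer feature maps
#' - onto its first two principal components for class-separability
#' visualization.
#'
#' @param x Numeric matrix (samples x dims) or 3-D array
#'   `(samples, time, channels)` / [trial_set()], flattened internally.
#' @param labels Class labels, one per sample.
#' @return Data frame with columns `pc1`, `pc2`, `label`.
#' @export
pca_scatter <- function(x, labels) {
  if (inherits(x, "trial_set")) x <- x$x
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2] * d[3])
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two samples", call. = FALSE)
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (sum(keep) < 2L) {
    stop("fewer than two non-degenerate dimensions", call. = FALSE)
  }
  pc <- pca_fit(x[, keep, drop = FALSE], 2L)
  proj <- pca_transform(x[, keep, drop = FALSE], pc)
  data.frame(pc1 = proj[, 1], pc2 = proj[, 2],
             label = factor(labels))
}

#' First-layer feature maps of a trained CNN
#'
#' Activations after the first convolution + ReLU, flattened per trial;
#' the "feature map" representation used for separability comparison.
#'
#' @param model A trained `nirs_cnn`.
#' @param trials A [trial_set()] or 3-D array.
#' @return Matrix `(n_trials, time * filters)`.
#' @export
cnn_feature_maps <- function(model, trials) {
  stopifnot(inherits(model, "nirs_cnn"), isTRUE(model$trained))
  x <- if (inherits(trials, "trial_set")) trials$x else trials
  fw <- .forward_layer(model$layers[[1]], x, training = FALSE)
  act <- fw$out * (fw$out > 0)
  d <- dim(act)
  dim(act) <- c(d[1], d[2] * d[3])
  act
}

#' Channel attribution of first-layer convolutional filters
#'
#' For each filter of the first convolutional layer, averages its weights
#' over the kernel (time) dimension to one weight per input
#' chromophore-channel, selects the channel with the highest averaged
#' weight, and extracts that channel's trace from every trial.  Filters
#' are returned ranked by class-conditional amplitude contrast: the
#' largest absolute difference between a task class's mean trace amplitude
#' and the rest-class mean.
#'
#' @param model A trained `nirs_cnn` whose first layer is the time
#'   convolution.
#' @param trials A [trial_set()] with labels.
#' @param use_absolute Average absolute weight values instead of signed
#'   ones (sign conventions can flip during training); default FALSE,
#'   the signed mean.
#' @return List of `attribution_result`s, each with `filter_id`,
#'   `channel_weights` (length 2N), `selected_channel`,
#'   `per_sample_traces` (`n_trials x M`), `contrast` and
#'   `class_means` (mean trace amplitude per class).
#' @export
filter_channel_attribution <- function(model, trials,
                                       use_absolute = FALSE) {
  stopifnot(inherits(model, "nirs_cnn"))
  if (!isTRUE(model$trained)) stop("model has not been trained",
                                   call. = FALSE)
  stopifnot(inherits(trials, "trial_set"))
  first <- model$layers[[1]]
  stopifnot(first$type == "conv1d")
  C <- first$channels
  k <- first$kernel_size
  if (dim(trials$x)[3] != C) {
    stop("trial set has ", dim(trials$x)[3],
         " columns but the model expects ", C, call. = FALSE)
  }
  labels <- trials$labels
  results <- lapply(seq_len(first$filters), function(f) {
    wf <- matrix(first$W[, f], nrow = C)  # C x k (rows offset-major blocks)
    w_use <- if (use_absolute) abs(wf) else wf
    channel_weights <- rowMeans(w_use)
    sel <- which.max(channel_weights)
    traces <- trials$x[, , sel, drop = TRUE]
    if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
    amp <- rowMeans(traces)
    class_means <- tapply(amp, labels, mean)
    contrast <- max(abs(class_means[c("right", "left")] -
                          class_means["rest"]), na.rm = TRUE)
    structure(list(filter_id = f, channel_weights = channel_weights,
                   selected_channel = sel, per_sample_traces = traces,
                   class_means = class_means, contrast = contrast),
              class = "attribution_result")
  })
  results[order(vapply(results, `[[`, numeric(1), "contrast"),
                decreasing = TRUE)]
}
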