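#' Stratified k-fold assignment
#'
#' Partitions sample indices into k folds of (as near as possible) equal
#' size while keeping the per-class counts across folds within one of each
#' other, so the 2:1:1 rest/right/left prior of the default block design
#' holds in every fold.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- factor(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")",
                  call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cl in levels(droplevels(labels))) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so fold sizes stay balanced
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

.accuracy <- function(truth, predicted) {
  mean(as.character(truth) == as.character(predicted))
}

.subset_rows <- function(x, idx) {
  if (inherits(x, "trial_set")) {
    trial_set(x$x[idx, , , drop = FALSE], x$labels[idx], x$fs_hz,
              x$block_duration_s)
  } else if (length(dim(x)) == 3L) {
    x[idx, , , drop = FALSE]
  } else {
    x[idx, , drop = FALSE]
  }
}

.n_rows <- function(x) {
  if (inherits(x, "trial_set")) n_trials(x)
  else if (length(dim(x)) == 3L) dim(x)[1]
  else nrow(x)
}

#' k-fold cross-validation of a pipeline
#'
#' Fits the full pipeline (normalization, PCA where applicable, and the
#' classifier) on each training fold and scores top-1 accuracy on the
#' held-out fold; no statistic is computed from held-out rows.
#'
#' @param pipeline A pipeline from [svm_pipeline()], [ann_pipeline()] or
#'   [cnn_pipeline()].
#' @param x Feature matrix or trial array / [trial_set()].
#' @param labels Class labels.
#' @param k Number of folds; default 10.
#' @param seed Seed controlling fold assignment and per-fold training.
#' @return A `cv_report`: `fold_accuracies`, `mean_accuracy`, `k`, `seed`,
#'   `spec_id`, `chosen_hyperparameters`, `folds`, `failed_folds`.
#' @export
cross_validate <- function(pipeline, x, labels, k = 10L, seed = 1L) {
  labels <- factor(labels)
  n <- .n_rows(x)
  stopifnot(n == length(labels))
  folds <- stratified_kfold(labels, k, seed)
  acc <- rep(NA_real_, k)
  failed <- character(0)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    res <- tryCatch({
      fitted <- fit_pipeline(pipeline, .subset_rows(x, train),
                             labels[train], seed = seed + f)
      pred <- predict(fitted, .subset_rows(x, test))
      .accuracy(labels[test], pred)
    }, error = function(e) {
      failed <<- c(failed, sprintf("fold %d: %s", f, conditionMessage(e)))
      NA_real_
    })
    acc[f] <- res
  }
  structure(list(fold_accuracies = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 k = as.integer(k), seed = as.integer(seed),
                 spec_id = pipeline$id,
                 chosen_hyperparameters = NULL,
                 folds = folds, failed_folds = failed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]: mean accuracy %.4f over %d folds (seed %d)\n",
              x$spec_id, x$mean_accuracy, x$k, x$seed))
  if (length(x$failed_folds)) {
    cat("  failed folds:\n   ", paste(x$failed_folds, collapse = "\n    "),
        "\n")
  }
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Epoch / batch-size / learning-rate values are the sets used for
#' per-subject tuning of the network classifiers; the SVM grids (C
#' log-spaced over 1e-2..1e2, PCA component counts) are package defaults.
#'
#' @return Named list of grids.
#' @export
default_grids <- function() {
  list(epochs = c(20L, 50L, 100L),
       batch_size = c(16L, 32L, 64L),
       learning_rate = c(1e-4, 5e-4, 1e-3),
       svm_c = 10^seq(-2, 2, by = 1),
       pca_components = c(2L, 5L, 10L, 20L, 50L, 100L, 200L))
}

#' Hyperparameter grid search by cross-validation
#'
#' Evaluates every grid point with [cross_validate()] and returns the
#' point with the highest mean accuracy.  Network grids are over
#' `epochs` x `batch_size` x `learning_rate` (ties broken toward fewer
#' epochs, then smaller batch, then lower learning rate); SVM grids are
#' over `pca_components` x `svm_c` (ties toward fewer components, then
#' smaller C).
#'
#' @param family `"svm"`, `"ann"` or `"cnn"`.
#' @param spec Structure spec ([svm_spec()] values are overridden by the
#'   grid; [ann_spec()] / [cnn_spec()] fix the architecture).
#' @param grid Named list of grid values, see [default_grids()].
#' @param x,labels Data as in [cross_validate()].
#' @param k,seed Cross-validation settings.
#' @return List with `best` (named hyperparameters), `best_report`
#'   (its `cv_report` with `chosen_hyperparameters` filled in), and
#'   `reports` (one `cv_report` per grid point, in evaluation order).
#' @export
grid_search <- function(family = c("svm", "ann", "cnn"), spec = NULL,
                        grid = default_grids(), x, labels, k = 10L,
                        seed = 1L) {
  family <- match.arg(family)
  if (family == "svm") {
    pts <- expand.grid(pca_components = grid$pca_components,
                       svm_c = grid$svm_c)
    # tie-break order: fewer components, then smaller C
    pts <- pts[order(pts$pca_components, pts$svm_c), , drop = FALSE]
  } else {
    pts <- expand.grid(learning_rate = grid$learning_rate,
                       batch_size = grid$batch_size,
                       epochs = grid$epochs)
    # tie-break order: fewer epochs, smaller batch, lower learning rate
    pts <- pts[order(pts$epochs, pts$batch_size, pts$learning_rate), ,
               drop = FALSE]
  }
  if (!nrow(pts)) stop("empty hyperparameter grid", call. = FALSE)
  reports <- vector("list", nrow(pts))
  best_i <- NA_integer_
  best_acc <- -Inf
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, , drop = FALSE]
    pipeline <- switch(
      family,
      svm = svm_pipeline(svm_spec(c_regularization = p$svm_c,
                                  n_components = p$pca_components)),
      ann = ann_pipeline(spec, train_config(epochs = p$epochs,
                                            batch_size = p$batch_size,
                                            learning_rate = p$learning_rate)),
      cnn = cnn_pipeline(spec, train_config(epochs = p$epochs,
                                            batch_size = p$batch_size,
                                            learning_rate = p$learning_rate)))
    rep_i <- cross_validate(pipeline, x, labels, k = k, seed = seed)
    rep_i$chosen_hyperparameters <- as.list(p)
    reports[[i]] <- rep_i
    if (rep_i$mean_accuracy > best_acc) {  # strict: first best wins ties
      best_acc <- rep_i$mean_accuracy
      best_i <- i
    }
  }
  list(best = as.list(pts[best_i, , drop = FALSE]),
       best_report = reports[[best_i]],
       reports = reports)
}

#' Sample-size learning curve
#'
#' For each requested size, draws a stratified subsample preserving the
#' class ratio, cross-validates the pipeline, and averages over `repeats`
#' independent subsamples.  Sizes too small for stratified k folds are
#' skipped with a warning.
#'
#' @param pipeline Classification pipeline.
#' @param x,labels Full data set.
#' @param sizes Integer subsample sizes.
#' @param k Folds per evaluation; default 10.
#' @param seed Base seed.
#' @param repeats Subsample draws per size (>= 1).
#' @return Data frame with columns `size`, `mean_accuracy`, `sd_accuracy`,
#'   `repeats`.
#' @export
learning_curve <- function(pipeline, x, labels, sizes, k = 10L, seed = 1L,
                           repeats = 3L) {
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  labels <- factor(labels)
  n <- .n_rows(x)
  stopifnot(all(sizes <= n))
  cls <- levels(droplevels(labels))
  prop <- table(labels)[cls] / n
  out <- list()
  for (s in sizes) {
    per_class <- round(prop * s)
    if (any(per_class < k)) {
      warning("size ", s, " leaves fewer than k = ", k,
              " samples in some class; skipped")
      next
    }
    accs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sub_seed <- as.integer(seed + 1000L * r + s)
      if (s == n) {  # full data: no subsampling, result == cross_validate
        idx <- seq_len(n)
      } else {
        set.seed(sub_seed)
        idx <- unlist(lapply(cls, function(cl)
          sample(which(labels == cl), per_class[[cl]])))
      }
      rep_r <- cross_validate(pipeline, .subset_rows(x, idx), labels[idx],
                              k = k, seed = sub_seed)
      accs[r] <- rep_r$mean_accuracy
    }
    out[[length(out) + 1L]] <- data.frame(size = s,
                                          mean_accuracy = mean(accs),
                                          sd_accuracy = stats::sd(accs),
                                          repeats = repeats)
  }
  if (!length(out)) stop("no size was large enough for stratified ", k,
                         "-fold cross-validation", call. = FALSE)
  do.call(rbind, out)
}
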