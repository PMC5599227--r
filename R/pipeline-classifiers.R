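#' @name classifier_pipelines
#' @title Leak-free classification pipelines
#'
#' @description
#' A pipeline bundles every data-dependent preprocessing step with the
#' classifier so that cross-validation can fit the whole chain on the
#' training fold only:
#' * `svm_pipeline()` - per-column min-max normalization, PCA, linear SVM;
#' * `ann_pipeline()` - per-column min-max normalization, fully connected
#'   network;
#' * `cnn_pipeline()` - convolutional network directly on trial arrays
#'   (the signal-level [0,1] normalization happens once per recording in
#'   [denoise_record()], before trials exist).
#'
#' `fit_pipeline(pipeline, x, labels, seed)` returns a fitted object whose
#' `predict()` applies the fitted preprocessing to new rows.
NULL

.pipeline <- function(kind, spec, config = NULL, id = NULL) {
  structure(list(kind = kind, spec = spec, config = config,
                 id = id %||% spec$id %||% kind),
            class = "nirs_pipeline")
}

#' @rdname classifier_pipelines
#' @param spec An [svm_spec()].
#' @export
svm_pipeline <- function(spec = svm_spec()) {
  .pipeline("svm", spec, id = sprintf("SVM(C=%g, pc=%d)",
                                      spec$c_regularization,
                                      spec$n_components))
}

#' @rdname classifier_pipelines
#' @param config A [train_config()].
#' @export
ann_pipeline <- function(spec, config = train_config()) {
  .pipeline("ann", spec, config)
}

#' @rdname classifier_pipelines
#' @export
cnn_pipeline <- function(spec, config = train_config()) {
  .pipeline("cnn", spec, config)
}

#' @rdname classifier_pipelines
#' @param pipeline A pipeline from one of the constructors above.
#' @param x Feature matrix (SVM/ANN) or 3-D trial array (CNN); a
#'   [trial_set()] is also accepted for the CNN.
#' @param labels Class labels.
#' @param seed Seed for this fit (overrides the seed in the training
#'   config so cross-validation folds get distinct streams).
#' @return A `nirs_fitted_pipeline`.
#' @export
fit_pipeline <- function(pipeline, x, labels, seed = 1L) {
  stopifnot(inherits(pipeline, "nirs_pipeline"))
  labels <- factor(labels)
  fitted <- switch(
    pipeline$kind,
    svm = {
      x <- as.matrix(x)
      mm <- suppressWarnings(fit_minmax(x))
      xs <- apply_minmax(x, mm)
      pc <- pca_fit(xs, pipeline$spec$n_components)
      model <- train_svm(pca_transform(xs, pc), labels, pipeline$spec,
                         seed = seed)
      list(minmax = mm, pca = pc, model = model)
    },
    ann = {
      x <- as.matrix(x)
      mm <- suppressWarnings(fit_minmax(x))
      cfg <- pipeline$config
      cfg$seed <- as.integer(seed)
      model <- train_ann(apply_minmax(x, mm), labels, pipeline$spec, cfg)
      list(minmax = mm, model = model)
    },
    cnn = {
      xa <- if (inherits(x, "trial_set")) x$x else x
      cfg <- pipeline$config
      cfg$seed <- as.integer(seed)
      model <- train_cnn(xa, labels, pipeline$spec, cfg)
      list(model = model)
    },
    stop("unknown pipeline kind ", pipeline$kind)
  )
  structure(c(fitted, list(kind = pipeline$kind, id = pipeline$id)),
            class = "nirs_fitted_pipeline")
}

#' @export
predict.nirs_fitted_pipeline <- function(object, newdata, ...) {
  switch(
    object$kind,
    svm = {
      xs <- apply_minmax(as.matrix(newdata), object$minmax)
      predict(object$model, pca_transform(xs, object$pca))
    },
    ann = predict(object$model,
                  apply_minmax(as.matrix(newdata), object$minmax)),
    cnn = {
      xa <- if (inherits(newdata, "trial_set")) newdata$x else newdata
      predict(object$model, xa)
    }
  )
}
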