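#' Principal component analysis of a feature table
#'
#' `pca_fit()` learns the mean and the top-variance orthonormal
#' directions from training rows only; `pca_transform()` projects
#' (mean-centred) rows onto them.
#'
#' @param table Numeric matrix, rows = samples.
#' @param n_components Number of components to retain.
#' @return `pca_fit`: a `pca_fit` object with `center`, `rotation`,
#'   `sdev`; `pca_transform`: the projected matrix.
#' @export
pca_fit <- function(table, n_components) {
  table <- as.matrix(table)
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  max_rank <- min(nrow(table) - 1L, ncol(table))
  if (n_components > max_rank) {
    warning("n_components reduced from ", n_components, " to rank limit ",
            max_rank)
    n_components <- max_rank
  }
  ctr <- colMeans(table)
  sv <- svd(sweep(table, 2L, ctr), nu = 0L, nv = n_components)
  structure(list(center = ctr,
                 rotation = sv$v,
                 sdev = sv$d[seq_len(n_components)] /
                   sqrt(max(1, nrow(table) - 1L)),
                 n_components = n_components),
            class = "pca_fit")
}

#' @rdname pca_fit
#' @param fitted A `pca_fit`.
#' @export
pca_transform <- function(table, fitted) {
  stopifnot(inherits(fitted, "pca_fit"))
  sweep(as.matrix(table), 2L, fitted$center) %*% fitted$rotation
}

#' Linear SVM specification
#'
#' @param c_regularization Soft-margin penalty C (> 0); larger values
#'   penalize training errors more heavily.
#' @param n_components Principal components retained before the SVM.
#' @return An `svm_spec`.
#' @export
svm_spec <- function(c_regularization = 1, n_components = 20L) {
  stopifnot(c_regularization > 0, n_components >= 1L)
  structure(list(c_regularization = c_regularization,
                 n_components = as.integer(n_components)),
            class = "svm_spec")
}

# Squared-hinge primal objective for one binary problem; exact and smooth,
# optimized deterministically with BFGS from a zero start.
.svm_binary <- function(x, y, C) {
  d <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    coef <- -2 * C * m * y
    c(w + drop(crossprod(x, coef)), sum(coef))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L])
}

#' Train a multiclass linear SVM
#'
#' One-vs-rest linear soft-margin SVM (squared hinge, optimized exactly
#' with BFGS, hence deterministic).  Inputs are expected to be already
#' normalized and PCA-reduced; see [svm_pipeline()] for the full chain.
#'
#' @param features Numeric matrix (samples x dims).
#' @param labels Factor/character class labels (>= 2 classes present).
#' @param spec An [svm_spec()] (only `c_regularization` is used here).
#' @param seed Unused (training is deterministic); kept for interface
#'   symmetry with the other classifiers.
#' @return A `nirs_svm` classifier for [predict()].
#' @export
train_svm <- function(features, labels, spec = svm_spec(), seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  present <- levels(droplevels(labels))
  if (length(present) < 2L) {
    stop("training requires at least two classes", call. = FALSE)
  }
  models <- lapply(present, function(cl) {
    y <- ifelse(labels == cl, 1, -1)
    .svm_binary(features, y, spec$c_regularization)
  })
  names(models) <- present
  structure(list(models = models, classes = present,
                 level_set = levels(labels), spec = spec),
            class = "nirs_svm")
}

#' @export
predict.nirs_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- vapply(object$models, function(m)
    drop(newdata %*% m$w) + m$b, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata),
                   dimnames = list(NULL, object$classes))
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$level_set)
}
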