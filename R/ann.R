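#' Fully connected network specification
#'
#' The six structures evaluated for feature-vector classification have one
#' or two hidden layers; see [ann_structures()].  Hidden activation is
#' ReLU and the 3-class output uses softmax.
#'
#' @param hidden_layers Integer widths of the hidden layers.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param output_classes Number of classes; default 3.
#' @param id Optional structure identifier (e.g. `"ANN2-a"`).
#' @return An `ann_spec`.
#' @export
ann_spec <- function(hidden_layers, activation = "relu",
                     output_classes = 3L, id = NULL) {
  hidden_layers <- as.integer(hidden_layers)
  if (!length(hidden_layers) || any(hidden_layers < 1L)) {
    stop("hidden layer widths must be positive", call. = FALSE)
  }
  if (!identical(activation, "relu")) {
    stop("only ReLU hidden activation is implemented", call. = FALSE)
  }
  structure(list(hidden_layers = hidden_layers, activation = activation,
                 output_classes = as.integer(output_classes),
                 id = id %||% paste0("ANN[",
                                     paste(hidden_layers, collapse = ","),
                                     "]")),
            class = "ann_spec")
}

#' Catalogue of fully connected structures
#'
#' @return Named list of [ann_spec()]s: ANN1-a/b/c with one hidden layer
#'   of 128/256/512 units, ANN2-a/b/c with two hidden layers of
#'   256+128 / 512+256 / 512+128 units.
#' @export
ann_structures <- function() {
  defs <- list(`ANN1-a` = 128L, `ANN1-b` = 256L, `ANN1-c` = 512L,
               `ANN2-a` = c(256L, 128L), `ANN2-b` = c(512L, 256L),
               `ANN2-c` = c(512L, 128L))
  mapply(function(h, id) ann_spec(h, id = id), defs, names(defs),
         SIMPLIFY = FALSE)
}

#' Build an untrained fully connected network
#'
#' @param spec An [ann_spec()].
#' @param n_inputs Input dimension (408 for the default feature table).
#' @param seed Seed for the weight initialization.
#' @return A `nirs_ann` with uniform fan-in-scaled initial weights.
#' @export
build_ann <- function(spec, n_inputs, seed = 1L) {
  stopifnot(inherits(spec, "ann_spec"), n_inputs >= 1L)
  set.seed(seed)
  widths <- c(n_inputs, spec$hidden_layers)
  layers <- list()
  for (i in seq_along(spec$hidden_layers)) {
    layers <- c(layers, list(.layer_dense(widths[i], widths[i + 1L]),
                             .layer_relu()))
  }
  layers <- c(layers, list(.layer_dense(widths[length(widths)],
                                        spec$output_classes)))
  structure(list(layers = layers, n_classes = spec$output_classes,
                 spec = spec, n_inputs = n_inputs, trained = FALSE),
            class = "nirs_ann")
}

#' Train a fully connected network on feature vectors
#'
#' Mini-batch Adam on the softmax cross-entropy.  Given the same seed the
#' run is fully reproducible.
#'
#' @param features Numeric matrix (samples x dims), typically a min-max
#'   normalized feature table.
#' @param labels Trial labels.
#' @param spec An [ann_spec()].
#' @param config A [train_config()].
#' @return A trained `nirs_ann`.
#' @export
train_ann <- function(features, labels, spec, config = train_config()) {
  features <- as.matrix(features)
  labels <- factor(labels)
  net <- build_ann(spec, ncol(features), seed = config$seed)
  y <- as.integer(labels)
  res <- .nn_train(net, features, y, config)
  net <- res$net
  net$trained <- TRUE
  net$epoch_loss <- res$epoch_loss
  net$level_set <- levels(labels)
  net
}

#' @export
predict.nirs_ann <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  p <- .nn_predict_proba(object, as.matrix(newdata))
  if (type == "prob") {
    colnames(p) <- object$level_set %||% seq_len(ncol(p))
    return(p)
  }
  lv <- object$level_set %||% as.character(seq_len(ncol(p)))
  factor(lv[max.col(p, ties.method = "first")], levels = lv)
}
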