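#' Convolutional network specification
#'
#' One-dimensional convolutional networks over trial matrices
#' `(M time points x 2N chromophore-channels)`.  Every convolutional layer
#' has `kernel_size = 3` filters spanning the full channel width, stride 1
#' and length-preserving zero padding, followed by ReLU, max-pooling of
#' size 2 (floor division of the time axis) and dropout at rate 0.5.  The
#' convolutional stack feeds two fully connected ReLU layers of 256 and
#' 128 units and a 3-class softmax output.
#'
#' @param conv_filters Integer filter counts, one per convolutional layer
#'   (e.g. `c(32, 32, 32)` for CNN2-a).
#' @param kernel_size Convolution kernel height; default 3.
#' @param pool_size Max-pooling kernel; default (and only supported) 2.
#' @param dropout_rate Dropout after each pooling step; default 0.5.
#' @param fc_widths Fully connected widths; default `c(256, 128)`.
#' @param output_classes Number of classes; default 3.
#' @param id Optional structure identifier (e.g. `"CNN1-a"`).
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(conv_filters, kernel_size = 3L, pool_size = 2L,
                     dropout_rate = 0.5, fc_widths = c(256L, 128L),
                     output_classes = 3L, id = NULL) {
  conv_filters <- as.integer(conv_filters)
  if (!length(conv_filters) || any(conv_filters < 1L)) {
    stop("conv_filters must be positive", call. = FALSE)
  }
  stopifnot(kernel_size >= 1L, kernel_size %% 2L == 1L,
            dropout_rate >= 0, dropout_rate < 1)
  if (pool_size != 2L) stop("only pool_size = 2 is supported",
                            call. = FALSE)
  structure(list(conv_filters = conv_filters,
                 kernel_size = as.integer(kernel_size), pool_size = 2L,
                 dropout_rate = dropout_rate,
                 fc_widths = as.integer(fc_widths),
                 output_classes = as.integer(output_classes),
                 id = id %||% paste0("CNN[",
                                     paste(conv_filters, collapse = ","),
                                     "]")),
            class = "cnn_spec")
}

#' Catalogue of convolutional structures
#'
#' @return Named list of [cnn_spec()]s: CNN1-a/b with one convolutional
#'   layer of 32/64 filters, CNN2-a/b with three layers of 32/64 filters
#'   each.
#' @export
cnn_structures <- function() {
  defs <- list(`CNN1-a` = 32L, `CNN1-b` = 64L,
               `CNN2-a` = c(32L, 32L, 32L), `CNN2-b` = c(64L, 64L, 64L))
  mapply(function(f, id) cnn_spec(f, id = id), defs, names(defs),
         SIMPLIFY = FALSE)
}

#' Layer-by-layer shape propagation
#'
#' Computes the input and output size of every layer of a [cnn_spec()]
#' applied to an `input_shape = c(time, channels)` trial, reproducing the
#' reference propagation table for CNN2-a on a 257 x 68 input.
#'
#' @param spec A [cnn_spec()].
#' @param input_shape `c(M, 2N)`.
#' @return Data frame with columns `layer`, `input`, `output`.
#' @export
cnn_shapes <- function(spec, input_shape = c(257L, 68L)) {
  tt <- as.integer(input_shape[1]); ch <- as.integer(input_shape[2])
  rows <- list()
  add <- function(layer, in_shape, out_shape) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer,
      input = paste(in_shape, collapse = ", "),
      output = paste(out_shape, collapse = ", "),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[i]
    add(sprintf("Convolutional layer %d", i), c(tt, ch), c(tt, f))
    ch <- f
    add(sprintf("Max-pooling %d", i), c(tt, ch), c(tt %/% 2L, ch))
    tt <- tt %/% 2L
    add(sprintf("Dropout %d", i), c(tt, ch), c(tt, ch))
  }
  flat <- tt * ch
  widths <- c(flat, spec$fc_widths)
  for (i in seq_along(spec$fc_widths)) {
    add(sprintf("Fully connected layer %d", i), widths[i], widths[i + 1L])
  }
  add("Output layer", widths[length(widths)], spec$output_classes)
  do.call(rbind, rows)
}

#' Build an untrained convolutional network
#'
#' @param spec A [cnn_spec()].
#' @param input_shape Trial shape `c(M, 2N)`; default `c(257, 68)`.
#' @param seed Seed for the weight initialization.
#' @return A `nirs_cnn`.
#' @export
build_cnn <- function(spec, input_shape = c(257L, 68L), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  tt <- as.integer(input_shape[1]); ch <- as.integer(input_shape[2])
  set.seed(seed)
  layers <- list()
  for (f in spec$conv_filters) {
    if (tt < 2L) {
      stop("architecture error: time axis collapsed below 2 samples; ",
           "expected propagation:\n",
           paste(utils::capture.output(print(cnn_shapes(spec, input_shape))),
                 collapse = "\n"), call. = FALSE)
    }
    layers <- c(layers, list(.layer_conv1d(ch, f, spec$kernel_size),
                             .layer_relu(),
                             .layer_maxpool(spec$pool_size),
                             .layer_dropout(spec$dropout_rate)))
    ch <- f
    tt <- tt %/% 2L
  }
  layers <- c(layers, list(.layer_flatten()))
  widths <- c(tt * ch, spec$fc_widths)
  for (i in seq_along(spec$fc_widths)) {
    layers <- c(layers, list(.layer_dense(widths[i], widths[i + 1L]),
                             .layer_relu()))
  }
  layers <- c(layers, list(.layer_dense(widths[length(widths)],
                                        spec$output_classes)))
  structure(list(layers = layers, n_classes = spec$output_classes,
                 spec = spec, input_shape = c(as.integer(input_shape[1]),
                                              as.integer(input_shape[2])),
                 trained = FALSE),
            class = "nirs_cnn")
}

#' Train a convolutional network on a trial set
#'
#' @param trials A [trial_set()] (or bare 3-D array `(n, M, 2N)`).
#' @param labels Trial labels; defaults to `trials$labels`.
#' @param spec A [cnn_spec()].
#' @param config A [train_config()].
#' @return A trained `nirs_cnn`.
#' @export
train_cnn <- function(trials, labels = NULL, spec,
                      config = train_config()) {
  x <- if (inherits(trials, "trial_set")) trials$x else trials
  if (is.null(labels) && inherits(trials, "trial_set")) {
    labels <- trials$labels
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  labels <- factor(labels)
  net <- build_cnn(spec, input_shape = dim(x)[2:3], seed = config$seed)
  res <- .nn_train(net, x, as.integer(labels), config)
  net <- res$net
  net$trained <- TRUE
  net$epoch_loss <- res$epoch_loss
  net$level_set <- levels(labels)
  net
}

#' @export
predict.nirs_cnn <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "trial_set")) newdata$x else newdata
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!all(dim(x)[2:3] == object$input_shape)) {
    stop("input shape ", paste(dim(x)[2:3], collapse = "x"),
         " does not match the training shape ",
         paste(object$input_shape, collapse = "x"), call. = FALSE)
  }
  p <- .nn_predict_proba(object, x)
  if (type == "prob") {
    colnames(p) <- object$level_set %||% seq_len(ncol(p))
    return(p)
  }
  lv <- object$level_set %||% as.character(seq_len(ncol(p)))
  factor(lv[max.col(p, ties.method = "first")], levels = lv)
}
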