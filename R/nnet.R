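#' @name nnet_engine
#' @title Minimal seeded neural-network engine
#'
#' @description
#' A small reverse-mode engine sufficient for the two network families in
#' this package: fully connected networks on feature vectors and 1-D
#' convolutional networks on multichannel time series.  Layers operate on
#' a mini-batch stored either as a matrix `(batch x units)` or a 3-D array
#' `(batch, time, channels)`.  Convolution is realised as an im2col
#' unfolding followed by one matrix multiplication; its filters span the
#' full channel width and slide along time with stride 1 and
#' length-preserving zero padding.  Max-pooling halves the time axis with
#' floor division (an orphan final sample is dropped) and dropout uses
#' inverted scaling so inference is a plain forward pass.  Optimization is
#' mini-batch Adam on the categorical cross-entropy of a softmax output.
#' All randomness (initialization, shuffling, dropout) comes from the
#' R RNG, seeded once per training run, so runs are reproducible.
NULL

# ---- layer constructors ----------------------------------------------------

.uniform_init <- function(n_in, n_out, fan_in) {
  lim <- sqrt(1 / fan_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = .uniform_init(n_in, n_out, n_in),
       b = matrix(0, 1, n_out))
}

# kernel_size x channels filters; W rows ordered offset-major:
# row (m-1)*C + c  <-> kernel offset m, input channel c.
.layer_conv1d <- function(channels, filters, kernel_size = 3L) {
  fan_in <- kernel_size * channels
  list(type = "conv1d", kernel_size = as.integer(kernel_size),
       channels = as.integer(channels), filters = as.integer(filters),
       W = .uniform_init(fan_in, filters, fan_in),
       b = matrix(0, 1, filters))
}

.layer_relu <- function() list(type = "relu")
.layer_maxpool <- function(size = 2L) {
  if (size != 2L) stop("only max-pooling with kernel size 2 is supported",
                       call. = FALSE)
  list(type = "maxpool", size = 2L)
}
.layer_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate)
.layer_flatten <- function() list(type = "flatten")

# ---- forward / backward ----------------------------------------------------

.im2col <- function(x, k) {
  # x: (B, T, C) zero-padded along time by (k-1)/2 on each side.
  d <- dim(x); B <- d[1]; C <- d[3]
  p <- (k - 1L) %/% 2L
  Tt <- d[2]
  xp <- array(0, c(B, Tt + 2L * p, C))
  xp[, p + seq_len(Tt), ] <- x
  cols <- matrix(0, B * Tt, k * C)
  for (m in seq_len(k)) {
    blk <- xp[, (m - 1L) + seq_len(Tt), , drop = FALSE]
    dim(blk) <- c(B * Tt, C)
    cols[, (m - 1L) * C + seq_len(C)] <- blk
  }
  cols
}

.col2im <- function(dcols, k, B, Tt, C) {
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(B, Tt + 2L * p, C))
  for (m in seq_len(k)) {
    blk <- dcols[, (m - 1L) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(B, Tt, C)
    dxp[, (m - 1L) + seq_len(Tt), ] <-
      dxp[, (m - 1L) + seq_len(Tt), , drop = FALSE] + blk
  }
  dxp[, p + seq_len(Tt), , drop = FALSE]
}

.forward_layer <- function(layer, x, training) {
  cache <- NULL
  out <- switch(
    layer$type,
    dense = {
      cache <- list(x = x)
      sweep(x %*% layer$W, 2L, layer$b, "+")
    },
    conv1d = {
      d <- dim(x)
      cols <- .im2col(x, layer$kernel_size)
      o <- sweep(cols %*% layer$W, 2L, layer$b, "+")
      dim(o) <- c(d[1], d[2], layer$filters)
      cache <- list(cols = cols, in_dim = d)
      o
    },
    relu = {
      cache <- list(pos = x > 0)
      x * (x > 0)
    },
    maxpool = {
      d <- dim(x)
      t2 <- d[2] %/% layer$size
      a <- x[, seq(1L, layer$size * t2, by = 2L), , drop = FALSE]
      b <- x[, seq(2L, layer$size * t2, by = 2L), , drop = FALSE]
      first <- a >= b
      cache <- list(first = first, in_dim = d, t2 = t2)
      pmax(a, b)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (array(stats::runif(length(x)), dim(x)) < keep) / keep
        cache <- list(mask = mask)
        x * mask
      } else {
        cache <- list(mask = NULL)
        x
      }
    },
    flatten = {
      d <- dim(x)
      cache <- list(in_dim = d)
      dim(x) <- c(d[1], d[2] * d[3])
      x
    },
    stop("unknown layer type ", layer$type)
  )
  list(out = out, cache = cache)
}

.backward_layer <- function(layer, dout, cache) {
  switch(
    layer$type,
    dense = list(dx = dout %*% t(layer$W),
                 dW = crossprod(cache$x, dout),
                 db = matrix(colSums(dout), 1)),
    conv1d = {
      d <- cache$in_dim
      dmat <- dout
      dim(dmat) <- c(d[1] * d[2], layer$filters)
      list(dx = .col2im(dmat %*% t(layer$W), layer$kernel_size,
                        d[1], d[2], d[3]),
           dW = crossprod(cache$cols, dmat),
           db = matrix(colSums(dmat), 1))
    },
    relu = list(dx = dout * cache$pos),
    maxpool = {
      d <- cache$in_dim
      dx <- array(0, d)
      sel <- layer$size * cache$t2
      dx[, seq(1L, sel, by = 2L), ] <- dout * cache$first
      dx[, seq(2L, sel, by = 2L), ] <- dout * !cache$first
      list(dx = dx)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout)
      else list(dx = dout * cache$mask)
    },
    flatten = {
      dim(dout) <- cache$in_dim
      list(dx = dout)
    }
  )
}

.nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- .forward_layer(net$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(logits = x, caches = caches)
}

.softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# ---- Adam training ---------------------------------------------------------

#' Training configuration for neural networks
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.  The
#'   default `adam_beta2 = 0.999` is the standard value; `paper_adam =
#'   TRUE` restores 0.1, which effectively disables second-moment
#'   smoothing; it is retained only for strict reproduction of the procedure
#'   as printed (almost certainly a typographical value).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param paper_adam Use `adam_beta2 = 0.1`.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L, paper_adam = FALSE) {
  if (paper_adam) adam_beta2 <- 0.1
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

.adam_state <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

.adam_update <- function(net, state, grads, cfg, t) {
  lr <- cfg$learning_rate; b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  eps <- cfg$adam_eps
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    s <- state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

.subset_batch <- function(x, idx) {
  if (length(dim(x)) == 3L) x[idx, , , drop = FALSE]
  else x[idx, , drop = FALSE]
}

# Train `net` on inputs x (matrix or 3-D array) and integer class index y.
# Returns list(net, epoch_loss).
.nn_train <- function(net, x, y, cfg) {
  n <- if (length(dim(x)) == 3L) dim(x)[1] else nrow(x)
  stopifnot(n == length(y))
  n_classes <- net$n_classes
  onehot <- diag(n_classes)[y, , drop = FALSE]
  state <- .adam_state(net)
  epoch_loss <- numeric(cfg$epochs)
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      xb <- .subset_batch(x, idx)
      yb <- onehot[idx, , drop = FALSE]
      fw <- .nn_forward(net, xb, training = TRUE)
      p <- .softmax(fw$logits)
      loss <- -mean(log(pmax(rowSums(p * yb), 1e-12)))
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      losses <- c(losses, loss)
      dlogits <- (p - yb) / length(idx)
      grads <- vector("list", length(net$layers))
      dout <- dlogits
      for (i in rev(seq_along(net$layers))) {
        bw <- .backward_layer(net$layers[[i]], dout, fw$caches[[i]])
        grads[[i]] <- bw
        dout <- bw$dx
      }
      t_step <- t_step + 1L
      upd <- .adam_update(net, state, grads, cfg, t_step)
      net <- upd$net
      state <- upd$state
    }
    epoch_loss[ep] <- mean(losses)
  }
  list(net = net, epoch_loss = epoch_loss)
}

.nn_predict_proba <- function(net, x) {
  .softmax(.nn_forward(net, x, training = FALSE)$logits)
}
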