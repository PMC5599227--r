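# ---- PCA -------------------------------------------------------------------

test_that("PCA recovers dominant directions and centres the data", {
  set.seed(1)
  # points on a line: first component explains ~100% of the variance
  t <- rnorm(50)
  x <- cbind(3 * t, -2 * t) + matrix(rnorm(100, sd = 1e-6), 50)
  pc <- pca_fit(x, 2)
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.999999)
  # the fitted mean projects to zero
  expect_equal(unname(pca_transform(matrix(colMeans(x), 1), pc)[1, ]),
               c(0, 0), tolerance = 1e-9)
})

test_that("PCA matches an eigendecomposition oracle and reconstruction
           error decreases with components", {
  set.seed(2)
  x <- matrix(rnorm(200), 20, 10) %*% diag(sqrt(10:1))
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  pc <- pca_fit(x, 10)
  expect_equal(pc$sdev^2, ev$values, tolerance = 1e-8)
  # columns match up to sign
  for (j in 1:10) {
    expect_equal(min(sum(abs(pc$rotation[, j] - ev$vectors[, j])),
                     sum(abs(pc$rotation[, j] + ev$vectors[, j]))),
                 0, tolerance = 1e-6)
  }
  errs <- vapply(1:10, function(kk) {
    p <- pca_fit(x, kk)
    proj <- pca_transform(x, p)
    recon <- proj %*% t(p$rotation) +
      matrix(p$center, nrow(x), ncol(x), byrow = TRUE)
    sum((x - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_warning(pca_fit(x, 50), "reduced")
})

# ---- SVM -------------------------------------------------------------------

test_that("linear SVM separates separable clusters and is deterministic", {
  toy <- toy_clusters()
  m1 <- train_svm(toy$x, toy$labels, svm_spec(c_regularization = 1))
  expect_equal(mean(predict(m1, toy$x) == toy$labels), 1)
  m2 <- train_svm(toy$x, toy$labels, svm_spec(c_regularization = 1))
  expect_identical(m1$models, m2$models)
  expect_error(train_svm(toy$x, rep("rest", nrow(toy$x))), "two classes")
})

test_that("training accuracy does not decrease along an increasing C grid", {
  # moderately overlapping fixture; expected behaviour computed with this
  # exact seed/grid and frozen (monotonicity is a trend, not a theorem)
  toy <- toy_clusters(sep = 2.5, sd = 1.2, seed = 2)
  accs <- vapply(10^seq(-2, 2), function(C) {
    m <- train_svm(toy$x, toy$labels, svm_spec(c_regularization = C))
    mean(predict(m, toy$x) == toy$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
})

test_that("label permutation drives SVM accuracy to the class prior", {
  # 100 trials: small-sample permutation CV is biased slightly below the
  # prior, so allow the binomial band plus a small bias allowance
  trials <- fast_trials(seed = 3, n_experiments = 5)
  feats <- extract_feature_table(trials)
  set.seed(101)
  perm <- sample(trials$labels)
  rep_p <- cross_validate(svm_pipeline(), feats, perm, k = 5, seed = 1)
  n <- length(perm)
  band <- 1.96 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(rep_p$mean_accuracy - 0.5), band + 0.05)
})

# ---- ANN -------------------------------------------------------------------

test_that("ANN structures match the reference catalogue", {
  st <- ann_structures()
  expect_named(st, c("ANN1-a", "ANN1-b", "ANN1-c",
                     "ANN2-a", "ANN2-b", "ANN2-c"))
  expect_equal(st[["ANN2-a"]]$hidden_layers, c(256L, 128L))
  expect_equal(st[["ANN1-c"]]$hidden_layers, 512L)
})

test_that("untrained network outputs valid softmax probabilities", {
  net <- build_ann(ann_spec(16), n_inputs = 8, seed = 1)
  set.seed(2)
  p <- predict(net, matrix(rnorm(40), 5), type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-12)
  # zero-weight network -> uniform 1/3
  net0 <- net
  for (i in seq_along(net0$layers)) {
    if (!is.null(net0$layers[[i]]$W)) {
      net0$layers[[i]]$W[] <- 0
      net0$layers[[i]]$b[] <- 0
    }
  }
  p0 <- predict(net0, matrix(rnorm(24), 3), type = "prob")
  expect_equal(unname(p0), matrix(1 / 3, 3, 3), tolerance = 1e-12)
})

test_that("ANN fits separable feature vectors", {
  toy <- toy_clusters(n_per_class = 67, d = 20, sep = 5, seed = 6)
  cfg <- train_config(epochs = 100, batch_size = 32,
                      learning_rate = 1e-3, seed = 1)
  m <- train_ann(toy$x, toy$labels, ann_structures()[["ANN1-a"]], cfg)
  expect_gte(mean(predict(m, toy$x) == toy$labels), 0.95)
  # loss trend decreases (median over epoch halves)
  expect_lt(median(tail(m$epoch_loss, 20)), median(head(m$epoch_loss, 20)))
})

test_that("training is seed-deterministic", {
  toy <- toy_clusters(n_per_class = 10, d = 6)
  cfg <- train_config(epochs = 5, batch_size = 8, seed = 42)
  m1 <- train_ann(toy$x, toy$labels, ann_spec(8), cfg)
  m2 <- train_ann(toy$x, toy$labels, ann_spec(8), cfg)
  expect_identical(m1$layers, m2$layers)
  set.seed(77)  # prediction must not depend on the RNG
  p1 <- predict(m1, toy$x, type = "prob")
  p2 <- predict(m1, toy$x, type = "prob")
  expect_identical(p1, p2)
})

# ---- CNN -------------------------------------------------------------------

test_that("CNN catalogue and ReLU behave as specified", {
  st <- cnn_structures()
  expect_equal(st[["CNN2-a"]]$conv_filters, c(32L, 32L, 32L))
  expect_equal(st[["CNN1-b"]]$conv_filters, 64L)
  # ReLU: a(-2) = 0, a(3) = 3 (via the engine layer)
  lay <- nirsbci:::.layer_relu()
  out <- nirsbci:::.forward_layer(lay, matrix(c(-2, 3), 1), FALSE)$out
  expect_equal(unname(out[1, ]), c(0, 3))
})

test_that("convolution equals a sliding dot-product oracle", {
  set.seed(10)
  B <- 2L; Tt <- 20L; C <- 4L; Fn <- 3L; k <- 3L
  x <- array(rnorm(B * Tt * C), c(B, Tt, C))
  layer <- nirsbci:::.layer_conv1d(C, Fn, k)
  out <- nirsbci:::.forward_layer(layer, x, FALSE)$out
  # oracle: o_i = sum over the kernel window of w * x[i:(i+k-1), ]
  # (valid positions; the layer's zero padding shifts indices by 1)
  for (b in seq_len(B)) {
    for (f in seq_len(Fn)) {
      wf <- matrix(layer$W[, f], nrow = C)  # C x k
      for (i in seq_len(Tt - k + 1L)) {
        o <- 0
        for (m in 0:(k - 1L)) {
          o <- o + sum(wf[, m + 1L] * x[b, i + m, ])
        }
        expect_equal(out[b, i + 1L, f], o + layer$b[1, f],
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("CNN gradients match numerical differentiation", {
  # tiny net, finite differences on a few random weights
  set.seed(11)
  x <- array(rnorm(3 * 8 * 2), c(3, 8, 2))
  y <- c(1L, 2L, 3L)
  spec <- cnn_spec(2, fc_widths = c(4L), output_classes = 3L)
  net <- build_cnn(spec, input_shape = c(8, 2), seed = 5)
  loss_of <- function(net) {
    p <- nirsbci:::.softmax(nirsbci:::.nn_forward(net, x, FALSE)$logits)
    -mean(log(p[cbind(1:3, y)]))
  }
  fw <- nirsbci:::.nn_forward(net, x, training = FALSE)
  p <- nirsbci:::.softmax(fw$logits)
  onehot <- diag(3)[y, ]
  dout <- (p - onehot) / 3
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- nirsbci:::.backward_layer(net$layers[[i]], dout, fw$caches[[i]])
    grads[[i]] <- bw
    dout <- bw$dx
  }
  eps <- 1e-6
  for (li in c(1L, 6L)) {           # conv layer and a dense layer
    W <- net$layers[[li]]$W
    for (probe in list(c(1L, 1L), c(nrow(W), ncol(W)))) {
      np <- net
      np$layers[[li]]$W[probe[1], probe[2]] <- W[probe[1], probe[2]] + eps
      nm <- net
      nm$layers[[li]]$W[probe[1], probe[2]] <- W[probe[1], probe[2]] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(grads[[li]]$dW[probe[1], probe[2]], num,
                   tolerance = 1e-5)
    }
  }
})

test_that("max-pooling halves odd lengths by floor", {
  set.seed(12)
  x <- array(rnorm(1 * 257 * 2), c(1, 257, 2))
  out <- nirsbci:::.forward_layer(nirsbci:::.layer_maxpool(), x, FALSE)$out
  expect_equal(dim(out), c(1, 128, 2))
  expect_equal(out[1, 1, 1], max(x[1, 1:2, 1]))
  expect_equal(out[1, 128, 2], max(x[1, 255:256, 2]))  # 257th dropped
})

test_that("CNN learns a trivially separable trial set", {
  set.seed(13)
  n <- 60L
  x <- array(rnorm(n * 32 * 4, sd = 0.1), c(n, 32, 4))
  lab <- rep(task_levels(), each = 20)
  x[lab == "right", , 1] <- x[lab == "right", , 1] + 2
  x[lab == "left", , 2] <- x[lab == "left", , 2] + 2
  m <- train_cnn(x, lab, cnn_spec(8, fc_widths = c(16L, 8L)),
                 train_config(epochs = 30, batch_size = 16, seed = 3))
  expect_gte(mean(predict(m, x) == lab), 0.95)
  expect_true(all(is.finite(m$epoch_loss)))
  m2 <- train_cnn(x, lab, cnn_spec(8, fc_widths = c(16L, 8L)),
                  train_config(epochs = 30, batch_size = 16, seed = 3))
  expect_identical(m$layers, m2$layers)
  expect_error(predict(m, array(0, c(2, 10, 4))), "shape")
})
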