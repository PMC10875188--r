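# The network kernel is authored in-package, so its backpropagation is
# verified against finite differences, layer by layer, on small networks.

numeric_grad <- function(net, x, y, loss_fun, li, nm, ij, eps = 1e-5) {
  f <- function(v) {
    n2 <- net
    n2$layers[[li]][[nm]][ij] <- v
    loss_fun(nn_forward(n2, x, train = FALSE)$out)
  }
  v0 <- net$layers[[li]][[nm]][ij]
  (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
}

max_grad_err <- function(net, x, y, loss_fun, grads) {
  err <- 0
  for (li in seq_along(net$layers)) {
    for (nm in intersect(c("W", "b", "Wx", "Wh"), names(net$layers[[li]]))) {
      if (is.null(net$layers[[li]][[nm]])) next
      for (ij in unique(c(1L, length(net$layers[[li]][[nm]])))) {
        ng <- numeric_grad(net, x, y, loss_fun, li, nm, ij)
        ag <- grads[[li]][[nm]][ij]
        err <- max(err, abs(ng - ag) / max(1e-8, abs(ng) + abs(ag)))
      }
    }
  }
  err
}

test_that("backpropagation matches finite differences through conv, pool, LSTM and dense layers", {
  set.seed(1)
  net <- nn_build(list(layer_conv1d(3, 3), layer_maxpool(4L), layer_lstm(4),
                       layer_dense(5), layer_dense(3, activation = "linear")),
                  input_len = 16, head = "softmax", seed = 2)
  x <- matrix(rnorm(4 * 16), 4, 16)
  y <- c(0L, 1L, 2L, 0L)
  fwd <- nn_forward(net, x, train = FALSE)
  ls <- softmax_xent(fwd$out, y)
  grads <- nn_backward(net, fwd, ls$grad)
  err <- max_grad_err(net, x, y, function(out) softmax_xent(out, y)$loss, grads)
  expect_lt(err, 1e-6)
})

test_that("backpropagation matches finite differences for the cosine sequence head", {
  set.seed(2)
  net <- nn_build(list(layer_conv1d(4, 3), layer_conv1d(1, 3, activation = "linear")),
                  input_len = 10, head = "cosine", seed = 3)
  x <- matrix(rnorm(3 * 10), 3, 10)
  tg <- matrix(0, 3, 10); tg[cbind(1:3, c(2, 5, 9))] <- 1
  fwd <- nn_forward(net, x, train = FALSE)
  ls <- cosine_loss(fwd$out, tg)
  grads <- nn_backward(net, fwd, ls$grad)
  err <- max_grad_err(net, x, NULL, function(out) cosine_loss(out, tg)$loss, grads)
  expect_lt(err, 1e-6)
})

test_that("dropout is active only in training mode", {
  m <- build_model(seed = 4)
  x <- matrix(rnorm(2 * 300), 2, 300)
  o1 <- nn_forward(m$net, x, train = FALSE)$out
  o2 <- nn_forward(m$net, x, train = FALSE)$out
  expect_identical(o1, o2)  # inference is deterministic
  set.seed(5); t1 <- nn_forward(m$net, x, train = TRUE)$out
  set.seed(6); t2 <- nn_forward(m$net, x, train = TRUE)$out
  expect_false(identical(t1, t2))  # dropout masks differ
})

test_that("classifier outputs are valid probability vectors for arbitrary input", {
  m <- build_model(seed = 7)
  set.seed(8)
  x <- matrix(rnorm(5 * 300, sd = 10), 5, 300)
  pr <- predict_steps(m, x)
  pcols <- grep("^p_", names(pr))
  expect_true(all(as.matrix(pr[, pcols]) >= 0))
  expect_equal(rowSums(pr[, pcols]), rep(1, 5), tolerance = 1e-6)
})

test_that("a perfectly aligned output attains the maximal cosine similarity", {
  tg <- matrix(0, 2, 20); tg[cbind(1:2, c(3, 17))] <- 1
  ls <- cosine_loss(tg * 5, tg)   # parallel vectors
  expect_equal(ls$loss, -1, tolerance = 1e-9)
  expect_equal(ls$cos, c(1, 1), tolerance = 1e-9)
})

test_that("Adam training reduces the loss on a separable toy problem", {
  set.seed(9)
  net <- nn_build(list(layer_dense(8), layer_dense(2, activation = "linear")),
                  input_len = 4, head = "softmax", seed = 10)
  x <- rbind(matrix(rnorm(160, 2), 40, 4), matrix(rnorm(160, -2), 40, 4))
  y <- rep(c(0L, 1L), each = 40)
  fit <- nn_train(net, x, y, epochs = 30, batch_size = 16, lr = 1e-2, seed = 11)
  expect_lt(utils::tail(fit$history$train_loss, 1), 0.1)
  expect_lt(utils::tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("checkpoint files update only when validation improves", {
  set.seed(12)
  net <- nn_build(list(layer_dense(4), layer_dense(2, activation = "linear")),
                  input_len = 3, head = "softmax", seed = 13)
  x <- matrix(rnorm(60 * 3), 60, 3); y <- rep(c(0L, 1L), 30)
  xv <- matrix(rnorm(20 * 3), 20, 3); yv <- rep(c(0L, 1L), 10)
  ck <- tempfile(fileext = ".rds")
  fit <- nn_train(net, x, y, xv, yv, epochs = 3, batch_size = 16, lr = 1e-3,
                  seed = 14, checkpoint_path = ck)
  expect_true(file.exists(ck))
  best <- readRDS(ck)
  # the checkpoint holds the best-on-validation weights, not the last ones
  pv <- nn_predict(best, xv)
  expect_equal(mean(max.col(pv) - 1L == yv), fit$best_metric)
  unlink(ck)
})

test_that("training aborts with a status when the loss turns non-finite", {
  net <- nn_build(list(layer_dense(4), layer_dense(2, activation = "linear")),
                  input_len = 3, head = "softmax", seed = 15)
  x <- matrix(rnorm(40 * 3), 40, 3); y <- rep(c(0L, 1L), 20)
  x[1, 1] <- NaN
  expect_error(nn_train(net, x, y, epochs = 2, batch_size = 40, lr = 1e-3, seed = 16),
               "diverged")
})
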