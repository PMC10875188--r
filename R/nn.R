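# Minimal dense/convolutional/recurrent network kernel.
#
# Activations flow as arrays [time, batch, channels] through convolutional
# and pooling layers, and as matrices [batch, features] through recurrent
# and dense layers. All heavy lifting is BLAS matrix products (im2col for
# convolutions), so training small sequence models is practical on one CPU.
# Training uses Adam with backpropagation (through time for the LSTM).

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
glorot_init <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

layer_conv1d <- function(filters, kernel, activation = "relu") {
  stopifnot(kernel %% 2L == 1L)
  list(type = "conv1d", filters = filters, kernel = kernel,
       activation = activation, W = NULL, b = NULL)
}
layer_maxpool <- function(pool = 2L) list(type = "maxpool", pool = pool)
layer_lstm <- function(units) list(type = "lstm", units = units,
                                   Wx = NULL, Wh = NULL, b = NULL)
layer_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate)
layer_dense <- function(units, activation = "relu")
  list(type = "dense", units = units, activation = activation, W = NULL, b = NULL)

#' Build a sequential network
#'
#' @param layers List of layer specs (internal constructors).
#' @param input_len Input sequence length.
#' @param head `"softmax"` (classification, cross-entropy) or `"cosine"`
#'   (sequence regression against multi-hot targets, cosine-similarity
#'   loss).
#' @param seed Seed for weight initialization.
#' @return An `"nn_model"` list.
#' @keywords internal
nn_build <- function(layers, input_len, head = c("softmax", "cosine"), seed = 1L) {
  head <- match.arg(head)
  set.seed(seed)
  t_len <- input_len
  # a network starting with a dense layer consumes the flat input directly
  input_dense <- layers[[1]]$type == "dense"
  ch <- if (input_dense) input_len else 1L
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv1d") {
      fan_in <- ly$kernel * ch
      ly$W <- he_init(fan_in, ly$filters, fan_in)
      ly$b <- numeric(ly$filters)
      ch <- ly$filters
    } else if (ly$type == "maxpool") {
      t_len <- t_len %/% ly$pool
    } else if (ly$type == "lstm") {
      H <- ly$units
      ly$Wx <- glorot_init(ch, 4L * H)
      ly$Wh <- glorot_init(H, 4L * H)
      ly$b <- numeric(4L * H)
      ly$b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      ch <- H
      t_len <- 1L  # sequence collapsed to the final hidden state
    } else if (ly$type == "dense") {
      ly$W <- he_init(ch, ly$units, ch)
      ly$b <- numeric(ly$units)
      ch <- ly$units
    }
    layers[[i]] <- ly
  }
  structure(list(layers = layers, input_len = input_len, head = head,
                 out_dim = ch, input_dense = input_dense, seed = seed),
            class = "nn_model")
}

#' Number of trainable parameters of a network
#' @param model An `"nn_model"` (or a wrapper with a `$net` field).
#' @return Integer parameter count.
#' @export
nn_count_params <- function(model) {
  if (!inherits(model, "nn_model") && !is.null(model$net)) model <- model$net
  sum(vapply(model$layers, function(ly)
    sum(lengths(lapply(ly[c("W", "b", "Wx", "Wh")], function(m) m %||% numeric(0)))),
    numeric(1)))
}

sigm <- function(x) 1 / (1 + exp(-x))
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Activations flow through conv/pool layers as matrices [T*B, C] with the
# time index fastest (row (t, b) = t + (b-1)*T), which keeps every heavy
# operation a plain BLAS matrix product or an indexed copy. The index
# vectors for shifted/strided row gathers depend only on (T, B, k) and are
# memoised per session.
.nn_idx_cache <- new.env(parent = emptyenv())

shift_rows <- function(T, B, off) {
  key <- paste0("s", T, "_", B, "_", off)
  v <- .nn_idx_cache[[key]]
  if (is.null(v)) {
    ts <- max(1L, 1L - off):min(T, T - off)
    dest <- as.vector(outer(ts, (0:(B - 1L)) * T, `+`))
    v <- list(dest = dest, src = dest + off)
    .nn_idx_cache[[key]] <- v
  }
  v
}

stride_rows <- function(T, B, p, j, To) {
  key <- paste0("p", T, "_", B, "_", p, "_", j)
  v <- .nn_idx_cache[[key]]
  if (is.null(v)) {
    v <- as.vector(outer(seq(j, by = p, length.out = To), (0:(B - 1L)) * T, `+`))
    .nn_idx_cache[[key]] <- v
  }
  v
}

batch_rows <- function(T, B, t) {
  key <- paste0("b", T, "_", B, "_", t)
  v <- .nn_idx_cache[[key]]
  if (is.null(v)) {
    v <- t + (0:(B - 1L)) * T
    .nn_idx_cache[[key]] <- v
  }
  v
}

# x: matrix [T*B, C] -> [T*B, k*C], zero padding at the time boundaries
im2col <- function(x, T, B, k) {
  C <- ncol(x)
  pl <- (k - 1L) %/% 2L
  out <- matrix(0, T * B, k * C)
  for (j in seq_len(k)) {
    ix <- shift_rows(T, B, j - pl - 1L)
    out[ix$dest, ((j - 1L) * C + 1L):(j * C)] <- x[ix$src, ]
  }
  out
}

col2im <- function(dXcol, T, B, C, k) {
  pl <- (k - 1L) %/% 2L
  dx <- matrix(0, T * B, C)
  for (j in seq_len(k)) {
    ix <- shift_rows(T, B, j - pl - 1L)
    dx[ix$src, ] <- dx[ix$src, ] + dXcol[ix$dest, ((j - 1L) * C + 1L):(j * C)]
  }
  dx
}

nn_forward <- function(model, xb, train = FALSE) {
  # xb: matrix [B, input_len]
  B <- nrow(xb)
  T <- model$input_len
  if (isTRUE(model$input_dense)) {
    a <- xb                         # flat [B, features] input
    T <- 1L
  } else {
    a <- matrix(t(xb), T * B, 1L)   # [T*B, 1], time fastest
  }
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv1d") {
      Xcol <- im2col(a, T, B, ly$kernel)
      Z <- add_bias(Xcol %*% ly$W, ly$b)
      if (ly$activation == "relu") {
        mask <- Z > 0
        Z <- Z * mask
      } else mask <- NULL
      caches[[i]] <- list(Xcol = Xcol, mask = mask, T = T, B = B, C = ncol(a))
      a <- Z
    } else if (ly$type == "maxpool") {
      p <- ly$pool; To <- T %/% p
      mx <- a[stride_rows(T, B, p, 1L, To), , drop = FALSE]
      am <- matrix(1L, nrow(mx), ncol(mx))
      for (j in 2:p) {
        xj <- a[stride_rows(T, B, p, j, To), , drop = FALSE]
        upd <- xj > mx
        mx[upd] <- xj[upd]
        am[upd] <- j
      }
      caches[[i]] <- list(argmax = am, Tin = T, B = B)
      a <- mx
      T <- To
    } else if (ly$type == "lstm") {
      H <- ly$units; C <- ncol(a)
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      steps <- vector("list", T)
      for (t in seq_len(T)) {
        xt <- a[batch_rows(T, B, t), , drop = FALSE]
        z <- add_bias(xt %*% ly$Wx + h %*% ly$Wh, ly$b)
        ig <- sigm(z[, 1:H, drop = FALSE])
        fg <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
        gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        og <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
        c_prev <- cc; h_prev <- h
        cc <- fg * c_prev + ig * gg
        h <- og * tanh(cc)
        steps[[t]] <- list(xt = xt, i = ig, f = fg, g = gg, o = og,
                           c = cc, c_prev = c_prev, h_prev = h_prev)
      }
      caches[[i]] <- list(steps = steps, T = T, Cin = C)
      a <- h  # [B, H]
      T <- 1L
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        mask <- matrix(stats::runif(length(a)) >= ly$rate, nrow(a), ncol(a)) /
          (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly$type == "dense") {
      Z <- add_bias(a %*% ly$W, ly$b)
      if (ly$activation == "relu") {
        mask <- Z > 0; Zout <- Z * mask
      } else { mask <- NULL; Zout <- Z }
      caches[[i]] <- list(a_in = a, mask = mask)
      a <- Zout
    }
  }
  if (ncol(a) == 1L && nrow(a) == T * B && T > 1L) {
    # sequence output (position network): [T*B, 1] -> [B, T]
    a <- t(matrix(a, T, B))
  }
  list(out = a, caches = caches, T_out = T, B = B)
}

nn_backward <- function(model, fwd, dout) {
  grads <- vector("list", length(model$layers))
  d <- dout
  seq_head <- fwd$T_out > 1L
  if (seq_head) d <- matrix(t(d), ncol = 1L)   # [B, T] -> [T*B, 1]
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$type == "dense") {
      if (!is.null(cache$mask)) d <- d * cache$mask
      grads[[i]] <- list(W = crossprod(cache$a_in, d), b = colSums(d))
      d <- d %*% t(ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
      grads[[i]] <- list()
    } else if (ly$type == "lstm") {
      T <- cache$T; H <- ly$units; B <- nrow(d)
      dWx <- matrix(0, nrow(ly$Wx), ncol(ly$Wx))
      dWh <- matrix(0, nrow(ly$Wh), ncol(ly$Wh))
      db <- numeric(4L * H)
      dx <- matrix(0, T * B, cache$Cin)
      dh <- d; dc <- matrix(0, B, H)
      for (t in rev(seq_len(T))) {
        st <- cache$steps[[t]]
        tc <- tanh(st$c)
        do_ <- dh * tc
        dc <- dc + dh * st$o * (1 - tc^2)
        di <- dc * st$g
        df <- dc * st$c_prev
        dg <- dc * st$i
        dc <- dc * st$f
        dz <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do_ * st$o * (1 - st$o))
        dWx <- dWx + crossprod(st$xt, dz)
        dWh <- dWh + crossprod(st$h_prev, dz)
        db <- db + colSums(dz)
        dh <- dz %*% t(ly$Wh)
        dx[batch_rows(T, B, t), ] <- dz %*% t(ly$Wx)
      }
      grads[[i]] <- list(Wx = dWx, Wh = dWh, b = db)
      d <- dx
    } else if (ly$type == "maxpool") {
      am <- cache$argmax
      T <- cache$Tin; B <- cache$B; p <- ly$pool
      To <- T %/% p
      dup <- matrix(0, T * B, ncol(am))
      for (j in seq_len(p)) {
        dup[stride_rows(T, B, p, j, To), ] <- d * (am == j)
      }
      grads[[i]] <- list()
      d <- dup
    } else if (ly$type == "conv1d") {
      dZ <- d
      if (!is.null(cache$mask)) dZ <- dZ * cache$mask
      grads[[i]] <- list(W = crossprod(cache$Xcol, dZ), b = colSums(dZ))
      d <- col2im(dZ %*% t(ly$W), cache$T, cache$B, cache$C, ly$kernel)
    }
  }
  grads
}

# ---- losses ----------------------------------------------------------------

softmax_xent <- function(logits, labels) {
  # labels: integer vector in 0..K-1
  B <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, grad = dp / B, prob = p)
}

#' Cosine-similarity loss for multi-hot targets
#'
#' `loss = -mean(cos(y, t))`; a perfect (parallel) output reaches -1.
#' @param y Output matrix (rows = samples).
#' @param target Multi-hot target matrix.
#' @return List with `loss` and `grad`.
#' @export
cosine_loss <- function(y, target) {
  ny <- sqrt(rowSums(y^2)) + 1e-12
  nt <- sqrt(rowSums(target^2)) + 1e-12
  cs <- rowSums(y * target) / (ny * nt)
  B <- nrow(y)
  grad <- -(target / (ny * nt) - (cs / ny^2) * y) / B
  list(loss = -mean(cs), grad = grad, cos = cs)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    nm <- intersect(c("W", "b", "Wx", "Wh"), names(ly))
    nm <- nm[!vapply(ly[nm], is.null, logical(1))]
    stats::setNames(lapply(nm, function(n) {
      list(m = ly[[n]] * 0, v = ly[[n]] * 0)
    }), nm)
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (!length(g)) next
    for (n in names(g)) {
      st <- state[[i]][[n]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[n]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[n]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      model$layers[[i]][[n]] <- model$layers[[i]][[n]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[n]] <- st
    }
  }
  list(model = model, state = state)
}

# ---- training loop ---------------------------------------------------------

#' Train a network with Adam
#'
#' Mini-batch training with per-epoch validation; weights are kept (and,
#' if `checkpoint_path` is given, saved) only when the validation metric
#' improves, so the returned model is the best-on-validation one.
#'
#' @param model An `"nn_model"`.
#' @param x Training inputs, matrix `[n, input_len]`.
#' @param y Integer labels (softmax head) or target matrix (cosine head).
#' @param x_val,y_val Validation set.
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Seed controlling shuffling and dropout masks.
#' @param checkpoint_path Optional RDS path updated on improvement.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best weights), `history` (per-epoch loss /
#'   metric), `best_metric`.
#' @keywords internal
nn_train <- function(model, x, y, x_val = NULL, y_val = NULL,
                     epochs = 5L, batch_size = 256L, lr = 1e-4,
                     seed = 1L, checkpoint_path = NULL, verbose = FALSE) {
  set.seed(seed)
  n <- nrow(x)
  state <- adam_init(model)
  tstep <- 0L
  classif <- model$head == "softmax"
  best <- if (classif) -Inf else Inf
  best_model <- model
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_metric = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      if (length(idx) < 2L) next
      fwd <- nn_forward(model, x[idx, , drop = FALSE], train = TRUE)
      ls <- if (classif) softmax_xent(fwd$out, y[idx])
            else cosine_loss(fwd$out, y[idx, , drop = FALSE])
      if (!is.finite(ls$loss)) stop("training diverged: non-finite loss")
      losses <- c(losses, ls$loss)
      grads <- nn_backward(model, fwd, ls$grad)
      tstep <- tstep + 1L
      upd <- adam_step(model, grads, state, lr, tstep)
      model <- upd$model; state <- upd$state
    }
    vm <- NA_real_
    if (!is.null(x_val)) {
      pv <- nn_predict(model, x_val)
      if (classif) {
        vm <- mean(max.col(pv) - 1L == y_val)   # validation accuracy
        improved <- vm > best
      } else {
        vm <- cosine_loss(pv, y_val)$loss       # validation loss
        improved <- vm < best
      }
      if (improved) {
        best <- vm
        best_model <- model
        if (!is.null(checkpoint_path)) saveRDS(model, checkpoint_path)
      }
    } else best_model <- model
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_metric = vm))
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f  val %.4f", ep, epochs,
                      mean(losses), vm))
    }
  }
  list(model = best_model, history = hist, best_metric = best)
}

# batched inference (dropout inert)
nn_predict <- function(model, x, batch_size = 512L) {
  n <- nrow(x)
  out <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    o <- nn_forward(model, x[idx, , drop = FALSE], train = FALSE)$out
    if (is.null(out)) out <- matrix(0, n, ncol(o))
    out[idx, ] <- o
  }
  out
}
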