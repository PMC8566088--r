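# Minimal batched neural-network machinery for the window classifiers:
# a small convolutional network and a single-layer LSTM, both trained with
# Adam on softmax cross-entropy. Written with plain array arithmetic; the
# convolutions are accumulated over kernel offsets, which keeps everything
# vectorized over the batch and spatial dimensions.

# ---- shared helpers --------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# run fn with a private RNG stream seeded by `seed`
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  set.seed(seed)
  fn()
}

onehot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# ---- convolutional network -------------------------------------------------

# Layer plan for a T x C window (defaults T = 30 frames, C = 10 channels):
#   C1: n1 kernels k1_h x k1_w (valid)      -> (T-k1_h+1) x (C-k1_w+1) x n1
#   S1: average pooling p x 1               -> halve the time axis
#   C2: n2 kernels k2_h x k2_w per map      -> maps multiply to n1*n2
#   S2: average pooling p x 1
#   softmax over the flattened features
# With the default config (5 kernels 5x2, pool 2x1, 8 kernels 4x2, pool
# 2x1) the shapes are 30x10 -> 26x9x5 -> 13x9x5 -> 10x8x40 -> 5x8x40.
cnn_shape_plan <- function(input_h = 30L, input_w = 10L, hyper = list()) {
  h <- cnn_hyper(hyper)
  c1_h <- input_h - h$k1[1] + 1L
  c1_w <- input_w - h$k1[2] + 1L
  if (c1_h < 1L || c1_w < 1L) stop("C1 kernel larger than input")
  if (c1_h %% h$pool != 0L) {
    stop("C1 output height ", c1_h, " not divisible by pooling ratio ", h$pool)
  }
  s1_h <- c1_h %/% h$pool
  c2_h <- s1_h - h$k2[1] + 1L
  c2_w <- c1_w - h$k2[2] + 1L
  if (c2_h < 1L || c2_w < 1L) stop("C2 kernel larger than its input")
  if (c2_h %% h$pool != 0L) {
    stop("C2 output height ", c2_h, " not divisible by pooling ratio ", h$pool)
  }
  s2_h <- c2_h %/% h$pool
  maps <- h$n1 * h$n2
  list(input = c(input_h, input_w),
       c1 = c(c1_h, c1_w, h$n1), s1 = c(s1_h, c1_w, h$n1),
       c2 = c(c2_h, c2_w, maps), s2 = c(s2_h, c2_w, maps),
       n_features = s2_h * c2_w * maps)
}

cnn_hyper <- function(hyper) {
  defaults <- list(n1 = 5L, k1 = c(5L, 2L), n2 = 8L, k2 = c(4L, 2L),
                   pool = 2L, lr = 1e-3, epochs = 40L, batch = 32L)
  utils::modifyList(defaults, hyper)
}

cnn_init <- function(n_classes, input_h, input_w, hyper, seed) {
  h <- cnn_hyper(hyper)
  plan <- cnn_shape_plan(input_h, input_w, h)
  with_seed(seed, function() {
    sc1 <- sqrt(2 / prod(h$k1))
    sc2 <- sqrt(2 / prod(h$k2))
    list(W1 = array(rnorm(prod(h$k1) * h$n1, sd = sc1), c(h$k1, h$n1)),
         b1 = numeric(h$n1),
         W2 = array(rnorm(prod(h$k2) * h$n2, sd = sc2), c(h$k2, h$n2)),
         b2 = numeric(h$n2),
         W3 = matrix(rnorm(plan$n_features * n_classes,
                           sd = sqrt(1 / plan$n_features)),
                     plan$n_features, n_classes),
         b3 = numeric(n_classes))
  })
}

# Valid convolutions as patch-matrix products (im2col): a batch array
# (nb x H x W) becomes a ((nb*oh*ow) x (kh*kw)) patch matrix whose product
# with the flattened kernel bank applies every kernel at once. Column
# order matches the column-major layout of the kernel arrays.
im2col <- function(A, kh, kw, oh, ow) {
  nb <- dim(A)[1]
  P <- matrix(0, nb * oh * ow, kh * kw)
  col <- 0L
  for (v in seq_len(kw)) {
    for (u in seq_len(kh)) {
      col <- col + 1L
      P[, col] <- A[, u:(u + oh - 1L), v:(v + ow - 1L), drop = FALSE]
    }
  }
  P
}

# scatter-add patch-matrix gradients back onto the input array
col2im <- function(dP, kh, kw, nb, H, W, oh, ow) {
  out <- array(0, c(nb, H, W))
  col <- 0L
  for (v in seq_len(kw)) {
    for (u in seq_len(kh)) {
      col <- col + 1L
      out[, u:(u + oh - 1L), v:(v + ow - 1L)] <-
        out[, u:(u + oh - 1L), v:(v + ow - 1L)] +
        array(dP[, col], c(nb, oh, ow))
    }
  }
  out
}

# average non-overlapping blocks of p rows along the time axis (dim 2)
pool_avg <- function(A, p) {
  hdim <- dim(A)[2]
  idx <- seq(1L, hdim, by = p)
  acc <- A[, idx, , , drop = FALSE] * 0
  for (r in seq_len(p)) acc <- acc + A[, idx + r - 1L, , , drop = FALSE]
  acc / p
}

unpool_avg <- function(dP, p, out_h) {
  d <- dim(dP)
  out <- array(0, c(d[1], out_h, d[3], d[4]))
  idx <- seq(1L, out_h, by = p)
  for (r in seq_len(p)) out[, idx + r - 1L, , ] <- dP / p
  out
}

cnn_forward_full <- function(params, X, hyper, plan) {
  h <- cnn_hyper(hyper)
  n <- dim(X)[1]
  # C1 + tanh, then pool
  cols1 <- im2col(X, h$k1[1], h$k1[2], plan$c1[1], plan$c1[2])
  Z1 <- sweep(cols1 %*% matrix(params$W1, prod(h$k1), h$n1), 2,
              params$b1, "+")
  A1 <- array(tanh(Z1), c(n, plan$c1[1], plan$c1[2], h$n1))
  P1 <- pool_avg(A1, h$pool)
  # fold the n1 maps into the batch dimension: (n, h, w, n1) -> (n*n1, h, w)
  B1 <- aperm(P1, c(1, 4, 2, 3))
  dim(B1) <- c(n * h$n1, plan$s1[1], plan$s1[2])
  # C2 + tanh (each kernel applied to every map -> n1*n2 maps), then pool
  cols2 <- im2col(B1, h$k2[1], h$k2[2], plan$c2[1], plan$c2[2])
  Z2 <- sweep(cols2 %*% matrix(params$W2, prod(h$k2), h$n2), 2,
              params$b2, "+")
  A2 <- array(tanh(Z2), c(n * h$n1, plan$c2[1], plan$c2[2], h$n2))
  P2 <- pool_avg(A2, h$pool)
  dim(P2) <- c(n, h$n1 * plan$s2[1] * plan$s2[2] * h$n2)
  logits <- sweep(P2 %*% params$W3, 2, params$b3, "+")
  list(cols1 = cols1, A1 = A1, cols2 = cols2, A2 = A2, features = P2,
       probs = softmax_rows(logits))
}

cnn_backward <- function(params, X, Y, fwd, hyper, plan) {
  h <- cnn_hyper(hyper)
  n <- dim(X)[1]
  dlogits <- (fwd$probs - Y) / n
  gW3 <- crossprod(fwd$features, dlogits)
  gb3 <- colSums(dlogits)
  dF <- tcrossprod(dlogits, params$W3)
  dP2 <- array(dF, c(n * h$n1, plan$s2[1], plan$s2[2], h$n2))
  dZ2 <- unpool_avg(dP2, h$pool, plan$c2[1]) * (1 - fwd$A2^2)
  dZ2m <- matrix(dZ2, ncol = h$n2)
  gW2 <- array(crossprod(fwd$cols2, dZ2m), dim(params$W2))
  gb2 <- colSums(dZ2m)
  dB1 <- col2im(tcrossprod(dZ2m, matrix(params$W2, prod(h$k2), h$n2)),
                h$k2[1], h$k2[2], n * h$n1, plan$s1[1], plan$s1[2],
                plan$c2[1], plan$c2[2])
  dim(dB1) <- c(n, h$n1, plan$s1[1], plan$s1[2])
  dP1 <- aperm(dB1, c(1, 3, 4, 2))
  dZ1 <- unpool_avg(dP1, h$pool, plan$c1[1]) * (1 - fwd$A1^2)
  dZ1m <- matrix(dZ1, ncol = h$n1)
  gW1 <- array(crossprod(fwd$cols1, dZ1m), dim(params$W1))
  gb1 <- colSums(dZ1m)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

cnn_train <- function(X, y, n_classes, hyper = list(), seed = 1L) {
  h <- cnn_hyper(hyper)
  plan <- cnn_shape_plan(dim(X)[2], dim(X)[3], h)
  params <- cnn_init(n_classes, dim(X)[2], dim(X)[3], h, seed)
  state <- adam_init(params)
  n <- dim(X)[1]
  Y <- onehot(y, n_classes)
  order_seq <- with_seed(seed + 1L, function() {
    lapply(seq_len(h$epochs), function(e) sample.int(n))
  })
  for (e in seq_len(h$epochs)) {
    ord <- order_seq[[e]]
    for (b0 in seq(1L, n, by = h$batch)) {
      idx <- ord[b0:min(b0 + h$batch - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fwd <- cnn_forward_full(params, Xb, h, plan)
      grads <- cnn_backward(params, Xb, Yb, fwd, h, plan)
      upd <- adam_step(params, grads, state, lr = h$lr)
      params <- upd$params
      state <- upd$state
    }
  }
  list(params = params, hyper = h, plan = plan, n_classes = n_classes)
}

cnn_predict <- function(model, X) {
  if (dim(X)[1] == 0L) return(integer(0))
  fwd <- cnn_forward_full(model$params, X, model$hyper, model$plan)
  max.col(fwd$probs, ties.method = "first")
}

# ---- LSTM ------------------------------------------------------------------

lstm_hyper <- function(hyper) {
  defaults <- list(hidden = 64L, lr = 1e-3, epochs = 30L, batch = 32L)
  utils::modifyList(defaults, hyper)
}

lstm_init <- function(n_in, n_classes, hyper, seed) {
  h <- lstm_hyper(hyper)
  H <- h$hidden
  with_seed(seed, function() {
    sc <- sqrt(1 / (n_in + H))
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
    list(Wx = matrix(rnorm(n_in * 4 * H, sd = sc), n_in, 4 * H),
         Wh = matrix(rnorm(H * 4 * H, sd = sc), H, 4 * H),
         b = b,
         Wy = matrix(rnorm(H * n_classes, sd = sqrt(1 / H)), H, n_classes),
         by = numeric(n_classes))
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

lstm_forward <- function(params, X, H) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  hs <- array(0, c(n, H, Tn + 1L))
  cs <- array(0, c(n, H, Tn + 1L))
  gates <- array(0, c(n, 4 * H, Tn))
  ig <- seq_len(H); fg <- H + ig; og <- 2 * H + ig; gg <- 3 * H + ig
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], nrow = n)
    z <- Xt %*% params$Wx + matrix(hs[, , t], nrow = n) %*% params$Wh
    z <- sweep(z, 2, params$b, "+")
    i <- sigmoid(z[, ig, drop = FALSE])
    f <- sigmoid(z[, fg, drop = FALSE])
    o <- sigmoid(z[, og, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    cs[, , t + 1L] <- f * matrix(cs[, , t], nrow = n) + i * g
    hs[, , t + 1L] <- o * tanh(matrix(cs[, , t + 1L], nrow = n))
    gates[, ig, t] <- i; gates[, fg, t] <- f
    gates[, og, t] <- o; gates[, gg, t] <- g
  }
  hT <- matrix(hs[, , Tn + 1L], nrow = n)
  logits <- sweep(hT %*% params$Wy, 2, params$by, "+")
  list(hs = hs, cs = cs, gates = gates,
       probs = softmax_rows(logits))
}

lstm_backward <- function(params, X, Y, fwd, H) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  ig <- seq_len(H); fg <- H + ig; og <- 2 * H + ig; gg <- 3 * H + ig
  dlogits <- (fwd$probs - Y) / n
  hT <- matrix(fwd$hs[, , Tn + 1L], nrow = n)
  gWy <- crossprod(hT, dlogits)
  gby <- colSums(dlogits)
  dh <- tcrossprod(dlogits, params$Wy)
  dc <- matrix(0, n, H)
  gWx <- params$Wx * 0; gWh <- params$Wh * 0; gb <- params$b * 0
  for (t in rev(seq_len(Tn))) {
    i <- fwd$gates[, ig, t, drop = TRUE]; dim(i) <- c(n, H)
    f <- fwd$gates[, fg, t, drop = TRUE]; dim(f) <- c(n, H)
    o <- fwd$gates[, og, t, drop = TRUE]; dim(o) <- c(n, H)
    g <- fwd$gates[, gg, t, drop = TRUE]; dim(g) <- c(n, H)
    ct <- matrix(fwd$cs[, , t + 1L], nrow = n)
    cprev <- matrix(fwd$cs[, , t], nrow = n)
    tct <- tanh(ct)
    dc <- dc + dh * o * (1 - tct^2)
    di <- dc * g
    df <- dc * cprev
    do_ <- dh * tct
    dg <- dc * i
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                do_ * o * (1 - o), dg * (1 - g^2))
    Xt <- matrix(X[, t, ], nrow = n)
    hprev <- matrix(fwd$hs[, , t], nrow = n)
    gWx <- gWx + crossprod(Xt, dz)
    gWh <- gWh + crossprod(hprev, dz)
    gb <- gb + colSums(dz)
    dh <- tcrossprod(dz, params$Wh)
    dc <- dc * f
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wy = gWy, by = gby)
}

lstm_train <- function(X, y, n_classes, hyper = list(), seed = 1L) {
  h <- lstm_hyper(hyper)
  params <- lstm_init(dim(X)[3], n_classes, h, seed)
  state <- adam_init(params)
  n <- dim(X)[1]
  Y <- onehot(y, n_classes)
  order_seq <- with_seed(seed + 1L, function() {
    lapply(seq_len(h$epochs), function(e) sample.int(n))
  })
  for (e in seq_len(h$epochs)) {
    ord <- order_seq[[e]]
    for (b0 in seq(1L, n, by = h$batch)) {
      idx <- ord[b0:min(b0 + h$batch - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fwd <- lstm_forward(params, Xb, h$hidden)
      grads <- lstm_backward(params, Xb, Yb, fwd, h$hidden)
      upd <- adam_step(params, grads, state, lr = h$lr)
      params <- upd$params
      state <- upd$state
    }
  }
  list(params = params, hyper = h, n_classes = n_classes)
}

lstm_predict <- function(model, X) {
  if (dim(X)[1] == 0L) return(integer(0))
  fwd <- lstm_forward(model$params, X, model$hyper$hidden)
  max.col(fwd$probs, ties.method = "first")
}
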