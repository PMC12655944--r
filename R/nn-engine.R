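# Minimal matrix-based neural-network engine used by the fusion CNN-LSTM and
# the MLP baselines. Forward/backward passes are written against base matrix
# algebra; all randomness (init, shuffling, dropout) draws from the R stream
# so that training is deterministic given a seed.

sigm <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
    relu = function(z) pmax(z, 0),
    tanh = function(z) tanh(z),
    elu  = function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    abort(sprintf("unknown activation '%s'", name)))
}

# derivative w.r.t. pre-activation z
act_grad <- function(name) {
  switch(name,
    relu = function(z) (z > 0) * 1,
    tanh = function(z) 1 - tanh(z)^2,
    elu  = function(z) ifelse(z > 0, 1, exp(pmin(z, 0))),
    abort(sprintf("unknown activation '%s'", name)))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- 1-D convolution over time ("same" padding, odd kernels) ----

im2col <- function(X, K) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; C <- d[3]
  pad <- (K - 1) %/% 2
  Xp <- array(0, c(B, Tn + 2 * pad, C))
  Xp[, pad + seq_len(Tn), ] <- X
  xcol <- matrix(0, B * Tn, K * C)
  for (k in seq_len(K)) {
    xcol[, ((k - 1) * C + 1):(k * C)] <-
      matrix(Xp[, k:(k + Tn - 1), , drop = FALSE], nrow = B * Tn)
  }
  xcol
}

conv1d_forward <- function(X, W, b, K) {
  d <- dim(X)
  xcol <- im2col(X, K)
  z <- xcol %*% W
  z <- sweep(z, 2, b, "+")
  list(z = array(z, c(d[1], d[2], ncol(W))), xcol = xcol, in_dim = d)
}

conv1d_backward <- function(cache, W, K, dz) {
  d <- cache$in_dim; B <- d[1]; Tn <- d[2]; C <- d[3]
  dzf <- matrix(dz, nrow = B * Tn)
  dW <- crossprod(cache$xcol, dzf)
  db <- colSums(dzf)
  dxcol <- tcrossprod(dzf, W)
  pad <- (K - 1) %/% 2
  dXp <- array(0, c(B, Tn + 2 * pad, C))
  for (k in seq_len(K)) {
    dXp[, k:(k + Tn - 1), ] <- dXp[, k:(k + Tn - 1), ] +
      array(dxcol[, ((k - 1) * C + 1):(k * C)], c(B, Tn, C))
  }
  list(dW = dW, db = db, dX = dXp[, pad + seq_len(Tn), , drop = FALSE])
}

# ---- non-overlapping max pooling over time ----

maxpool_forward <- function(X, p) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; F <- d[3]
  T2 <- Tn %/% p
  idx1 <- seq(1, T2 * p, by = p)
  out <- X[, idx1, , drop = FALSE]
  arg <- array(1L, dim(out))
  if (p > 1) {
    for (j in 2:p) {
      S <- X[, seq(j, T2 * p, by = p), , drop = FALSE]
      m <- S > out
      out[m] <- S[m]
      arg[m] <- j
    }
  }
  list(out = out, arg = arg, in_dim = d, p = p, T2 = T2)
}

maxpool_backward <- function(cache, dOut) {
  d <- cache$in_dim
  dX <- array(0, d)
  for (j in seq_len(cache$p)) {
    tmp <- dOut
    tmp[cache$arg != j] <- 0
    dX[, seq(j, cache$T2 * cache$p, by = cache$p), ] <- tmp
  }
  dX
}

# ---- LSTM (returns the full hidden sequence; gates ordered i, f, o, g) ----

lstm_init <- function(D, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(W = glorot(D, 4 * H), U = glorot(H, 4 * H), b = b)
}

lstm_forward <- function(X, par) {
  d <- dim(X); B <- d[1]; Tn <- d[2]
  H <- nrow(par$U)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hseq <- array(0, c(B, Tn, H))
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], nrow = B)
    a <- xt %*% par$W + h %*% par$U
    a <- sweep(a, 2, par$b, "+")
    i <- sigm(a[, 1:H, drop = FALSE])
    f <- sigm(a[, (H + 1):(2 * H), drop = FALSE])
    o <- sigm(a[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    steps[[t]] <- list(i = i, f = f, o = o, g = g,
                       c_prev = cc, tc = tc, h_prev = h)
    cc <- c_new
    h <- o * tc
    Hseq[, t, ] <- h
  }
  list(Hseq = Hseq, steps = steps, in_dim = d)
}

lstm_backward <- function(X, par, cache, dH) {
  d <- cache$in_dim; B <- d[1]; Tn <- d[2]
  H <- nrow(par$U)
  dW <- par$W * 0; dU <- par$U * 0; db <- par$b * 0
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dX <- array(0, d)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], nrow = B) + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    df <- dc * st$c_prev
    di <- dc * st$g
    dg <- dc * st$i
    dc_next <- dc * st$f
    da <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    xt <- matrix(X[, t, ], nrow = B)
    dW <- dW + crossprod(xt, da)
    dU <- dU + crossprod(st$h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(par$W)
    dh_next <- da %*% t(par$U)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# ---- heads ----

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class 1..K; returns loss and dlogits
softmax_ce <- function(logits, y) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(B), y)], eps)))
  Y <- matrix(0, B, ncol(logits))
  Y[cbind(seq_len(B), y)] <- 1
  list(loss = loss, dlogits = (p - Y) / B, p = p)
}

sigmoid_bce <- function(z, y) {
  B <- nrow(z)
  p <- sigm(z)
  eps <- 1e-12
  loss <- -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  list(loss = loss, dz = (p - y) / B, p = p)
}

# ---- optimizers (flat named lists of arrays) ----

opt_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

opt_step <- function(params, grads, state, optimizer, lr, t) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    if (optimizer == "adam") {
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      mh <- s$m / (1 - 0.9^t)
      vh <- s$v / (1 - 0.999^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
    } else if (optimizer == "rmsprop") {
      s$v <- 0.9 * s$v + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(s$v) + 1e-8)
    } else if (optimizer == "sgd") {
      params[[nm]] <- params[[nm]] - lr * g
    } else {
      abort(sprintf("unknown optimizer '%s'", optimizer))
    }
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
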