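# Minimal dense/convolutional/recurrent building blocks with hand-written
# backward passes. Everything operates on base R arrays in double precision:
# sequence batches are [n, W, C] arrays, per-step dense maps collapse the
# first two dims (column-major, so rows stay aligned) before a single matrix
# product. All backward passes are verified against numerical differentiation
# in the test suite.

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) pmax(z, 0)
lrelu <- function(z, a = 0.1) ifelse(z > 0, z, a * z)
drelu <- function(z) as.numeric(z > 0)
dlrelu <- function(z, a = 0.1) ifelse(z > 0, 1, a)

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

collapse2 <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

uncollapse2 <- function(m, n, t) {
  dim(m) <- c(n, t, ncol(m))
  m
}

# ---- 1D convolution along time (valid or causal, optional dilation) -------

conv1d_forward <- function(x, kernel, bias, dilation = 1L, causal = FALSE) {
  n <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  K <- nrow(kernel) / Cin
  pad <- if (causal) (K - 1L) * dilation else 0L
  if (pad > 0) {
    xp <- array(0, dim = c(n, W + pad, Cin))
    xp[, pad + seq_len(W), ] <- x
  } else {
    xp <- x
  }
  t_out <- dim(xp)[2] - (K - 1L) * dilation
  if (t_out < 1) stop_named("kernel span %d exceeds sequence length %d", (K - 1L) * dilation + 1L, W)
  Xc <- matrix(0, nrow = n * t_out, ncol = K * Cin)
  for (k in seq_len(K)) {
    sl <- xp[, (k - 1L) * dilation + seq_len(t_out), , drop = FALSE]
    dim(sl) <- c(n * t_out, Cin)
    Xc[, (k - 1L) * Cin + seq_len(Cin)] <- sl
  }
  out <- sweep(Xc %*% kernel, 2, bias, "+")
  dim(out) <- c(n, t_out, ncol(kernel))
  list(out = out, cache = list(Xc = Xc, n = n, W = W, Cin = Cin, K = K,
                               dilation = dilation, pad = pad, t_out = t_out))
}

conv1d_backward <- function(dout, kernel, cache) {
  n <- cache$n; t_out <- cache$t_out; Cin <- cache$Cin; K <- cache$K
  d2 <- dout
  dim(d2) <- c(n * t_out, ncol(kernel))
  dkernel <- crossprod(cache$Xc, d2)
  dbias <- colSums(d2)
  dXc <- d2 %*% t(kernel)
  dxp <- array(0, dim = c(n, cache$W + cache$pad, Cin))
  for (k in seq_len(K)) {
    piece <- dXc[, (k - 1L) * Cin + seq_len(Cin), drop = FALSE]
    dim(piece) <- c(n, t_out, Cin)
    idx <- (k - 1L) * cache$dilation + seq_len(t_out)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + piece
  }
  dx <- dxp[, cache$pad + seq_len(cache$W), , drop = FALSE]
  list(dx = dx, dkernel = dkernel, dbias = dbias)
}

# ---- batch normalization over feature columns ------------------------------

bn_forward <- function(x, gamma, beta, state, train, momentum = 0.9, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, state = state,
       cache = list(x = x, xhat = xhat, mu = mu, inv_sd = inv_sd, train = train))
}

bn_backward <- function(dout, gamma, cache) {
  n <- nrow(cache$x)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  if (!cache$train) {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  xc <- sweep(cache$x, 2, cache$mu)
  dvar <- colSums(dxhat * xc) * (-0.5) * cache$inv_sd^3
  dmu <- -colSums(sweep(dxhat, 2, cache$inv_sd, "*")) + dvar * (-2) * colMeans(xc)
  dx <- sweep(dxhat, 2, cache$inv_sd, "*") +
    sweep(xc, 2, 2 * dvar / n, "*") +
    matrix(dmu / n, n, length(dmu), byrow = TRUE)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- shared classification head: [features, demo] -> dense relu -> sigmoid -

head_init <- function(n_feat, n_demo, hidden, n_out) {
  list(
    head_W1 = glorot(n_feat + n_demo, hidden),
    head_b1 = numeric(hidden),
    head_W2 = glorot(hidden, n_out),
    head_b2 = numeric(n_out)
  )
}

head_forward <- function(params, feat, demo) {
  h_in <- cbind(feat, demo)
  z1 <- sweep(h_in %*% params$head_W1, 2, params$head_b1, "+")
  h1 <- relu(z1)
  logits <- sweep(h1 %*% params$head_W2, 2, params$head_b2, "+")
  list(prob = sigmoid(logits),
       cache = list(h_in = h_in, z1 = z1, h1 = h1, n_feat = ncol(feat)))
}

head_backward <- function(params, cache, dlogits) {
  dW2 <- crossprod(cache$h1, dlogits)
  db2 <- colSums(dlogits)
  dh1 <- dlogits %*% t(params$head_W2)
  dz1 <- dh1 * drelu(cache$z1)
  dW1 <- crossprod(cache$h_in, dz1)
  db1 <- colSums(dz1)
  dh_in <- dz1 %*% t(params$head_W1)
  list(
    grads = list(head_W1 = dW1, head_b1 = db1, head_W2 = dW2, head_b2 = db2),
    dfeat = dh_in[, seq_len(cache$n_feat), drop = FALSE]
  )
}

# ---- binary cross-entropy over all (sample, label) cells -------------------

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradient of mean BCE w.r.t. the pre-sigmoid logits.
bce_dlogits <- function(prob, y) (prob - y) / length(y)

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(params = params, opt = opt)
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
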