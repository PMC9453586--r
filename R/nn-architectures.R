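# Architecture-specific initialization, forward and backward passes. Every
# architecture maps a lab-value window [n, W, C] plus a static demographics
# matrix [n, D] to per-label probabilities [n, C] through the shared
# late-concatenation head (sequence features and demographics are merged only
# after the sequence encoder). The backward passes take d(loss)/d(logits) and
# return gradients for every parameter.

# ---- LSTM ------------------------------------------------------------------
# Single tanh LSTM layer; the last hidden state passes through batch
# normalization, is concatenated with demographics, and feeds the dense head.

lstm_init <- function(spec) {
  C <- spec$C; U <- spec$units
  params <- list(
    lstm_Wx = glorot(C, 4 * U),
    lstm_Wh = glorot(U, 4 * U),
    lstm_b = numeric(4 * U),
    bn_gamma = rep(1, U),
    bn_beta = numeric(U)
  )
  c(params, head_init(U, spec$D, spec$head_hidden, spec$C))
}

lstm_state_init <- function(spec) list(mean = numeric(spec$units), var = rep(1, spec$units))

lstm_forward <- function(params, state, x, demo, train) {
  n <- dim(x)[1]; W <- dim(x)[2]; U <- length(params$bn_gamma)
  h <- matrix(0, n, U); cc <- matrix(0, n, U)
  steps <- vector("list", W)
  gi <- seq_len(U); gf <- U + gi; go <- 2 * U + gi; gg <- 3 * U + gi
  for (t in seq_len(W)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(n, dim(x)[3])
    z <- sweep(xt %*% params$lstm_Wx + h %*% params$lstm_Wh, 2, params$lstm_b, "+")
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE]); g <- tanh(z[, gg, drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c_prev, i = i, f = f,
                       o = o, g = g, c = cc, tc = tc)
    h <- o * tc
  }
  bn <- bn_forward(h, params$bn_gamma, params$bn_beta, state, train)
  hd <- head_forward(params, bn$out, demo)
  list(prob = hd$prob, state = bn$state,
       cache = list(steps = steps, bn = bn$cache, head = hd$cache, n = n, W = W, U = U))
}

lstm_backward <- function(params, cache, dlogits) {
  hb <- head_backward(params, cache$head, dlogits)
  bb <- bn_backward(hb$dfeat, params$bn_gamma, cache$bn)
  grads <- c(hb$grads, list(bn_gamma = bb$dgamma, bn_beta = bb$dbeta))
  U <- cache$U
  gi <- seq_len(U); gf <- U + gi; go <- 2 * U + gi; gg <- 3 * U + gi
  dWx <- array(0, dim = dim(params$lstm_Wx))
  dWh <- array(0, dim = dim(params$lstm_Wh))
  db <- numeric(4 * U)
  dh <- bb$dx
  dc <- matrix(0, cache$n, U)
  for (t in rev(seq_len(cache$W))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g; dg <- dc * st$i; df <- dc * st$c_prev
    dz <- matrix(0, cache$n, 4 * U)
    dz[, gi] <- di * st$i * (1 - st$i)
    dz[, gf] <- df * st$f * (1 - st$f)
    dz[, go] <- do_ * st$o * (1 - st$o)
    dz[, gg] <- dg * (1 - st$g^2)
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(params$lstm_Wh)
    dc <- dc * st$f
  }
  c(grads, list(lstm_Wx = dWx, lstm_Wh = dWh, lstm_b = db))
}

# ---- CNN -------------------------------------------------------------------
# One valid 1D convolution along time (leaky-ReLU), flattened, then the head.

cnn_init <- function(spec) {
  t_out <- spec$W - spec$kernel + 1L
  params <- list(
    conv_K = glorot(spec$kernel * spec$C, spec$filters),
    conv_b = numeric(spec$filters)
  )
  c(params, head_init(t_out * spec$filters, spec$D, spec$head_hidden, spec$C))
}

cnn_forward <- function(params, state, x, demo, train) {
  cv <- conv1d_forward(x, params$conv_K, params$conv_b)
  a <- lrelu(cv$out)
  n <- dim(a)[1]
  feat <- a; dim(feat) <- c(n, prod(dim(a)[2:3]))
  hd <- head_forward(params, feat, demo)
  list(prob = hd$prob, state = state,
       cache = list(conv = cv$cache, z = cv$out, head = hd$cache, adim = dim(a)))
}

cnn_backward <- function(params, cache, dlogits) {
  hb <- head_backward(params, cache$head, dlogits)
  da <- hb$dfeat; dim(da) <- cache$adim
  dz <- da * dlrelu(cache$z)
  cb <- conv1d_backward(dz, params$conv_K, cache$conv)
  c(hb$grads, list(conv_K = cb$dkernel, conv_b = cb$dbias))
}

# ---- M-CNN -----------------------------------------------------------------
# Two parallel convolutional streams with different kernel sizes (short- and
# long-range temporal patterns); their flattened outputs are concatenated
# before the head.

mcnn_init <- function(spec) {
  k1 <- spec$kernels[1]; k2 <- spec$kernels[2]
  f1 <- spec$W - k1 + 1L; f2 <- spec$W - k2 + 1L
  params <- list(
    s1_K = glorot(k1 * spec$C, spec$filters),
    s1_b = numeric(spec$filters),
    s2_K = glorot(k2 * spec$C, spec$filters),
    s2_b = numeric(spec$filters)
  )
  c(params, head_init((f1 + f2) * spec$filters, spec$D, spec$head_hidden, spec$C))
}

mcnn_forward <- function(params, state, x, demo, train) {
  c1 <- conv1d_forward(x, params$s1_K, params$s1_b)
  c2 <- conv1d_forward(x, params$s2_K, params$s2_b)
  a1 <- lrelu(c1$out); a2 <- lrelu(c2$out)
  n <- dim(x)[1]
  f1 <- a1; dim(f1) <- c(n, prod(dim(a1)[2:3]))
  f2 <- a2; dim(f2) <- c(n, prod(dim(a2)[2:3]))
  hd <- head_forward(params, cbind(f1, f2), demo)
  list(prob = hd$prob, state = state,
       cache = list(c1 = c1$cache, c2 = c2$cache, z1 = c1$out, z2 = c2$out,
                    head = hd$cache, d1 = dim(a1), d2 = dim(a2),
                    n1 = prod(dim(a1)[2:3])))
}

mcnn_backward <- function(params, cache, dlogits) {
  hb <- head_backward(params, cache$head, dlogits)
  df1 <- hb$dfeat[, seq_len(cache$n1), drop = FALSE]
  df2 <- hb$dfeat[, -seq_len(cache$n1), drop = FALSE]
  dim(df1) <- cache$d1; dim(df2) <- cache$d2
  dz1 <- df1 * dlrelu(cache$z1)
  dz2 <- df2 * dlrelu(cache$z2)
  b1 <- conv1d_backward(dz1, params$s1_K, cache$c1)
  b2 <- conv1d_backward(dz2, params$s2_K, cache$c2)
  c(hb$grads, list(s1_K = b1$dkernel, s1_b = b1$dbias,
                   s2_K = b2$dkernel, s2_b = b2$dbias))
}

# ---- TCN -------------------------------------------------------------------
# Stack of causal, dilated 1D convolutions (length-preserving via left zero
# padding, leaky-ReLU between layers); the final layer's last time step is
# the sequence feature — by causality it summarizes the whole window.

tcn_init <- function(spec) {
  params <- list()
  cin <- spec$C
  for (l in seq_along(spec$dilations)) {
    params[[paste0("tcn_K", l)]] <- glorot(spec$kernel * cin, spec$filters)
    params[[paste0("tcn_b", l)]] <- numeric(spec$filters)
    cin <- spec$filters
  }
  c(params, head_init(spec$filters, spec$D, spec$head_hidden, spec$C))
}

tcn_forward <- function(params, state, x, demo, train) {
  n <- dim(x)[1]; W <- dim(x)[2]
  a <- x
  caches <- list()
  dil <- state$dilations
  for (l in seq_along(dil)) {
    cv <- conv1d_forward(a, params[[paste0("tcn_K", l)]], params[[paste0("tcn_b", l)]],
                         dilation = dil[l], causal = TRUE)
    caches[[l]] <- list(conv = cv$cache, z = cv$out)
    a <- lrelu(cv$out)
  }
  feat <- a[, W, , drop = FALSE]; dim(feat) <- c(n, dim(a)[3])
  hd <- head_forward(params, feat, demo)
  list(prob = hd$prob, state = state,
       cache = list(layers = caches, head = hd$cache, n = n, W = W,
                    f = dim(a)[3], dil = dil))
}

tcn_backward <- function(params, cache, dlogits) {
  hb <- head_backward(params, cache$head, dlogits)
  grads <- hb$grads
  # seed the sequence gradient: only the last time step feeds the head
  da <- array(0, dim = c(cache$n, cache$W, cache$f))
  da[, cache$W, ] <- hb$dfeat
  for (l in rev(seq_along(cache$dil))) {
    ly <- cache$layers[[l]]
    dz <- da * dlrelu(ly$z)
    cb <- conv1d_backward(dz, params[[paste0("tcn_K", l)]], ly$conv)
    grads[[paste0("tcn_K", l)]] <- cb$dkernel
    grads[[paste0("tcn_b", l)]] <- cb$dbias
    da <- cb$dx
  }
  grads
}

# ---- Transformer with learned time encoding --------------------------------
# Each step's features are concatenated with a learned time embedding (one
# affine component plus sinusoids of affine arguments), projected to the
# model width by a 1x1 temporal convolution (per-step dense map), passed
# through one block of multi-head self-attention and a per-step ReLU dense
# layer, then mean-pooled over time into the sequence feature vector.

transformer_init <- function(spec) {
  M <- spec$d_model; k <- spec$t2v_k
  params <- list(
    t2v_w = runif(k, -1, 1),
    t2v_b = runif(k, -1, 1),
    proj_W = glorot(spec$C + k, M),
    proj_b = numeric(M),
    att_Wq = glorot(M, M), att_Wk = glorot(M, M), att_Wv = glorot(M, M),
    att_Wo = glorot(M, M), att_bo = numeric(M),
    ffn_W = glorot(M, M), ffn_b = numeric(M)
  )
  c(params, head_init(M, spec$D, spec$head_hidden, spec$C))
}

#' Learned time encoding for transformer inputs
#'
#' Embeds integer step indices as one affine ("linear trend") component plus
#' sinusoidal components with learned frequencies and phases, so the
#' attention layers see both absolute position and periodic structure.
#' Component `j = 1` is `w[1] * t + b[1]`; components `j >= 2` are
#' `sin(w[j] * t + b[j])`.
#'
#' @param step_indices Numeric vector of time step indices (e.g. `0:(W-1)`).
#' @param params A list with numeric `w` and `b` of equal length `>= 2`
#'   (one linear plus at least one periodic component).
#' @return A `length(step_indices) x length(w)` embedding matrix.
#' @export
#' @examples
#' time_encode(0:5, list(w = c(1, 0.5), b = c(0, 0)))
time_encode <- function(step_indices, params) {
  w <- params$w; b <- params$b
  if (length(w) < 2 || length(w) != length(b)) {
    stop_named("time encoding needs >= 2 components (one linear + >= 1 periodic)")
  }
  arg <- outer(step_indices, w) + matrix(b, length(step_indices), length(w), byrow = TRUE)
  cbind(arg[, 1, drop = FALSE], sin(arg[, -1, drop = FALSE]))
}

time_encode_backward <- function(step_indices, params, dtv) {
  w <- params$w; b <- params$b
  arg <- outer(step_indices, w) + matrix(b, length(step_indices), length(w), byrow = TRUE)
  darg <- cbind(dtv[, 1, drop = FALSE], dtv[, -1, drop = FALSE] * cos(arg[, -1, drop = FALSE]))
  list(dw = colSums(darg * step_indices), db = colSums(darg))
}

transformer_forward <- function(params, state, x, demo, train) {
  n <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  M <- ncol(params$proj_W); H <- state$heads; dk <- M / H
  steps <- seq_len(W) - 1
  tv <- time_encode(steps, list(w = params$t2v_w, b = params$t2v_b))
  xa <- array(0, dim = c(n, W, C + ncol(tv)))
  xa[, , seq_len(C)] <- x
  for (j in seq_len(ncol(tv))) xa[, , C + j] <- matrix(tv[, j], n, W, byrow = TRUE)
  X2 <- collapse2(xa)
  Z0 <- sweep(X2 %*% params$proj_W, 2, params$proj_b, "+")
  Q2 <- Z0 %*% params$att_Wq; K2 <- Z0 %*% params$att_Wk; V2 <- Z0 %*% params$att_Wv
  Q <- uncollapse2(Q2, n, W); K <- uncollapse2(K2, n, W); V <- uncollapse2(V2, n, W)
  O <- array(0, dim = c(n, W, M))
  A <- array(0, dim = c(n, H, W, W))
  for (i in seq_len(n)) {
    for (h in seq_len(H)) {
      cols <- (h - 1) * dk + seq_len(dk)
      Qi <- matrix(Q[i, , cols], W, dk); Ki <- matrix(K[i, , cols], W, dk)
      Vi <- matrix(V[i, , cols], W, dk)
      S <- Qi %*% t(Ki) / sqrt(dk)
      S <- exp(S - apply(S, 1, max))
      Ai <- S / rowSums(S)
      A[i, h, , ] <- Ai
      O[i, , cols] <- Ai %*% Vi
    }
  }
  O2 <- collapse2(O)
  Zo <- sweep(O2 %*% params$att_Wo, 2, params$att_bo, "+")
  Zf_in <- Zo
  F1 <- relu(sweep(Zf_in %*% params$ffn_W, 2, params$ffn_b, "+"))
  Fa <- uncollapse2(F1, n, W)
  feat <- apply(Fa, c(1, 3), mean)
  hd <- head_forward(params, feat, demo)
  list(prob = hd$prob, state = state,
       cache = list(X2 = X2, Z0 = Z0, Q = Q, K = K, V = V, A = A, O2 = O2,
                    Zf_in = Zf_in, F1 = F1, head = hd$cache,
                    n = n, W = W, C = C, M = M, H = H, dk = dk, tv = tv,
                    steps = steps))
}

transformer_backward <- function(params, cache, dlogits) {
  hb <- head_backward(params, cache$head, dlogits)
  n <- cache$n; W <- cache$W; M <- cache$M; H <- cache$H; dk <- cache$dk
  # mean pool: spread the feature gradient evenly over time steps
  dFa <- array(0, dim = c(n, W, M))
  for (t in seq_len(W)) dFa[, t, ] <- hb$dfeat / W
  dF1 <- collapse2(dFa)
  zf <- sweep(cache$Zf_in %*% params$ffn_W, 2, params$ffn_b, "+")
  dzf <- dF1 * drelu(zf)
  g_ffn_W <- crossprod(cache$Zf_in, dzf)
  g_ffn_b <- colSums(dzf)
  dZo <- dzf %*% t(params$ffn_W)
  g_att_Wo <- crossprod(cache$O2, dZo)
  g_att_bo <- colSums(dZo)
  dO2 <- dZo %*% t(params$att_Wo)
  dO <- uncollapse2(dO2, n, W)
  dQ <- array(0, dim = c(n, W, M)); dK <- dQ; dV <- dQ
  for (i in seq_len(n)) {
    for (h in seq_len(H)) {
      cols <- (h - 1) * dk + seq_len(dk)
      Ai <- matrix(cache$A[i, h, , ], W, W)
      Vi <- matrix(cache$V[i, , cols], W, dk)
      dOi <- matrix(dO[i, , cols], W, dk)
      dV[i, , cols] <- crossprod(Ai, dOi)
      dAi <- dOi %*% t(Vi)
      dSi <- (dAi - rowSums(dAi * Ai)) * Ai
      Qi <- matrix(cache$Q[i, , cols], W, dk); Ki <- matrix(cache$K[i, , cols], W, dk)
      dQ[i, , cols] <- dSi %*% Ki / sqrt(dk)
      dK[i, , cols] <- crossprod(dSi, Qi) / sqrt(dk)
    }
  }
  dQ2 <- collapse2(dQ); dK2 <- collapse2(dK); dV2 <- collapse2(dV)
  g_Wq <- crossprod(cache$Z0, dQ2)
  g_Wk <- crossprod(cache$Z0, dK2)
  g_Wv <- crossprod(cache$Z0, dV2)
  dZ0 <- dQ2 %*% t(params$att_Wq) + dK2 %*% t(params$att_Wk) + dV2 %*% t(params$att_Wv)
  g_proj_W <- crossprod(cache$X2, dZ0)
  g_proj_b <- colSums(dZ0)
  dX2 <- dZ0 %*% t(params$proj_W)
  ktv <- ncol(cache$tv)
  dXa <- uncollapse2(dX2, n, W)
  dtv <- matrix(0, W, ktv)
  for (j in seq_len(ktv)) dtv[, j] <- colSums(matrix(dXa[, , cache$C + j], n, W))
  tvb <- time_encode_backward(cache$steps, list(w = params$t2v_w, b = params$t2v_b), dtv)
  c(hb$grads,
    list(ffn_W = g_ffn_W, ffn_b = g_ffn_b, att_Wo = g_att_Wo, att_bo = g_att_bo,
         att_Wq = g_Wq, att_Wk = g_Wk, att_Wv = g_Wv,
         proj_W = g_proj_W, proj_b = g_proj_b,
         t2v_w = tvb$dw, t2v_b = tvb$db))
}
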