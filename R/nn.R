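# Internal neural-network engine, vectorized base R.
#
# Layout conventions:
#   * a batch is a 3-D array X (4, width, B): channels x positions x batch;
#   * conv layers use im2col: positions unroll into columns of a
#     (C_in * w) x (L_out * B) matrix, so one matrix product per layer;
#   * columns are ordered position-fastest within batch, matching
#     as.vector() on a (L_out x B) mask matrix;
#   * per-sample true lengths are threaded through every layer; positions
#     beyond a sample's valid range are zeroed after each conv and the
#     BLSTM freezes its state there, so right-padding a batch with extra
#     zero columns never changes a score.
#
# All gradients (parameters and input) are exact backprop and are checked
# against central finite differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

im2col <- function(X3, w) {
  d <- dim(X3)
  Cin <- d[1L]; Lin <- d[2L]; B <- d[3L]
  Lout <- Lin - w + 1L
  out <- matrix(0, Cin * w, Lout * B)
  for (j in seq_len(w)) {
    out[((j - 1L) * Cin + 1L):(j * Cin), ] <-
      matrix(X3[, j:(j + Lout - 1L), , drop = FALSE], nrow = Cin)
  }
  out
}

col2im <- function(dXc, dims, w) {
  Cin <- dims[1L]; Lin <- dims[2L]; B <- dims[3L]
  Lout <- Lin - w + 1L
  dX3 <- array(0, dims)
  for (j in seq_len(w)) {
    idx <- j:(j + Lout - 1L)
    dX3[, idx, ] <- dX3[, idx, , drop = FALSE] +
      array(dXc[((j - 1L) * Cin + 1L):(j * Cin), ], dim = c(Cin, Lout, B))
  }
  dX3
}

# mask vector (length Lout*B) for per-sample valid lengths
len_mask <- function(lens, Lout) {
  as.numeric(outer(seq_len(Lout), lens, `<=`))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Reference BLSTM sequence length for a full-size window under `cfg`:
# used to size the FC layer in "flatten" reduction mode.
cfg_l2_ref <- function(cfg) {
  pad <- cfg$filter_sizes[1L] %/% 2L
  q <- if (is.null(cfg$maxpool)) 1L else max(1L, cfg$maxpool)
  L1 <- cfg$window_size + 2L * pad - cfg$filter_sizes[1L] + 1L
  L1 <- (L1 + q - 1L) %/% q
  L2 <- L1 - cfg$filter_sizes[2L] + 1L
  (L2 + q - 1L) %/% q
}

# ---- parameter initialization -------------------------------------------

nn_init_params <- function(cfg) {
  w1 <- cfg$filter_sizes[1L]; w2 <- cfg$filter_sizes[2L]
  n1 <- cfg$filter_counts[1L]; n2 <- cfg$filter_counts[2L]
  H <- cfg$blstm_units; Fc <- cfg$fc_units
  lstm_init <- function(Cin) {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- cfg$forget_bias %||% 1   # forget-gate bias (chrono-style)
    list(Wx = glorot(4L * H, Cin, Cin, H),
         Wh = glorot(4L * H, H, H, H),
         b = b)
  }
  fc_in <- if (identical(cfg$blstm_reduction, "flatten")) {
    2L * H * cfg_l2_ref(cfg)
  } else 2L * H
  # Second conv starts as glorot noise plus an identity passthrough at its
  # central tap (filter j forwards first-layer channel (j-1) mod n1 + 1),
  # so first-layer motif responses reach the recurrent read-out from step
  # one instead of having to route through a fully random layer first.
  W2 <- glorot(n2, n1 * w2, n1 * w2, n2)
  jc <- (w2 + 1L) %/% 2L
  for (j in seq_len(n2)) {
    W2[j, (jc - 1L) * n1 + ((j - 1L) %% n1) + 1L] <-
      W2[j, (jc - 1L) * n1 + ((j - 1L) %% n1) + 1L] + 1
  }
  list(conv1 = list(W = glorot(n1, 4L * w1, 4L * w1, n1), b = numeric(n1)),
       bn1 = list(gamma = rep(1, n1), beta = numeric(n1)),
       conv2 = list(W = W2, b = numeric(n2)),
       bn2 = list(gamma = rep(1, n2), beta = numeric(n2)),
       lstm_f = lstm_init(n2),
       lstm_b = lstm_init(n2),
       fc = list(W = glorot(Fc, fc_in, fc_in, Fc), b = numeric(Fc)),
       out = list(W = glorot(1L, Fc, Fc, 1L), b = 0))
}

nn_init_state <- function(cfg) {
  list(bn1 = list(mean = numeric(cfg$filter_counts[1L]),
                  var = rep(1, cfg$filter_counts[1L])),
       bn2 = list(mean = numeric(cfg$filter_counts[2L]),
                  var = rep(1, cfg$filter_counts[2L])))
}

# ---- batch norm ----------------------------------------------------------

bn_forward <- function(Y, bnp, st, training) {
  if (training) {
    mu <- rowMeans(Y)
    va <- rowMeans(Y * Y) - mu * mu
    va[va < 0] <- 0
    inv <- 1 / sqrt(va + BN_EPS)
    xhat <- (Y - mu) * inv
    st$mean <- BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * mu
    st$var <- BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * va
    list(out = bnp$gamma * xhat + bnp$beta, xhat = xhat, inv = inv,
         state = st, training = TRUE)
  } else {
    inv <- 1 / sqrt(st$var + BN_EPS)
    list(out = bnp$gamma * (Y - st$mean) * inv + bnp$beta,
         inv = inv, state = st, training = FALSE)
  }
}

bn_backward <- function(dOut, bnp, cache) {
  if (cache$training) {
    N <- ncol(dOut)
    dgamma <- rowSums(dOut * cache$xhat)
    dbeta <- rowSums(dOut)
    dxhat <- dOut * bnp$gamma
    dY <- (cache$inv / N) *
      (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
    list(dY = dY, dgamma = dgamma, dbeta = dbeta)
  } else {
    list(dY = dOut * bnp$gamma * cache$inv,
         dgamma = rowSums(dOut * (cache$outm %||% 0)),   # unused in eval
         dbeta = rowSums(dOut))
  }
}

# ---- max pooling (optional, non-overlapping) -----------------------------

# Non-overlapping max pool of width q along positions. The position axis
# is right-padded with zeros to a multiple of q so a trailing partial
# block survives; per-sample valid lengths become ceiling(lens / q)
# (invalid positions are zeroed upstream, so they never win a max over a
# live activation, and a sample's partial final block stays usable).
pool_forward <- function(A3, lens, q) {
  d <- dim(A3)
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  Lp <- (L + q - 1L) %/% q
  if (Lp * q > L) {
    Ap <- array(0, dim = c(C, Lp * q, B))
    Ap[, seq_len(L), ] <- A3
    A3 <- Ap
  }
  P <- array(-Inf, dim = c(C, Lp, B))
  amax <- array(1L, dim = c(C, Lp, B))
  for (j in seq_len(q)) {
    S <- A3[, seq(j, by = q, length.out = Lp), , drop = FALSE]
    better <- S > P
    P[better] <- S[better]
    amax[better] <- j
  }
  list(P = P, amax = amax, lens = (lens + q - 1L) %/% q, in_dim = d, q = q)
}

pool_backward <- function(dP, cache) {
  d <- cache$in_dim
  q <- cache$q
  Lp <- dim(dP)[2L]
  dA <- array(0, dim = c(d[1L], Lp * q, d[3L]))
  for (j in seq_len(q)) {
    sel <- cache$amax == j
    slice <- array(0, dim(dP))
    slice[sel] <- dP[sel]
    idx <- seq(j, by = q, length.out = Lp)
    dA[, idx, ] <- dA[, idx, , drop = FALSE] + slice
  }
  dA[, seq_len(d[2L]), , drop = FALSE]
}

# ---- conv block: conv -> mask -> BN -> ReLU -> (pool) -> dropout ---------

conv_block_forward <- function(X3, lens, convp, bnp, st, w, training,
                               drop_p, pool_q) {
  d <- dim(X3)
  Lout <- d[2L] - w + 1L
  if (Lout < 1L) stopf("sequence too short for filter width %d", w)
  lens_out <- lens - w + 1L
  if (any(lens_out < 1L)) {
    stopf("window too short for the configured filter widths (shortest valid length %d)",
          min(lens_out))
  }
  Xc <- im2col(X3, w)
  Y <- convp$W %*% Xc + convp$b
  mv <- len_mask(lens_out, Lout)
  Y <- Y * rep(mv, each = nrow(Y))
  if (is.null(bnp)) {
    bn <- list(out = Y, state = st, training = training, skipped = TRUE)
  } else {
    bn <- bn_forward(Y, bnp, st, training)
  }
  relu_mask <- bn$out > 0
  # re-zero invalid positions post-BN/ReLU (BN shifts the earlier zeros),
  # so pooling and the BLSTM only ever see 0 there
  A <- bn$out * relu_mask * rep(mv, each = nrow(bn$out))
  cache <- list(Xc = Xc, in_dim = d, w = w, mv = mv, bn = bn,
                relu_mask = relu_mask, Lout = Lout, pool = NULL,
                drop_mask = NULL)
  A3 <- array(A, dim = c(nrow(A), Lout, d[3L]))
  if (!is.null(pool_q) && pool_q > 1L) {
    pc <- pool_forward(A3, lens_out, pool_q)
    A3 <- pc$P
    lens_out <- pc$lens
    cache$pool <- pc
  }
  if (training && drop_p > 0) {
    dm <- array(stats::rbinom(length(A3), 1L, 1 - drop_p) / (1 - drop_p),
                dim = dim(A3))
    A3 <- A3 * dm
    cache$drop_mask <- dm
  }
  list(A3 = A3, lens = lens_out, cache = cache, state = bn$state)
}

conv_block_backward <- function(dA3, convp, bnp, cache) {
  if (!is.null(cache$drop_mask)) dA3 <- dA3 * cache$drop_mask
  if (!is.null(cache$pool)) dA3 <- pool_backward(dA3, cache$pool)
  dA <- matrix(dA3, nrow = dim(dA3)[1L])
  dA <- dA * rep(cache$mv, each = nrow(dA))
  dBnOut <- dA * cache$relu_mask
  if (isTRUE(cache$bn$skipped)) {
    bb <- list(dY = dBnOut, dgamma = NULL, dbeta = NULL)
  } else {
    bb <- bn_backward(dBnOut, bnp, cache$bn)
  }
  dY <- bb$dY * rep(cache$mv, each = nrow(bb$dY))
  dW <- dY %*% t(cache$Xc)
  db <- rowSums(dY)
  dXc <- t(convp$W) %*% dY
  dX3 <- col2im(dXc, cache$in_dim, cache$w)
  list(dX3 = dX3, dconv = list(W = dW, b = db),
       dbn = list(gamma = bb$dgamma, beta = bb$dbeta))
}

# ---- length-masked LSTM --------------------------------------------------

# A3: (C, L, B); mask M: (L x B); direction "fwd" runs t = 1..L,
# "bwd" runs t = L..1. Returns the state after the last processed step
# (== state at each sample's boundary valid step, by masking).
lstm_forward <- function(A3, M, p, direction) {
  d <- dim(A3)
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  H <- length(p$b) %/% 4L
  ord <- if (direction == "fwd") seq_len(L) else rev(seq_len(L))
  h <- matrix(0, H, B)
  cc <- matrix(0, H, B)
  H_all <- array(0, dim = c(H, L, B))
  steps <- vector("list", L)
  i1 <- 1L:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  for (s in seq_len(L)) {
    t <- ord[s]
    x <- matrix(A3[, t, ], C, B)
    m <- matrix(M[t, ], nrow = 1L)
    z <- p$Wx %*% x + p$Wh %*% h + p$b
    gi <- sigmoid(z[i1, , drop = FALSE])
    gf <- sigmoid(z[i2, , drop = FALSE])
    gg <- tanh(z[i3, , drop = FALSE])
    go <- sigmoid(z[i4, , drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    mm <- matrix(rep(m, each = H), H, B)
    steps[[s]] <- list(x = x, h_prev = h, c_prev = cc, gi = gi, gf = gf,
                       gg = gg, go = go, tc = tc, mm = mm, t = t)
    cc <- mm * c_new + (1 - mm) * cc
    h <- mm * h_new + (1 - mm) * h
    H_all[, t, ] <- mm * h_new        # zeroed beyond each valid length
  }
  list(h_final = h, H_all = H_all, steps = steps,
       C = C, L = L, B = B, H = H, ord = ord)
}

# dh_final: gradient at the final state; dH_inject: optional (H, L, B)
# gradient injected at every timestep's (mask-zeroed) emitted state.
lstm_backward <- function(fw, p, dh_final, dH_inject = NULL) {
  C <- fw$C; L <- fw$L; B <- fw$B; H <- fw$H
  dWx <- matrix(0, 4L * H, C); dWh <- matrix(0, 4L * H, H)
  db <- numeric(4L * H)
  dA3 <- array(0, dim = c(C, L, B))
  dh <- dh_final
  dc <- matrix(0, H, B)
  for (s in rev(seq_len(L))) {
    st <- fw$steps[[s]]
    mm <- st$mm
    dh_new <- dh * mm
    dh_pass <- dh * (1 - mm)
    if (!is.null(dH_inject)) {
      dh_new <- dh_new + matrix(dH_inject[, st$t, ], nrow(dh), ncol(dh)) * mm
    }
    dtc <- dh_new * st$go
    dgo <- dh_new * st$tc
    dc_new <- dc * mm + dtc * (1 - st$tc^2)
    dc_pass <- dc * (1 - mm)
    dgf <- dc_new * st$c_prev
    dgi <- dc_new * st$gg
    dgg <- dc_new * st$gi
    dc_prev <- dc_new * st$gf + dc_pass
    dz <- rbind(dgi * st$gi * (1 - st$gi),
                dgf * st$gf * (1 - st$gf),
                dgg * (1 - st$gg^2),
                dgo * st$go * (1 - st$go))
    dWx <- dWx + dz %*% t(st$x)
    dWh <- dWh + dz %*% t(st$h_prev)
    db <- db + rowSums(dz)
    dA3[, st$t, ] <- dA3[, st$t, ] + t(p$Wx) %*% dz
    dh <- t(p$Wh) %*% dz + dh_pass
    dc <- dc_prev
  }
  list(dA3 = dA3, dp = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- full forward / backward ---------------------------------------------

nn_forward <- function(model, X3, lens, training = FALSE) {
  cfg <- model$config
  p <- model$params
  b1 <- conv_block_forward(X3, lens, p$conv1, p$bn1, model$state$bn1,
                           cfg$filter_sizes[1L], training,
                           cfg$dropout_rate, cfg$maxpool)
  b2 <- conv_block_forward(b1$A3, b1$lens, p$conv2, p$bn2, model$state$bn2,
                           cfg$filter_sizes[2L], training,
                           cfg$dropout_rate, cfg$maxpool)
  L2 <- dim(b2$A3)[2L]
  M <- matrix(outer(seq_len(L2), b2$lens, `<=`), L2, length(lens)) * 1
  lf <- lstm_forward(b2$A3, M, p$lstm_f, "fwd")
  lb <- lstm_forward(b2$A3, M, p$lstm_b, "bwd")
  flatten <- identical(cfg$blstm_reduction, "flatten")
  if (flatten) {
    H <- nrow(lf$h_final)
    B <- dim(b2$A3)[3L]
    L2_ref <- cfg_l2_ref(cfg)
    stack <- function(H_all) {
      Z <- array(0, dim = c(H, L2_ref, B))
      Z[, seq_len(min(L2, L2_ref)), ] <- H_all[, seq_len(min(L2, L2_ref)), ]
      matrix(Z, nrow = H * L2_ref)
    }
    hcat <- rbind(stack(lf$H_all), stack(lb$H_all))
  } else {
    hcat <- rbind(lf$h_final, lb$h_final)
  }
  # tanh on the hidden FC layer: symmetric and saturating but without the
  # permanent-death failure mode ReLU has when every unit goes negative
  # on small data (the sigmoid output activation follows `out`)
  fc_pre <- p$fc$W %*% hcat + p$fc$b
  fc_act <- tanh(fc_pre)
  logit <- as.numeric(p$out$W %*% fc_act + p$out$b)
  list(logit = logit,
       caches = list(b1 = b1, b2 = b2, lf = lf, lb = lb, hcat = hcat,
                     fc_act = fc_act),
       state = list(bn1 = b1$state, bn2 = b2$state))
}

nn_backward <- function(model, fw, dlogit) {
  p <- model$params
  ca <- fw$caches
  B <- length(dlogit)
  dlog <- matrix(dlogit, 1L, B)
  dWo <- dlog %*% t(ca$fc_act)
  dbo <- sum(dlog)
  dfc_act <- t(p$out$W) %*% dlog
  dfc_pre <- dfc_act * (1 - ca$fc_act^2)
  dWf <- dfc_pre %*% t(ca$hcat)
  dbf <- rowSums(dfc_pre)
  dhcat <- t(p$fc$W) %*% dfc_pre
  H <- nrow(ca$lf$h_final)
  if (identical(model$config$blstm_reduction, "flatten")) {
    L2 <- ca$lf$L
    B2 <- ca$lf$B
    L2_ref <- nrow(dhcat) %/% (2L * H)
    unstack <- function(rows) {
      Z <- array(dhcat[rows, , drop = FALSE], dim = c(H, L2_ref, B2))
      inj <- array(0, dim = c(H, L2, B2))
      inj[, seq_len(min(L2, L2_ref)), ] <- Z[, seq_len(min(L2, L2_ref)), ]
      inj
    }
    zero <- matrix(0, H, B2)
    lbk_f <- lstm_backward(ca$lf, p$lstm_f, zero,
                           dH_inject = unstack(seq_len(H * L2_ref)))
    lbk_b <- lstm_backward(ca$lb, p$lstm_b, zero,
                           dH_inject = unstack(H * L2_ref + seq_len(H * L2_ref)))
  } else {
    lbk_f <- lstm_backward(ca$lf, p$lstm_f, dhcat[1:H, , drop = FALSE])
    lbk_b <- lstm_backward(ca$lb, p$lstm_b,
                           dhcat[(H + 1L):(2L * H), , drop = FALSE])
  }
  dA2 <- lbk_f$dA3 + lbk_b$dA3
  bb2 <- conv_block_backward(dA2, p$conv2, p$bn2, ca$b2$cache)
  bb1 <- conv_block_backward(bb2$dX3, p$conv1, p$bn1, ca$b1$cache)
  list(grads = list(conv1 = bb1$dconv, bn1 = bb1$dbn,
                    conv2 = bb2$dconv, bn2 = bb2$dbn,
                    lstm_f = lbk_f$dp, lstm_b = lbk_b$dp,
                    fc = list(W = dWf, b = dbf),
                    out = list(W = dWo, b = dbo)),
       dX = bb1$dX3)
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (grp in names(params)) {
    for (nm in names(params[[grp]])) {
      g <- grads[[grp]][[nm]]
      opt$m[[grp]][[nm]] <- beta1 * opt$m[[grp]][[nm]] + (1 - beta1) * g
      opt$v[[grp]][[nm]] <- beta2 * opt$v[[grp]][[nm]] + (1 - beta2) * g * g
      mhat <- opt$m[[grp]][[nm]] / bc1
      vhat <- opt$v[[grp]][[nm]] / bc2
      params[[grp]][[nm]] <- params[[grp]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, opt = opt)
}

# Scale gradients so their global L2 norm is at most `max_norm`.
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(rapply(grads, function(g) sum(g * g), how = "unlist")))
  if (is.finite(total) && total > max_norm) {
    grads <- rapply(grads, function(g) g * (max_norm / total), how = "replace")
  }
  grads
}

# Stable binary cross-entropy on logits; returns mean loss and d(logit).
bce_with_logits <- function(logit, y) {
  loss <- mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
  dlogit <- (sigmoid(logit) - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}
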