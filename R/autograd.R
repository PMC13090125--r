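# Analytic backward pass through the encoder. Each function mirrors its
# forward counterpart in encoder.R and consumes the caches recorded with
# keep_cache = TRUE. Gradients are returned as a parameter tree with the same
# shape as the weights (verified against finite differences in the tests).

layernorm_bwd <- function(dy, ln, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- ln$inv * (dxhat - m1 - ln$xhat * m2)
  list(dx = dx, dg = colSums(dy * ln$xhat), db = colSums(dy))
}

ffn_bwd <- function(dout, weights, cache) {
  L <- length(weights)
  dws <- vector("list", L)
  dh <- dout
  for (i in L:1) {
    dz <- if (i < L) dh * (cache[[i]]$z > 0) else dh
    dws[[i]] <- crossprod(cache[[i]]$input, dz)
    dh <- tcrossprod(dz, weights[[i]])
  }
  list(dweights = dws, dx = dh)
}

# Backpropagate d_xl (gradient at the final, layer-normed representations)
# through the whole encoder; returns gradients for ffn_f, ffn_p, all
# transformer layers and the final layer norm.
encoder_backward <- function(d_xl, fwd, params, cfg) {
  cache <- fwd$cache
  dh <- cfg$d / cfg$heads
  scale <- 1 / sqrt(cfg$d)
  g_layers <- vector("list", cfg$layers)

  lnf <- layernorm_bwd(d_xl, cache$lnf, params$ln_f_g)
  dx <- lnf$dx

  for (li in cfg$layers:1) {
    lc <- cache$layers[[li]]
    lp <- params$layers[[li]]
    # feed-forward sub-block
    dffn_out <- dx
    dw2 <- crossprod(lc$r1, dffn_out)
    dr1 <- tcrossprod(dffn_out, lp$w2)
    dz1 <- dr1 * (lc$z1 > 0)
    dw1 <- crossprod(lc$ln2$y, dz1)
    dln2y <- tcrossprod(dz1, lp$w1)
    ln2 <- layernorm_bwd(dln2y, lc$ln2, lp$ln2_g)
    dx_mid <- dx + ln2$dx
    # attention sub-block
    dattn_out <- dx_mid
    dwo <- crossprod(lc$o, dattn_out)
    do_ <- tcrossprod(dattn_out, lp$wo)
    dq <- matrix(0, nrow(dx), cfg$d)
    dk <- matrix(0, nrow(dx), cfg$d)
    dv <- matrix(0, nrow(dx), cfg$d)
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      a <- lc$att[[h]]
      do_h <- do_[, cols, drop = FALSE]
      da <- tcrossprod(do_h, lc$v[, cols, drop = FALSE])
      dv[, cols] <- crossprod(a, do_h)
      dscores <- a * (da - rowSums(da * a)) * scale
      dq[, cols] <- dscores %*% lc$k[, cols, drop = FALSE]
      dk[, cols] <- crossprod(dscores, lc$q[, cols, drop = FALSE])
    }
    dwq <- crossprod(lc$ln1$y, dq)
    dwk <- crossprod(lc$ln1$y, dk)
    dwv <- crossprod(lc$ln1$y, dv)
    dln1y <- tcrossprod(dq, lp$wq) + tcrossprod(dk, lp$wk) +
      tcrossprod(dv, lp$wv)
    ln1 <- layernorm_bwd(dln1y, lc$ln1, lp$ln1_g)
    dx <- dx_mid + ln1$dx
    g_layers[[li]] <- list(ln1_g = ln1$dg, ln1_b = ln1$db,
                           wq = dwq, wk = dwk, wv = dwv, wo = dwo,
                           ln2_g = ln2$dg, ln2_b = ln2$db,
                           w1 = dw1, w2 = dw2)
  }
  # peak encoder
  dx0 <- dx
  f_bwd <- ffn_bwd(dx0[, seq_len(cfg$d_m), drop = FALSE], params$ffn_f,
                   cache$enc$f_cache)
  p_bwd <- ffn_bwd(dx0[, cfg$d_m + seq_len(cfg$d_p), drop = FALSE],
                   params$ffn_p, cache$enc$p_cache)
  list(ffn_f = f_bwd$dweights, ffn_p = p_bwd$dweights, layers = g_layers,
       ln_f_g = lnf$dg, ln_f_b = lnf$db)
}

# Zero-filled gradient tree for the requested head weights only, so unused
# (large) heads cost nothing during batched accumulation.
zero_head_grads <- function(params, heads = names(params$heads)) {
  param_zeros_like(params$heads[heads])
}

ENCODER_PARAM_NAMES <- c("ffn_f", "ffn_p", "layers", "ln_f_g", "ln_f_b")

# Extract the trainable subtree (encoder + the named heads) and merge an
# updated subtree back into the full parameter tree.
trainable_subtree <- function(params, heads) {
  c(params[ENCODER_PARAM_NAMES], list(heads = params$heads[heads]))
}

merge_subtree <- function(params, sub) {
  params[ENCODER_PARAM_NAMES] <- sub[ENCODER_PARAM_NAMES]
  params$heads[names(sub$heads)] <- sub$heads
  params
}

# Merge encoder gradients and head gradients into a full tree aligned with
# the parameter tree.
assemble_grads <- function(enc_grads, head_grads) {
  c(enc_grads, list(heads = head_grads))
}

# Adam optimizer state and update (default hyperparameters).
adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}
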