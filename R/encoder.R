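#' Encoder architecture configuration
#'
#' All architecture hyperparameters of the spectrum transformer. The reference
#' configuration uses `d = 1024` split into a Fourier branch of width
#' `d_m = 980` and a raw-pair branch of width `d_p = 44`, 7 pre-norm
#' transformer layers with 8 heads, ReLU activations, no linear-layer biases,
#' a 4-layer feed-forward stack on the Fourier features, and 20000 mass bins
#' for the masked-peak classification head. Hidden widths that the reference
#' description leaves open (`ffn_f_hidden`, `ffn_hidden`) default to `2 * d_m`
#' and `4 * d` and are configurable.
#'
#' @param d embedding size; must equal `d_m + d_p` and divide by `heads`.
#' @param d_m,d_p Fourier / raw-pair branch widths.
#' @param layers,heads transformer depth and head count.
#' @param c_bins number of mass bins of the masked-peak head.
#' @param n_peaks peak columns of the input matrix (60 pretrain, 100
#'   finetune).
#' @param ffn_f_depth number of linear layers in the Fourier feed-forward.
#' @param ffn_f_hidden,ffn_p_hidden,ffn_hidden hidden widths.
#' @param n_props,fp_bits,emb_dim output head sizes.
#' @param bias_prefix number of leading Fourier components summed in the
#'   attention bias (`NULL` = all `2B`).
#' @param grid a [fourier_grid()]; defaults to the full-resolution grid.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(d = 1024, d_m = 980, d_p = 44, layers = 7,
                           heads = 8, c_bins = 20000, n_peaks = 60,
                           ffn_f_depth = 4, ffn_f_hidden = 2 * d_m,
                           ffn_p_hidden = d_p, ffn_hidden = 4 * d,
                           n_props = 11, fp_bits = 4096, emb_dim = d,
                           bias_prefix = NULL, grid = fourier_grid()) {
  stop_if_not(d == d_m + d_p, "d must equal d_m + d_p")
  stop_if_not(d %% heads == 0, "heads must divide d")
  stop_if_not(c_bins >= 2, "c_bins must be >= 2")
  stop_if_not(ffn_f_depth >= 1, "ffn_f_depth must be >= 1")
  two_b <- 2 * length(grid$b)
  if (!is.null(bias_prefix)) {
    stop_if_not(bias_prefix <= two_b, "bias_prefix exceeds 2B")
  }
  structure(list(d = d, d_m = d_m, d_p = d_p, layers = layers, heads = heads,
                 c_bins = c_bins, n_peaks = n_peaks, ffn_f_depth = ffn_f_depth,
                 ffn_f_hidden = ffn_f_hidden, ffn_p_hidden = ffn_p_hidden,
                 ffn_hidden = ffn_hidden, n_props = n_props, fp_bits = fp_bits,
                 emb_dim = emb_dim, bias_prefix = bias_prefix %||% two_b,
                 grid = grid),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config: d=%d (%d+%d), %d layers x %d heads, c=%d, ~%s params>\n",
              x$d, x$d_m, x$d_p, x$layers, x$heads, x$c_bins,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# Shapes of every weight tensor, as a named list of dim vectors.
param_shapes <- function(cfg) {
  two_b <- 2 * length(cfg$grid$b)
  ffn_f_dims <- c(two_b, rep(cfg$ffn_f_hidden, cfg$ffn_f_depth - 1), cfg$d_m)
  ffn_f <- lapply(seq_len(cfg$ffn_f_depth),
                  function(i) c(ffn_f_dims[i], ffn_f_dims[i + 1]))
  layer <- list(ln1_g = cfg$d, ln1_b = cfg$d,
                wq = c(cfg$d, cfg$d), wk = c(cfg$d, cfg$d),
                wv = c(cfg$d, cfg$d), wo = c(cfg$d, cfg$d),
                ln2_g = cfg$d, ln2_b = cfg$d,
                w1 = c(cfg$d, cfg$ffn_hidden), w2 = c(cfg$ffn_hidden, cfg$d))
  list(
    ffn_f = ffn_f,
    ffn_p = list(c(2, cfg$ffn_p_hidden), c(cfg$ffn_p_hidden, cfg$d_p)),
    layers = rep(list(layer), cfg$layers),
    ln_f_g = cfg$d, ln_f_b = cfg$d,
    heads = list(w_mass = c(cfg$d, cfg$c_bins),
                 w_order = c(2 * cfg$d, 1),
                 w_props = c(cfg$d, cfg$n_props),
                 w_f = c(cfg$d, 1),
                 w_emb = c(cfg$d, cfg$emb_dim),
                 w_fp0 = c(cfg$d, cfg$d),
                 w_fp1 = c(cfg$d, cfg$fp_bits))
  )
}

#' Total trainable parameter count of a configuration
#'
#' Computed analytically from the weight shapes, without allocating any
#' tensor. The reference configuration lands within order 1e8, consistent with
#' the published model scale (exact equality is not claimed because some
#' hidden widths are not printed).
#'
#' @param cfg an [encoder_config()].
#' @return numeric parameter count.
#' @export
count_params <- function(cfg) {
  shapes <- param_shapes(cfg)
  total <- 0
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      total <<- total + prod(x)
    }
  }
  walk(shapes)
  total
}

#' Initialize model parameters
#'
#' He-style scaled normal initialization for weight matrices, unit gain and
#' zero bias for the layer norms. Linear layers carry no bias terms.
#'
#' @param cfg an [encoder_config()].
#' @param seed RNG seed.
#' @return nested list of parameter arrays (a parameter tree).
#' @export
init_params <- function(cfg, seed = 1) {
  shapes <- param_shapes(cfg)
  with_seed(seed, {
    build <- function(x, name) {
      if (is.list(x)) {
        out <- lapply(seq_along(x), function(i) {
          build(x[[i]], names(x)[i] %||% "")
        })
        names(out) <- names(x)
        out
      } else if (length(x) == 1) {
        if (grepl("_g$", name)) rep(1, x) else rep(0, x)
      } else {
        matrix(rnorm(prod(x), sd = sqrt(2 / x[1])), nrow = x[1], ncol = x[2])
      }
    }
    build(shapes, "")
  })
}

relu <- function(x) pmax(x, 0)

# Row-wise layer norm; returns normalized matrix and cached statistics.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

# Feed-forward stack with ReLU between layers (none after the last); caches
# pre-activations for the backward pass.
ffn_fwd <- function(x, weights) {
  hs <- list()
  h <- x
  for (i in seq_along(weights)) {
    z <- h %*% weights[[i]]
    hs[[i]] <- list(input = h, z = z)
    h <- if (i < length(weights)) relu(z) else z
  }
  list(out = h, cache = hs)
}

#' Encode the peaks of one spectrum matrix
#'
#' Column j of the output is the concatenation of the Fourier branch
#' `FFN_F(Phi(m_j))` with the raw-pair branch `FFN_P(m_j, i_j)`, giving the
#' width-`d` peak encoding. Padded columns encode the (0, 0) pair and are
#' excluded downstream via the pad mask.
#'
#' @param sm a [spectrum_matrix()].
#' @param params parameter tree from [init_params()].
#' @param cfg the [encoder_config()].
#' @return list with `x0` ((n+1) x d matrix of encodings, one row per token)
#'   and forward caches.
#' @export
encode_peaks <- function(sm, params, cfg) {
  mz <- sm$values[1, ]
  it <- sm$values[2, ]
  phi <- fourier_features(mz, cfg$grid)
  f <- ffn_fwd(phi, params$ffn_f)
  p <- ffn_fwd(cbind(mz, it), params$ffn_p)
  list(x0 = cbind(f$out, p$out), phi = phi, f_cache = f$cache,
       p_cache = p$cache)
}

#' Pairwise attention bias from Fourier-feature differences
#'
#' Entry (i, j) is the sum over the first `prefix` Fourier components of
#' `Phi(m_i) - Phi(m_j)`: an antisymmetric, zero-diagonal matrix that lets
#' attention scores react directly to precise m/z differences (neutral
#' losses). Added to the query-key dot products before the `1/sqrt(d)`
#' scaling.
#'
#' @param phi Fourier feature matrix of the spectrum's m/z values
#'   ((n+1) x 2B).
#' @param prefix number of leading components summed.
#' @return (n+1) x (n+1) bias matrix.
#' @export
attention_bias <- function(phi, prefix = ncol(phi)) {
  stop_if_not(prefix <= ncol(phi), "prefix exceeds 2B")
  s <- rowSums(phi[, seq_len(prefix), drop = FALSE])
  outer(s, s, `-`)
}

# Numerically stable row softmax; fully masked rows become uniform over the
# unmasked set by construction upstream (queries at padded rows are unused).
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Run the transformer encoder over encoded peaks
#'
#' `layers` pre-norm blocks of multi-head self-attention (with the additive
#' Fourier-difference bias) and position-wise feed-forward nets, followed by a
#' final layer norm. Padded positions are masked out of attention as keys, so
#' adding padded columns leaves real outputs unchanged. Row 1 of the output
#' (the precursor token) is the spectrum embedding.
#'
#' @param sm a [spectrum_matrix()].
#' @param params parameter tree.
#' @param cfg the [encoder_config()].
#' @param keep_cache keep forward activations (needed for backprop).
#' @return list with `xl` ((n+1) x d final states), `embedding` (d-vector) and
#'   `cache` when requested.
#' @export
forward_encoder <- function(sm, params, cfg, keep_cache = FALSE) {
  enc <- encode_peaks(sm, params, cfg)
  x <- enc$x0
  n_tok <- nrow(x)
  bias <- attention_bias(enc$phi, cfg$bias_prefix)
  key_mask <- !sm$pad_mask
  dh <- cfg$d / cfg$heads
  scale <- 1 / sqrt(cfg$d)
  caches <- list()
  for (li in seq_len(cfg$layers)) {
    lp <- params$layers[[li]]
    ln1 <- layernorm_fwd(x, lp$ln1_g, lp$ln1_b)
    q <- ln1$y %*% lp$wq
    k <- ln1$y %*% lp$wk
    v <- ln1$y %*% lp$wv
    att <- vector("list", cfg$heads)
    o <- matrix(0, n_tok, cfg$d)
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      scores <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) + bias) * scale
      scores[, !key_mask] <- -Inf
      a <- softmax_rows(scores)
      att[[h]] <- a
      o[, cols] <- a %*% v[, cols, drop = FALSE]
    }
    attn_out <- o %*% lp$wo
    x_mid <- x + attn_out
    ln2 <- layernorm_fwd(x_mid, lp$ln2_g, lp$ln2_b)
    z1 <- ln2$y %*% lp$w1
    r1 <- relu(z1)
    ffn_out <- r1 %*% lp$w2
    x_new <- x_mid + ffn_out
    if (keep_cache) {
      caches[[li]] <- list(x_in = x, ln1 = ln1, q = q, k = k, v = v,
                           att = att, o = o, x_mid = x_mid, ln2 = ln2,
                           z1 = z1, r1 = r1)
    }
    x <- x_new
  }
  lnf <- layernorm_fwd(x, params$ln_f_g, params$ln_f_b)
  out <- list(xl = lnf$y, embedding = lnf$y[1, ])
  if (keep_cache) {
    out$cache <- list(enc = enc, layers = caches, bias = bias,
                      key_mask = key_mask, lnf = lnf, x_pre_lnf = x)
  }
  out
}

#' Output heads over final peak representations
#'
#' @param xl final (n+1) x d representation matrix ([forward_encoder()]).
#' @param params parameter tree.
#' @param task one of `"mass"`, `"order"`, `"properties"`, `"fluorine"`,
#'   `"embedding"`, `"fingerprint"`.
#' @param masked_idx token rows of masked peaks (mass task).
#' @param xl2 second spectrum's representations (order task).
#' @param pad_mask pad mask (fingerprint task sums over real tokens only).
#' @return task-specific prediction: per-masked-peak bin probabilities (rows
#'   sum to 1), elution-order probability, property vector, fluorine
#'   probability, embedding vector, or fingerprint activation vector.
#' @export
heads_forward <- function(xl, params, task, masked_idx = NULL, xl2 = NULL,
                          pad_mask = NULL) {
  hp <- params$heads
  switch(task,
    mass = {
      logits <- xl[masked_idx, , drop = FALSE] %*% hp$w_mass
      softmax_rows(logits)
    },
    order = {
      u <- c(xl[1, ], xl2[1, ])
      1 / (1 + exp(-sum(u * hp$w_order)))
    },
    properties = drop(xl[1, ] %*% hp$w_props),
    fluorine = 1 / (1 + exp(-sum(xl[1, ] * hp$w_f))),
    embedding = drop(xl[1, ] %*% hp$w_emb),
    fingerprint = {
      keep <- if (is.null(pad_mask)) seq_len(nrow(xl)) else which(!pad_mask)
      r <- relu(xl[keep, , drop = FALSE] %*% hp$w_fp0)
      drop(colSums(r) %*% hp$w_fp1)
    },
    abort(sprintf("unknown task '%s'", task))
  )
}
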