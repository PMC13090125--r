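#' Self-supervised pre-training configuration
#'
#' Masked-peak + retention-order self-supervision: 30% of the real peaks of
#' each spectrum are masked (sampled proportionally to intensity, never the
#' precursor token), masked m/z values are replaced by the sentinel -1.0 while
#' intensities stay, and the model reconstructs the mass bin of every masked
#' peak while also predicting which spectrum of a same-run pair eluted later.
#' The total loss weighs the mass term 0.8 and the order term 0.2. With 20%
#' probability a spectrum is augmented by adding one uniform shift from
#' (0, 50) Da to all its m/z values, precursor included.
#'
#' @param mask_ratio fraction of real peaks to mask.
#' @param mass_weight,order_weight loss weights (must sum to 1).
#' @param c_bins mass bins over `(0, mz_max)` Da.
#' @param mz_max upper edge of the binned mass range (Da).
#' @param shift_prob,shift_range augmentation probability and shift range.
#' @param n_peaks peak columns of the input matrices.
#' @param batch_size pairs per optimization step.
#' @param lr Adam learning rate.
#' @return a `pretrain_config`.
#' @export
pretrain_config <- function(mask_ratio = 0.3, mass_weight = 0.8,
                            order_weight = 0.2, c_bins = 20000, mz_max = 1000,
                            shift_prob = 0.2, shift_range = c(0, 50),
                            n_peaks = 60, batch_size = 64, lr = 3e-4) {
  stop_if_not(abs(mass_weight + order_weight - 1) < 1e-12,
              "mass_weight + order_weight must equal 1")
  stop_if_not(mask_ratio > 0 && mask_ratio < 1, "mask_ratio in (0, 1)")
  structure(list(mask_ratio = mask_ratio, mass_weight = mass_weight,
                 order_weight = order_weight, c_bins = c_bins, mz_max = mz_max,
                 shift_prob = shift_prob, shift_range = shift_range,
                 n_peaks = n_peaks, batch_size = batch_size, lr = lr),
            class = "pretrain_config")
}

#' Discretize a mass into its classification bin
#'
#' Equal-width half-open bins over `[0, mz_max)`: bin `b` covers
#' `[b * mz_max / c, (b + 1) * mz_max / c)`, indices 0-based.
#'
#' @param m numeric masses (Da).
#' @param c_bins number of bins.
#' @param mz_max range upper edge.
#' @return integer 0-based bin indices.
#' @export
mass_bin_label <- function(m, c_bins = 20000, mz_max = 1000) {
  stop_if_not(all(m >= 0 & m < mz_max), "mass outside [0, mz_max)")
  pmin(as.integer(floor(m * c_bins / mz_max)), c_bins - 1L)
}

#' Mask a spectrum matrix for masked-peak modeling
#'
#' Samples `round(mask_ratio * n_real)` real peaks without replacement,
#' proportionally to their intensities (successive weighted draws with
#' renormalization), replaces their m/z with -1.0 and keeps intensities. The
#' precursor column is never a candidate. Uses the current RNG state.
#'
#' @param sm a [spectrum_matrix()].
#' @param cfg a [pretrain_config()].
#' @return list: `masked` (the masked matrix), `mask_idx` (token rows of
#'   masked peaks), `labels` (0-based true bins).
#' @export
mask_spectrum_matrix <- function(sm, cfg) {
  real <- which(!sm$pad_mask)[-1]            # peak columns, excluding precursor
  n_real <- length(real)
  stop_if_not(n_real >= 1, "spectrum has no real peaks")
  n_mask <- round(cfg$mask_ratio * n_real)
  if (n_mask == 0) {
    return(list(masked = sm, mask_idx = integer(0), labels = integer(0)))
  }
  w <- sm$values[2, real]
  pick <- real[sample.int(n_real, n_mask, prob = w)]
  labels <- mass_bin_label(sm$values[1, pick], cfg$c_bins, cfg$mz_max)
  out <- sm
  out$values[1, pick] <- -1.0
  list(masked = out, mask_idx = pick, labels = labels)
}

#' Random m/z shift augmentation
#'
#' With probability `shift_prob`, adds one uniform scalar from `shift_range`
#' to every m/z entry (precursor included), leaving intensities unchanged, so
#' all pairwise m/z differences are preserved exactly. Uses the current RNG
#' state.
#'
#' @param sm a [spectrum_matrix()].
#' @param cfg a [pretrain_config()].
#' @return a (possibly shifted) spectrum matrix.
#' @export
augment_shift <- function(sm, cfg) {
  if (cfg$shift_prob > 0 && runif(1) < cfg$shift_prob) {
    delta <- runif(1, cfg$shift_range[1], cfg$shift_range[2])
    real <- !sm$pad_mask
    sm$values[1, real] <- sm$values[1, real] + delta
  }
  sm
}

#' Sample a same-run training pair
#'
#' Draws two distinct eligible spectra uniformly from one run; the order label
#' is 1 exactly when the second spectrum elutes later than the first. Uses the
#' current RNG state.
#'
#' @param spectra a spectra tibble sharing one `source_id`, >= 2 rows.
#' @return list with `i`, `j` (row indices) and `y_order`.
#' @export
sample_training_pair <- function(spectra) {
  stop_if_not(nrow(spectra) >= 2, "need at least 2 spectra in the run")
  stop_if_not(length(unique(spectra$source_id)) == 1,
              "pair sampling requires a single run")
  ij <- sample.int(nrow(spectra), 2)
  list(i = ij[1], j = ij[2],
       y_order = as.integer(spectra$rt[ij[2]] > spectra$rt[ij[1]]))
}

#' Pre-training losses
#'
#' The mass loss sums the negative log probability of the true bin over the
#' masked peaks of each spectrum and averages over the two spectra of the
#' pair; the order loss is binary cross-entropy; the total weighs them
#' `mass_weight` / `order_weight`.
#'
#' @param probs_i,probs_j per-masked-peak bin probability matrices.
#' @param labels_i,labels_j 0-based true bins.
#' @param yhat_order predicted elution-order probability.
#' @param y_order 0/1 label.
#' @param cfg a [pretrain_config()].
#' @return list with `loss_mass`, `loss_order`, `loss`.
#' @export
pretrain_losses <- function(probs_i, labels_i, probs_j, labels_j,
                            yhat_order, y_order, cfg = pretrain_config()) {
  nll <- function(p, lab) {
    if (!length(lab)) return(0)
    -sum(log(pmax(p[cbind(seq_along(lab), lab + 1)], 1e-300)))
  }
  loss_mass <- (nll(probs_i, labels_i) + nll(probs_j, labels_j)) / 2
  yh <- min(max(yhat_order, 1e-12), 1 - 1e-12)
  loss_order <- -(y_order * log(yh) + (1 - y_order) * log(1 - yh))
  list(loss_mass = loss_mass, loss_order = loss_order,
       loss = cfg$mass_weight * loss_mass + cfg$order_weight * loss_order)
}

# Forward + backward of one masked pair; returns loss components and the
# gradient tree (already weighted by the loss weights).
pair_grads <- function(sm_i, sm_j, y_order, params, cfg, model_cfg) {
  mi <- mask_spectrum_matrix(sm_i, cfg)
  mj <- mask_spectrum_matrix(sm_j, cfg)
  fi <- forward_encoder(mi$masked, params, model_cfg, keep_cache = TRUE)
  fj <- forward_encoder(mj$masked, params, model_cfg, keep_cache = TRUE)
  pi_ <- heads_forward(fi$xl, params, "mass", masked_idx = mi$mask_idx)
  pj <- heads_forward(fj$xl, params, "mass", masked_idx = mj$mask_idx)
  yhat <- heads_forward(fi$xl, params, "order", xl2 = fj$xl)
  losses <- pretrain_losses(pi_, mi$labels, pj, mj$labels, yhat, y_order, cfg)

  d <- model_cfg$d
  head_g <- zero_head_grads(params, c("w_mass", "w_order"))
  d_xl_i <- matrix(0, nrow(fi$xl), d)
  d_xl_j <- matrix(0, nrow(fj$xl), d)
  # mass head: d(-log p)/dlogits = p - onehot, weighted 0.5 * mass_weight
  add_mass <- function(probs, mask, labels, xl, d_xl) {
    if (!length(labels)) return(d_xl)
    dlog <- probs
    dlog[cbind(seq_along(labels), labels + 1)] <-
      dlog[cbind(seq_along(labels), labels + 1)] - 1
    dlog <- dlog * (cfg$mass_weight / 2)
    head_g$w_mass <<- head_g$w_mass +
      crossprod(xl[mask, , drop = FALSE], dlog)
    d_xl[mask, ] <- d_xl[mask, , drop = FALSE] +
      tcrossprod(dlog, params$heads$w_mass)
    d_xl
  }
  d_xl_i <- add_mass(pi_, mi$mask_idx, mi$labels, fi$xl, d_xl_i)
  d_xl_j <- add_mass(pj, mj$mask_idx, mj$labels, fj$xl, d_xl_j)
  # order head
  dlogit <- cfg$order_weight * (yhat - y_order)
  u <- c(fi$xl[1, ], fj$xl[1, ])
  head_g$w_order <- head_g$w_order + matrix(dlogit * u, ncol = 1)
  w_ord <- drop(params$heads$w_order)
  d_xl_i[1, ] <- d_xl_i[1, ] + dlogit * w_ord[seq_len(d)]
  d_xl_j[1, ] <- d_xl_j[1, ] + dlogit * w_ord[d + seq_len(d)]

  enc_i <- encoder_backward(d_xl_i, fi, params, model_cfg)
  enc_j <- encoder_backward(d_xl_j, fj, params, model_cfg)
  grads <- assemble_grads(param_add(enc_i, enc_j), head_g)
  nll_peaks <- c(peak_nll(pi_, mi$labels), peak_nll(pj, mj$labels))
  list(losses = losses, grads = grads, nll = nll_peaks,
       top1 = c(top1_hits(pi_, mi$labels), top1_hits(pj, mj$labels)))
}

peak_nll <- function(probs, labels) {
  if (!length(labels)) return(numeric(0))
  -log(pmax(probs[cbind(seq_along(labels), labels + 1)], 1e-300))
}

top1_hits <- function(probs, labels) {
  if (!length(labels)) return(logical(0))
  max.col(probs, ties.method = "first") == labels + 1
}

#' Run self-supervised pre-training at desk scale
#'
#' Full-model optimization of the masked-peak + retention-order objective with
#' Adam (default hyperparameters). Each step samples `batch_size` same-run
#' spectrum pairs, applies the shift augmentation, masks both spectra, and
#' averages gradients over the batch. Aborts on non-finite loss.
#'
#' @param spectra a spectra tibble (MS2 rows with precursor m/z and retention
#'   times; at least one `source_id` with two eligible spectra).
#' @param model_cfg an [encoder_config()].
#' @param cfg a [pretrain_config()].
#' @param steps optimization steps.
#' @param seed RNG seed controlling initialization, sampling, masking and
#'   augmentation.
#' @param params optional warm-start parameter tree.
#' @return an `ms2_model`: list with `params`, `model_cfg`, `pretrain_cfg` and
#'   a per-step `trace` tibble (`loss_mass`, `loss_order`, `loss`,
#'   `top1_acc`).
#' @export
pretrain <- function(spectra, model_cfg, cfg = pretrain_config(), steps = 100,
                     seed = 1, params = NULL) {
  eligible <- dplyr::filter(spectra, .data$ms_level == 2L, .data$valid,
                            is.finite(.data$precursor_mz), !is.na(.data$rt))
  stop_if_not(nrow(eligible) > 0, "no eligible spectra")
  runs <- split(seq_len(nrow(eligible)), eligible$source_id)
  runs <- runs[lengths(runs) >= 2]
  stop_if_not(length(runs) > 0, "no run has two eligible spectra")
  sms <- purrr::pmap(list(eligible$mz, eligible$intensity,
                          eligible$precursor_mz),
                     spectrum_matrix, n = cfg$n_peaks)
  params <- params %||% init_params(model_cfg, seed = derive_seed(seed, "init"))
  active_heads <- c("w_mass", "w_order")
  state <- adam_init(trainable_subtree(params, active_heads))
  trace <- vector("list", steps)
  with_seed(derive_seed(seed, "train"), {
    for (step in seq_len(steps)) {
      acc <- NULL
      l_mass <- l_order <- l_tot <- 0
      hits <- logical(0)
      nlls <- numeric(0)
      for (b in seq_len(cfg$batch_size)) {
        run <- runs[[sample.int(length(runs), 1)]]
        pair <- sample_training_pair(eligible[run, , drop = FALSE])
        sm_i <- augment_shift(sms[[run[pair$i]]], cfg)
        sm_j <- augment_shift(sms[[run[pair$j]]], cfg)
        pg <- pair_grads(sm_i, sm_j, pair$y_order, params, cfg, model_cfg)
        acc <- if (is.null(acc)) pg$grads else param_add(acc, pg$grads)
        l_mass <- l_mass + pg$losses$loss_mass
        l_order <- l_order + pg$losses$loss_order
        l_tot <- l_tot + pg$losses$loss
        hits <- c(hits, pg$top1)
        nlls <- c(nlls, pg$nll)
      }
      if (!is.finite(l_tot)) {
        abort(sprintf("divergence: non-finite loss at step %d", step),
              class = "ms2embed_train_error")
      }
      grads <- param_scale(acc, 1 / cfg$batch_size)
      upd <- adam_step(trainable_subtree(params, active_heads), grads, state,
                       lr = cfg$lr)
      params <- merge_subtree(params, upd$params)
      state <- upd$state
      trace[[step]] <- tibble(step = step, loss_mass = l_mass / cfg$batch_size,
                              loss_order = l_order / cfg$batch_size,
                              loss = l_tot / cfg$batch_size,
                              nll_mass = if (length(nlls)) mean(nlls) else NA_real_,
                              top1_acc = if (length(hits)) mean(hits) else NA_real_)
    }
  })
  structure(list(params = params, model_cfg = model_cfg, pretrain_cfg = cfg,
                 trace = dplyr::bind_rows(trace), task = "pretrain"),
            class = "ms2_model")
}

#' @export
print.ms2_model <- function(x, ...) {
  cat(sprintf("<ms2_model: task=%s, d=%d, %d layers, %s steps trained>\n",
              x$task, x$model_cfg$d, x$model_cfg$layers,
              if (is.null(x$trace)) "0" else nrow(x$trace)))
  invisible(x)
}

#' Embed spectra with a trained model
#'
#' The embedding of a spectrum is the final representation of its precursor
#' token.
#'
#' @param spectra a spectra tibble.
#' @param model an `ms2_model`.
#' @param n_peaks peak budget per spectrum (defaults to the model's).
#' @return numeric matrix, one embedding row per spectrum.
#' @export
embed_spectra <- function(spectra, model, n_peaks = NULL) {
  n_peaks <- n_peaks %||% model$model_cfg$n_peaks
  emb <- purrr::pmap(list(spectra$mz, spectra$intensity, spectra$precursor_mz),
                     function(m, i, p) {
                       sm <- spectrum_matrix(m, i, p, n = n_peaks)
                       forward_encoder(sm, model$params, model$model_cfg)$embedding
                     })
  do.call(rbind, emb)
}

#' Linear probing of embeddings against fingerprint bits
#'
#' Trains one linear layer + sigmoid (logistic regression, BCE) on frozen
#' embeddings to predict binary fingerprint bits, and reports the best
#' validation recall over the epoch budget with its matching precision.
#' All-zero (degenerate) bits are excluded from averaging.
#'
#' @param embeddings n x d matrix.
#' @param bits n x B 0/1 matrix of fingerprint labels.
#' @param epochs gradient-descent epochs.
#' @param val_fraction held-out fraction.
#' @param lr learning rate.
#' @param seed RNG seed for the split.
#' @return list with `recall`, `precision` and the epoch trace.
#' @export
probe_fingerprints <- function(embeddings, bits, epochs = 50,
                               val_fraction = 0.3, lr = 0.5, seed = 1) {
  n <- nrow(embeddings)
  stop_if_not(nrow(bits) == n, "embeddings/bits misaligned")
  idx_val <- with_seed(seed, sample.int(n, max(1, round(val_fraction * n))))
  idx_tr <- setdiff(seq_len(n), idx_val)
  keep_bits <- colSums(bits[idx_tr, , drop = FALSE]) > 0
  stop_if_not(any(keep_bits), "all fingerprint bits degenerate")
  y_tr <- bits[idx_tr, keep_bits, drop = FALSE]
  y_val <- bits[idx_val, keep_bits, drop = FALSE]
  x_tr <- scale(embeddings[idx_tr, , drop = FALSE])
  ctr <- attr(x_tr, "scaled:center")
  scl <- attr(x_tr, "scaled:scale")
  scl[scl == 0 | !is.finite(scl)] <- 1
  x_val <- sweep(sweep(embeddings[idx_val, , drop = FALSE], 2, ctr), 2, scl, `/`)
  d <- ncol(x_tr)
  w <- matrix(0, d, ncol(y_tr))
  b <- rep(0, ncol(y_tr))
  best <- list(recall = 0, precision = 0)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    p <- 1 / (1 + exp(-(x_tr %*% w + matrix(b, nrow(x_tr), length(b), byrow = TRUE))))
    dlog <- (p - y_tr) / nrow(x_tr)
    w <- w - lr * crossprod(x_tr, dlog)
    b <- b - lr * colSums(dlog)
    pv <- 1 / (1 + exp(-(x_val %*% w + matrix(b, nrow(x_val), length(b), byrow = TRUE))))
    pred <- pv > 0.5
    has_pos <- colSums(y_val) > 0
    rec <- mean(vapply(which(has_pos), function(jj) {
      sum(pred[, jj] & y_val[, jj] == 1) / sum(y_val[, jj] == 1)
    }, numeric(1)))
    prec_den <- vapply(which(has_pos), function(jj) sum(pred[, jj]), numeric(1))
    prec <- mean(vapply(seq_along(which(has_pos)), function(ii) {
      jj <- which(has_pos)[ii]
      if (prec_den[ii] == 0) return(1)
      sum(pred[, jj] & y_val[, jj] == 1) / prec_den[ii]
    }, numeric(1)))
    hist[ep] <- rec
    if (!is.na(rec) && rec > best$recall) best <- list(recall = rec, precision = prec)
  }
  c(best, list(trace = hist))
}
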