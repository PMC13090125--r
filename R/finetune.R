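#' Fine-tuning configuration
#'
#' Defaults follow the reference setting: contrastive margin 0.1, cosine
#' stability epsilon 1e-8, focal loss alpha 0.8 and gamma 0.5, 11 molecular
#' properties, hard-negative precursor mass window 0.05 Da and a 100-peak
#' input budget.
#'
#' @param margin contrastive (triplet) margin.
#' @param eps cosine numerical-stability constant.
#' @param focal_alpha,focal_gamma focal loss terms.
#' @param n_props number of jointly predicted properties.
#' @param negative_mass_window precursor mass window for hard negatives (Da).
#' @param n_peaks peak columns of the input matrices.
#' @param lr Adam learning rate.
#' @param batch_size examples per optimization step.
#' @return a `finetune_config`.
#' @export
finetune_config <- function(margin = 0.1, eps = 1e-8, focal_alpha = 0.8,
                            focal_gamma = 0.5, n_props = 11,
                            negative_mass_window = 0.05, n_peaks = 100,
                            lr = 3e-4, batch_size = 32) {
  stop_if_not(margin > 0, "margin must be positive")
  stop_if_not(focal_alpha > 0 && focal_alpha < 1, "alpha in (0,1)")
  stop_if_not(focal_gamma >= 0, "gamma must be nonnegative")
  structure(list(margin = margin, eps = eps, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, n_props = n_props,
                 negative_mass_window = negative_mass_window,
                 n_peaks = n_peaks, lr = lr, batch_size = batch_size),
            class = "finetune_config")
}

#' Mine contrastive triplets from an annotated library
#'
#' A triplet pairs a reference spectrum with a positive (another spectrum of
#' the same molecule, i.e. sharing the identity key) and a hard negative (a
#' spectrum of a different molecule whose precursor mass lies within the mass
#' window of the reference's). Returns all valid triples, optionally
#' subsampled.
#'
#' @param library an annotated spectra tibble with a `molecule_key` column.
#' @param cfg a [finetune_config()].
#' @param max_triplets optional cap, drawn uniformly with `seed`.
#' @param seed RNG seed used when capping.
#' @return tibble with `reference`, `positive`, `negative` row indices
#'   (possibly empty).
#' @export
mine_triplets <- function(library, cfg = finetune_config(),
                          max_triplets = NULL, seed = 1) {
  stop_if_not(nrow(library) > 0, "empty library")
  key <- library$molecule_key
  pmz <- library$precursor_mz
  out <- list()
  for (r in seq_len(nrow(library))) {
    pos <- which(key == key[r])
    pos <- pos[pos != r]
    if (!length(pos)) next
    neg <- which(key != key[r] & abs(pmz - pmz[r]) <= cfg$negative_mass_window)
    if (!length(neg)) next
    grid <- expand.grid(positive = pos, negative = neg)
    out[[length(out) + 1]] <- tibble(reference = r, positive = grid$positive,
                                     negative = grid$negative)
  }
  trips <- if (length(out)) dplyr::bind_rows(out) else {
    tibble(reference = integer(0), positive = integer(0), negative = integer(0))
  }
  if (!is.null(max_triplets) && nrow(trips) > max_triplets) {
    keep <- with_seed(seed, sample.int(nrow(trips), max_triplets))
    trips <- trips[sort(keep), , drop = FALSE]
  }
  trips
}

#' Triplet margin loss on embedding cosines
#'
#' `max{cos(z, z-) - cos(z, z+) + margin, 0}`: zero once the reference is
#' closer (by at least the margin) to the positive than to the negative.
#'
#' @param z,z_pos,z_neg reference / positive / negative embeddings.
#' @param cfg a [finetune_config()].
#' @return nonnegative scalar.
#' @export
triplet_loss <- function(z, z_pos, z_neg, cfg = finetune_config()) {
  max(cosine_sim(z, z_neg, cfg$eps) - cosine_sim(z, z_pos, cfg$eps) +
        cfg$margin, 0)
}

#' Fingerprint cosine loss
#'
#' `1 - cos(prediction, target)`, zero at a perfect (collinear) prediction.
#'
#' @param y_hat predicted fingerprint activations.
#' @param y true binary fingerprint (must be nonzero).
#' @param eps cosine stability constant.
#' @return loss in `[0, 2]`.
#' @export
fingerprint_loss <- function(y_hat, y, eps = 1e-8) {
  stop_if_not(sum(y^2) > 0, "zero-vector fingerprint target")
  1 - cosine_sim(y_hat, y, eps)
}

#' Mean squared error over jointly predicted properties
#'
#' @param y_hat,y length-r property vectors.
#' @return `||y_hat - y||^2 / r`.
#' @export
property_loss <- function(y_hat, y) {
  stop_if_not(length(y_hat) == length(y), "property length mismatch")
  sum((y_hat - y)^2) / length(y)
}

#' Min-max property scaling from training statistics
#'
#' Learns per-property training minima and maxima and maps them to `[0, 1]`;
#' the same transform is applied unchanged to validation data (values outside
#' the training range land outside `[0, 1]`, by design).
#'
#' @param train data frame of raw training property values.
#' @return a `property_scaler`; apply with [scale_properties()].
#' @export
property_scaler <- function(train) {
  lo <- vapply(train, min, numeric(1))
  hi <- vapply(train, max, numeric(1))
  flat <- names(train)[hi == lo]
  if (length(flat)) {
    abort(sprintf("constant propert%s: %s",
                  if (length(flat) > 1) "ies" else "y",
                  paste(flat, collapse = ", ")),
          class = "ms2embed_scale_error")
  }
  structure(list(lo = lo, hi = hi), class = "property_scaler")
}

#' @rdname property_scaler
#' @param scaler a `property_scaler`.
#' @param data data frame of raw property values.
#' @export
scale_properties <- function(scaler, data) {
  out <- as_tibble(data)
  for (nm in names(out)) {
    out[[nm]] <- (out[[nm]] - scaler$lo[[nm]]) / (scaler$hi[[nm]] - scaler$lo[[nm]])
  }
  out
}

#' Focal binary cross-entropy for fluorine detection
#'
#' `-alpha_F * (1 - p_F)^gamma * log(p_F)` with `p_F` the probability assigned
#' to the true class and `alpha_F = alpha` for positives, `1 - alpha` for
#' negatives; `gamma` down-weights well-classified examples. With `gamma = 0`
#' and `alpha = 0.5` this is half the standard binary cross-entropy.
#'
#' @param y_hat predicted probability of fluorine presence.
#' @param y 0/1 label.
#' @param cfg a [finetune_config()].
#' @return nonnegative scalar.
#' @export
focal_loss <- function(y_hat, y, cfg = finetune_config()) {
  y_hat <- min(max(y_hat, .Machine$double.eps), 1 - .Machine$double.eps)
  p <- if (y == 1) y_hat else 1 - y_hat
  a <- if (y == 1) cfg$focal_alpha else 1 - cfg$focal_alpha
  -a * (1 - p)^cfg$focal_gamma * log(p)
}

# d loss / d z for the cosine-based losses. cos(a, b) gradient wrt a.
dcos_da <- function(a, b, eps = 1e-8) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  den <- max(na * nb, eps)
  b / den - sum(a * b) * a / max(na^2 * na * nb, eps)
}

#' Fine-tune a pre-trained model on an annotated library
#'
#' End-to-end optimization of the chosen task loss (embedding triplets,
#' fingerprint cosine, property regression, or focal fluorine detection) over
#' Murcko-disjoint folds, with early stopping on the validation metric
#' plateau: training halts once the metric has not improved for `patience`
#' evaluations and the best-validation parameters are returned. Aborts when
#' the folds leak (a validation molecule sub-histogram-related to a training
#' molecule).
#'
#' @param model an `ms2_model` (pre-trained or freshly initialized).
#' @param task `"similarity"`, `"fingerprint"`, `"properties"` or
#'   `"fluorine"`.
#' @param train,val annotated spectra tibbles (see
#'   [generate_annotated_library()] for the expected columns).
#' @param cfg a [finetune_config()].
#' @param steps maximum optimization steps.
#' @param eval_every evaluate validation metric every this many steps.
#' @param patience evaluations without improvement before stopping.
#' @param seed RNG seed.
#' @param check_leakage verify Murcko-histogram disjointness before training.
#' @return an `ms2_model` with fine-tuned parameters and a validation trace.
#' @export
finetune <- function(model, task = c("similarity", "fingerprint",
                                     "properties", "fluorine"),
                     train, val, cfg = finetune_config(), steps = 50,
                     eval_every = 10, patience = 3, seed = 1,
                     check_leakage = TRUE) {
  task <- match.arg(task)
  if (check_leakage && "smiles" %in% names(train) && "smiles" %in% names(val)) {
    assert_fold_disjoint(train$smiles, val$smiles)
  }
  params <- model$params
  model_cfg <- model$model_cfg
  scaler <- NULL
  if (task == "properties") {
    scaler <- property_scaler(props_frame(train))
    train_y <- as.matrix(scale_properties(scaler, props_frame(train)))
    val_y <- as.matrix(scale_properties(scaler, props_frame(val)))
  }
  trips <- if (task == "similarity") {
    tr <- mine_triplets(train, cfg)
    stop_if_not(nrow(tr) > 0, "no triplets minable from training fold")
    tr
  }
  sm_train <- purrr::pmap(list(train$mz, train$intensity, train$precursor_mz),
                          spectrum_matrix, n = cfg$n_peaks)
  active_heads <- switch(task, similarity = "w_emb",
                         fingerprint = c("w_fp0", "w_fp1"),
                         properties = "w_props", fluorine = "w_f")
  state <- adam_init(trainable_subtree(params, active_heads))
  best <- list(metric = -Inf, params = params)
  bad <- 0
  trace <- list()
  if (steps > 0) with_seed(derive_seed(seed, "finetune"), {
    for (step in seq_len(steps)) {
      acc <- NULL
      for (b in seq_len(cfg$batch_size)) {
        g <- switch(task,
          similarity = triplet_example_grads(trips, sm_train, params, cfg, model_cfg),
          fingerprint = supervised_example_grads(train, sm_train, params, cfg,
                                                 model_cfg, "fingerprint"),
          properties = supervised_example_grads(train, sm_train, params, cfg,
                                                model_cfg, "properties",
                                                targets = train_y),
          fluorine = supervised_example_grads(train, sm_train, params, cfg,
                                              model_cfg, "fluorine"))
        acc <- if (is.null(acc)) g else param_add(acc, g)
      }
      upd <- adam_step(trainable_subtree(params, active_heads),
                       param_scale(acc, 1 / cfg$batch_size), state,
                       lr = cfg$lr)
      params <- merge_subtree(params, upd$params)
      state <- upd$state
      if (step %% eval_every == 0 || step == steps) {
        m <- evaluate_task(params, model_cfg, task, val, cfg,
                           scaler = scaler,
                           val_y = if (task == "properties") val_y)
        trace[[length(trace) + 1]] <- tibble(step = step, val_metric = m)
        if (m > best$metric + 1e-9) {
          best <- list(metric = m, params = params)
          bad <- 0
        } else {
          bad <- bad + 1
          if (bad >= patience) break
        }
      }
    }
  })
  structure(list(params = best$params, model_cfg = model_cfg,
                 finetune_cfg = cfg, task = task, scaler = scaler,
                 trace = if (length(trace)) dplyr::bind_rows(trace),
                 val_metric = if (is.finite(best$metric)) best$metric),
            class = "ms2_model")
}

props_frame <- function(library) {
  stop_if_not("properties" %in% names(library),
              "library lacks a properties list-column")
  dplyr::bind_rows(lapply(library$properties, as.list))
}

#' Abort on Murcko-histogram fold leakage
#'
#' @param train_smiles,val_smiles SMILES of the two folds.
#' @param k,m relation parameters.
#' @return invisibly `TRUE`; aborts on a related cross-fold pair.
#' @export
assert_fold_disjoint <- function(train_smiles, val_smiles, k = 4, m = 5) {
  ht <- lapply(parse_smiles(unique(train_smiles)), murcko_histogram)
  hv <- lapply(parse_smiles(unique(val_smiles)), murcko_histogram)
  for (a in hv) {
    for (b in ht) {
      if (subhistogram_related(a, b, k = k, m = m)) {
        abort("fold leakage: validation molecule related to training molecule",
              class = "ms2embed_leakage_error")
      }
    }
  }
  invisible(TRUE)
}

# One sampled triplet: forward three spectra through the embedding head,
# hinge on the cosines, backprop when the hinge is active.
triplet_example_grads <- function(trips, sms, params, cfg, model_cfg) {
  row <- trips[sample.int(nrow(trips), 1), ]
  f <- lapply(c(row$reference, row$positive, row$negative), function(i) {
    forward_encoder(sms[[i]], params, model_cfg, keep_cache = TRUE)
  })
  z <- lapply(f, function(x) heads_forward(x$xl, params, "embedding"))
  hinge <- cosine_sim(z[[1]], z[[3]], cfg$eps) -
    cosine_sim(z[[1]], z[[2]], cfg$eps) + cfg$margin
  head_g <- zero_head_grads(params, "w_emb")
  enc_g <- NULL
  if (hinge > 0) {
    dz <- list(
      dcos_da(z[[1]], z[[3]], cfg$eps) - dcos_da(z[[1]], z[[2]], cfg$eps),
      -dcos_da(z[[2]], z[[1]], cfg$eps),
      dcos_da(z[[3]], z[[1]], cfg$eps)
    )
    for (t in 1:3) {
      head_g$w_emb <- head_g$w_emb + outer(f[[t]]$xl[1, ], dz[[t]])
      d_xl <- matrix(0, nrow(f[[t]]$xl), model_cfg$d)
      d_xl[1, ] <- drop(params$heads$w_emb %*% dz[[t]])
      g <- encoder_backward(d_xl, f[[t]], params, model_cfg)
      enc_g <- if (is.null(enc_g)) g else param_add(enc_g, g)
    }
  }
  if (is.null(enc_g)) {
    enc_g <- param_zeros_like(params[ENCODER_PARAM_NAMES])
  }
  assemble_grads(enc_g, head_g)
}

# One sampled supervised example for the fingerprint / properties / fluorine
# heads.
supervised_example_grads <- function(library, sms, params, cfg, model_cfg,
                                     task, targets = NULL) {
  i <- sample.int(nrow(library), 1)
  fwd <- forward_encoder(sms[[i]], params, model_cfg, keep_cache = TRUE)
  head_g <- zero_head_grads(params, switch(task,
    fingerprint = c("w_fp0", "w_fp1"), properties = "w_props",
    fluorine = "w_f"))
  d_xl <- matrix(0, nrow(fwd$xl), model_cfg$d)
  if (task == "fingerprint") {
    y <- as.numeric(library$fingerprint[[i]])
    keep <- which(!sms[[i]]$pad_mask)
    r <- relu(fwd$xl[keep, , drop = FALSE] %*% params$heads$w_fp0)
    pooled <- colSums(r)
    y_hat <- drop(pooled %*% params$heads$w_fp1)
    dy_hat <- -dcos_da(y_hat, y, cfg$eps)        # loss = 1 - cos
    head_g$w_fp1 <- head_g$w_fp1 + outer(pooled, dy_hat)
    dpooled <- drop(params$heads$w_fp1 %*% dy_hat)
    dr <- matrix(dpooled, length(keep), model_cfg$d, byrow = TRUE) * (r > 0)
    head_g$w_fp0 <- head_g$w_fp0 +
      crossprod(fwd$xl[keep, , drop = FALSE], dr)
    d_xl[keep, ] <- tcrossprod(dr, params$heads$w_fp0)
  } else if (task == "properties") {
    y <- targets[i, ]
    y_hat <- heads_forward(fwd$xl, params, "properties")
    dy <- 2 * (y_hat - y) / length(y)
    head_g$w_props <- head_g$w_props + outer(fwd$xl[1, ], dy)
    d_xl[1, ] <- drop(params$heads$w_props %*% dy)
  } else if (task == "fluorine") {
    y <- library$fluorine[i]
    y_hat <- heads_forward(fwd$xl, params, "fluorine")
    dlogit <- focal_logit_grad(y_hat, y, cfg)
    head_g$w_f <- head_g$w_f + matrix(dlogit * fwd$xl[1, ], ncol = 1)
    d_xl[1, ] <- dlogit * drop(params$heads$w_f)
  }
  enc_g <- encoder_backward(d_xl, fwd, params, model_cfg)
  assemble_grads(enc_g, head_g)
}

# d focal loss / d logit (logit of y_hat), derived analytically.
focal_logit_grad <- function(y_hat, y, cfg) {
  y_hat <- min(max(y_hat, 1e-7), 1 - 1e-7)
  p <- if (y == 1) y_hat else 1 - y_hat
  a <- if (y == 1) cfg$focal_alpha else 1 - cfg$focal_alpha
  g <- cfg$focal_gamma
  # dL/dp, then dp/dlogit = +/- y_hat (1 - y_hat)
  dl_dp <- a * (g * (1 - p)^(g - 1) * log(p) - (1 - p)^g / p)
  dp_dlogit <- if (y == 1) y_hat * (1 - y_hat) else -y_hat * (1 - y_hat)
  dl_dp * dp_dlogit
}

# Validation metric per task; larger is better.
evaluate_task <- function(params, model_cfg, task, val, cfg, scaler = NULL,
                          val_y = NULL) {
  model <- structure(list(params = params, model_cfg = model_cfg),
                     class = "ms2_model")
  sms <- purrr::pmap(list(val$mz, val$intensity, val$precursor_mz),
                     spectrum_matrix, n = cfg$n_peaks)
  if (task == "similarity") {
    trips <- mine_triplets(val, cfg)
    if (nrow(trips) == 0) return(NA_real_)
    z <- lapply(sms, function(sm) {
      heads_forward(forward_encoder(sm, params, model_cfg)$xl, params,
                    "embedding")
    })
    scores <- c(
      vapply(seq_len(nrow(trips)), function(r) {
        cosine_sim(z[[trips$reference[r]]], z[[trips$positive[r]]], cfg$eps)
      }, numeric(1)),
      vapply(seq_len(nrow(trips)), function(r) {
        cosine_sim(z[[trips$reference[r]]], z[[trips$negative[r]]], cfg$eps)
      }, numeric(1)))
    labels <- rep(c(1, 0), each = nrow(trips))
    evaluate_binary_ranking(scores, labels)
  } else if (task == "fingerprint") {
    mean(vapply(seq_along(sms), function(i) {
      fwd <- forward_encoder(sms[[i]], params, model_cfg)
      y_hat <- heads_forward(fwd$xl, params, "fingerprint",
                             pad_mask = sms[[i]]$pad_mask)
      cosine_sim(y_hat, as.numeric(val$fingerprint[[i]]), cfg$eps)
    }, numeric(1)))
  } else if (task == "properties") {
    -mean(vapply(seq_along(sms), function(i) {
      fwd <- forward_encoder(sms[[i]], params, model_cfg)
      property_loss(heads_forward(fwd$xl, params, "properties"), val_y[i, ])
    }, numeric(1)))
  } else {
    scores <- vapply(seq_along(sms), function(i) {
      heads_forward(forward_encoder(sms[[i]], params, model_cfg)$xl, params,
                    "fluorine")
    }, numeric(1))
    if (length(unique(val$fluorine)) < 2) return(NA_real_)
    evaluate_binary_ranking(scores, val$fluorine)
  }
}
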