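test_that("frequency grid matches the published block sizes", {
  g <- fourier_grid()
  expect_equal(g$n_low, 1000)
  expect_equal(length(g$b), 6000)
  expect_equal(g$b[g$n_low], 1)               # low block ends at 1/1
  expect_equal(g$b[length(g$b)], 1 / 1e-4)    # high block ends at 1/m_min
  expect_false(is.unsorted(g$b[(g$n_low + 1):length(g$b)], strictly = TRUE))
  # hand application at small scale
  g2 <- fourier_grid(m_min = 0.5, m_max = 2, high_stride = 1)
  expect_equal(g2$b, c(0.5, 1, 1, 2))
  expect_error(fourier_grid(m_min = 2), "m_min")
})

test_that("Fourier features are bounded, periodic and Pythagorean", {
  g <- fourier_grid(0.1, 10, 1)
  phi0 <- fourier_features(0, g)
  expect_true(all(phi0[seq(1, ncol(phi0), 2)] == 0))
  expect_true(all(phi0[seq(2, ncol(phi0), 2)] == 1))
  phi <- fourier_features(c(12.34, 567.8, -1), g)
  expect_true(all(phi >= -1 & phi <= 1))
  s2c2 <- phi[, seq(1, ncol(phi), 2)]^2 + phi[, seq(2, ncol(phi), 2)]^2
  expect_equal(s2c2, matrix(1, nrow(phi), ncol(phi) / 2))
  # the unit-frequency pair has period one
  k <- which(abs(g$b - 1) < 1e-12)[1]
  pa <- fourier_features(3.7, g)
  pb <- fourier_features(4.7, g)
  expect_equal(pa[, (2 * k - 1):(2 * k)], pb[, (2 * k - 1):(2 * k)],
               tolerance = 1e-9)
})

test_that("attention bias is antisymmetric with zero diagonal and matches
           brute force", {
  g <- fourier_grid(0.1, 5, 1)
  phi <- fourier_features(c(10.2, 55.7, 101.3, -1), g)
  for (prefix in c(4, ncol(phi))) {
    bias <- attention_bias(phi, prefix)
    expect_equal(diag(bias), rep(0, 4))
    expect_equal(bias, -t(bias))
    brute <- matrix(0, 4, 4)
    for (i in 1:4) {
      for (j in 1:4) {
        for (k in seq_len(prefix)) brute[i, j] <- brute[i, j] + phi[i, k] - phi[j, k]
      }
    }
    expect_equal(bias, brute, tolerance = 1e-9)
  }
  expect_error(attention_bias(phi, ncol(phi) + 1), "2B")
})

test_that("peak encoding has width d and is a pure function of (m, i)", {
  cfg <- tiny_encoder_cfg()
  params <- init_params(cfg, seed = 3)
  sm <- spectrum_matrix(c(1.5, 2.5, 2.5 + 1e-12), c(3, 8, 8), 4.2, n = 6)
  enc <- encode_peaks(sm, params, cfg)
  expect_equal(ncol(enc$x0), cfg$d)
  expect_equal(nrow(enc$x0), 7)
  # same base-peak intensity, so the shared peak has the same relative
  # intensity in both spectra and must encode identically
  sm2 <- spectrum_matrix(c(9.9, 1.5), c(8, 3), 4.2, n = 6)
  enc2 <- encode_peaks(sm2, params, cfg)
  expect_equal(enc$x0[2, ], enc2$x0[2, ], tolerance = 1e-12)
})

test_that("encoder is permutation-equivariant with invariant precursor", {
  cfg <- tiny_encoder_cfg()
  params <- init_params(cfg, seed = 11)
  mz <- c(1.1, 2.3, 3.7, 4.4)
  it <- c(0.2, 1, 0.5, 0.8)
  sm <- spectrum_matrix(mz, it, 4.9, n = 4)
  out <- forward_encoder(sm, params, cfg)
  # permuting the non-precursor columns by hand
  perm <- c(1, 4, 2, 5, 3)
  smp <- sm
  smp$values <- sm$values[, perm]
  smp$pad_mask <- sm$pad_mask[perm]
  outp <- forward_encoder(smp, params, cfg)
  expect_equal(outp$xl, out$xl[perm, ], tolerance = 1e-5)
  expect_equal(outp$embedding, out$embedding, tolerance = 1e-5)
})

test_that("padded columns do not perturb real outputs", {
  cfg <- tiny_encoder_cfg()
  params <- init_params(cfg, seed = 5)
  mz <- c(1.4, 2.2, 3.3)
  it <- c(1, 0.4, 0.9)
  out4 <- forward_encoder(spectrum_matrix(mz, it, 4.1, n = 3), params, cfg)
  out6 <- forward_encoder(spectrum_matrix(mz, it, 4.1, n = 5), params, cfg)
  expect_equal(out6$xl[1:4, ], out4$xl, tolerance = 1e-10)
  # determinism
  out4b <- forward_encoder(spectrum_matrix(mz, it, 4.1, n = 3), params, cfg)
  expect_identical(out4$xl, out4b$xl)
})

test_that("output heads respect their contracts", {
  cfg <- tiny_encoder_cfg(c_bins = 30)
  params <- init_params(cfg, seed = 9)
  sm <- spectrum_matrix(c(1.2, 2.8, 3.9), c(2, 9, 4), 4.6, n = 5)
  fwd <- forward_encoder(sm, params, cfg)
  probs <- heads_forward(fwd$xl, params, "mass", masked_idx = c(2, 4))
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  params0 <- params
  params0$heads$w_order[] <- 0
  expect_equal(heads_forward(fwd$xl, params0, "order", xl2 = fwd$xl), 0.5)
  fp <- heads_forward(fwd$xl, params, "fingerprint", pad_mask = sm$pad_mask)
  expect_length(fp, cfg$fp_bits)
  expect_length(heads_forward(fwd$xl, params, "properties"), cfg$n_props)
  pf <- heads_forward(fwd$xl, params, "fluorine")
  expect_true(pf > 0 && pf < 1)
  expect_length(heads_forward(fwd$xl, params, "embedding"), cfg$emb_dim)
  expect_error(heads_forward(fwd$xl, params, "nonsense"), "unknown task")
})

test_that("reference configuration parameter count sits at the 1e8 scale", {
  n <- count_params(encoder_config())
  expect_gt(n, 5e7)
  expect_lt(n, 5e8)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_encoder_cfg(c_bins = 20)
  params <- init_params(cfg, seed = 7)
  sm <- spectrum_matrix(c(1.2, 2.7, 3.1), c(5, 10, 2), 4.5, n = 5)
  pcfg <- pretrain_config(c_bins = 20, mz_max = 1000, n_peaks = 5,
                          mask_ratio = 0.4, shift_prob = 0)
  loss_at <- function(p) {
    set.seed(99)
    ms2embed:::pair_grads(sm, sm, 1L, p, pcfg, cfg)$losses$loss
  }
  set.seed(99)
  g <- ms2embed:::pair_grads(sm, sm, 1L, params, pcfg, cfg)$grads
  coords <- list(
    list(path = list("layers", 1, "wq"), idx = c(3, 5)),
    list(path = list("layers", 2, "w2"), idx = c(7, 2)),
    list(path = list("layers", 1, "ln2_g"), idx = 4),
    list(path = list("ffn_f", 1), idx = c(10, 3)),
    list(path = list("ffn_p", 2), idx = c(2, 2)),
    list(path = list("heads", "w_mass"), idx = c(5, 9)),
    list(path = list("heads", "w_order"), idx = c(20, 1)),
    list(path = list("ln_f_b"), idx = 7)
  )
  eps <- 1e-6
  for (co in coords) {
    get_leaf <- function(tree) purrr::reduce(co$path, function(t, k) t[[k]],
                                             .init = tree)
    set_leaf <- function(tree, val) {
      leaf <- get_leaf(tree)
      if (length(co$idx) == 2) leaf[co$idx[1], co$idx[2]] <- val
      else leaf[co$idx] <- val
      # write back along the path
      assign_path <- function(t, path, value) {
        if (length(path) == 1) {
          t[[path[[1]]]] <- value
          return(t)
        }
        t[[path[[1]]]] <- assign_path(t[[path[[1]]]], path[-1], value)
        t
      }
      assign_path(tree, co$path, leaf)
    }
    leaf <- get_leaf(params)
    cur <- if (length(co$idx) == 2) leaf[co$idx[1], co$idx[2]] else leaf[co$idx]
    gleaf <- get_leaf(g)
    gval <- if (length(co$idx) == 2) gleaf[co$idx[1], co$idx[2]] else gleaf[co$idx]
    num <- (loss_at(set_leaf(params, cur + eps)) -
              loss_at(set_leaf(params, cur - eps))) / (2 * eps)
    expect_equal(gval, num, tolerance = 1e-4)
  }
})
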