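test_that("mass bin labels follow half-open equal-width binning", {
  expect_equal(mass_bin_label(0), 0L)
  expect_equal(mass_bin_label(999.99, c_bins = 20000), 19999L)
  expect_equal(mass_bin_label(0.05, c_bins = 20000), 1L)
  expect_error(mass_bin_label(1000), "outside")
  expect_error(mass_bin_label(-0.1), "outside")
})

test_that("masking never touches the precursor and respects the ratio", {
  cfg <- pretrain_config(mask_ratio = 0.3, c_bins = 1000)
  sm <- spectrum_matrix(seq(10, 100, by = 10), c(9:1, 10), 150, n = 12)
  set.seed(1)
  for (i in 1:500) {
    mk <- mask_spectrum_matrix(sm, cfg)
    expect_false(1 %in% mk$mask_idx)
    expect_equal(length(mk$mask_idx), round(0.3 * 10))
    expect_true(all(mk$masked$values[1, mk$mask_idx] == -1.0))
    # intensities untouched
    expect_equal(mk$masked$values[2, ], sm$values[2, ])
  }
})

test_that("masking frequency tracks successive weighted draws", {
  # 3-peak spectrum, mask 1 peak: inclusion probability is proportional to
  # intensity; compare against the exact weights
  cfg <- pretrain_config(mask_ratio = 0.34, c_bins = 1000)
  sm <- spectrum_matrix(c(10, 20, 30), c(1, 2, 7), 50, n = 3)
  set.seed(42)
  picks <- replicate(6000, mask_spectrum_matrix(sm, cfg)$mask_idx)
  freq <- table(factor(picks, levels = 2:4)) / length(picks)
  probs <- c(1, 2, 7) / 10
  for (k in 1:3) {
    se <- sqrt(probs[k] * (1 - probs[k]) / 6000)
    expect_lt(abs(freq[k] - probs[k]), 4 * se)
  }
})

test_that("loss analytics: uniform baseline, weighting, perfect predictions", {
  cfg <- pretrain_config(c_bins = 20000)
  uniform <- matrix(1 / 20000, 1, 20000)
  l <- pretrain_losses(uniform, 0L, uniform, 7L, 0.5, 1L, cfg)
  expect_equal(l$loss_mass, log(20000), tolerance = 1e-9)
  expect_equal(log(20000), 9.9035, tolerance = 1e-4)
  perfect <- matrix(0, 1, 20000)
  perfect[1, 4] <- 1
  lp <- pretrain_losses(perfect, 3L, perfect, 3L, 0.5, 1L, cfg)
  expect_equal(lp$loss_mass, 0)
  # the 0.8 / 0.2 weighting
  expect_equal(0.8 * 1 + 0.2 * 2, 1.2)
  mixed <- pretrain_losses(uniform, 0L, uniform, 0L, 0.5, 1L, cfg)
  expect_equal(mixed$loss,
               0.8 * mixed$loss_mass + 0.2 * mixed$loss_order)
})

test_that("shift augmentation preserves pairwise m/z differences", {
  cfg0 <- pretrain_config(shift_prob = 0)
  sm <- spectrum_matrix(c(50, 80, 120), c(1, 2, 3), 150, n = 4)
  expect_identical(augment_shift(sm, cfg0), sm)
  cfg1 <- pretrain_config(shift_prob = 1)
  set.seed(2)
  shifted <- augment_shift(sm, cfg1)
  real <- !sm$pad_mask
  delta <- shifted$values[1, 1] - sm$values[1, 1]
  expect_gt(delta, 0)
  expect_lt(delta, 50)
  expect_equal(diff(shifted$values[1, real]), diff(sm$values[1, real]),
               tolerance = 1e-12)
  # padded columns stay zero
  expect_equal(shifted$values[1, !real], sm$values[1, !real])
  set.seed(9)
  a <- augment_shift(sm, cfg1)
  set.seed(9)
  b <- augment_shift(sm, cfg1)
  expect_identical(a, b)
})

test_that("pair sampling produces correct order labels within one run", {
  sp <- spectra_tibble(mz = list(c(1, 2), c(1, 2), c(1, 2)),
                       intensity = list(c(1, 1), c(1, 1), c(1, 1)),
                       ms_level = 2L, rt = c(10, 20, 30), precursor_mz = 5)
  set.seed(4)
  for (i in 1:50) {
    pair <- sample_training_pair(sp)
    expect_equal(pair$y_order,
                 as.integer(sp$rt[pair$j] > sp$rt[pair$i]))
    expect_true(pair$i != pair$j)
  }
  expect_error(sample_training_pair(sp[1, ]), "at least 2")
})

test_that("zero-step pretraining returns the initialization", {
  run <- generate_run(sim_config(seed = 2))
  ms2 <- dplyr::filter(run, ms_level == 2)
  cfg <- tiny_encoder_cfg(c_bins = 100, n_peaks = 12)
  pc <- pretrain_config(c_bins = 100, n_peaks = 12, batch_size = 2)
  m0 <- pretrain(ms2, cfg, pc, steps = 0, seed = 3)
  expect_identical(m0$params, init_params(cfg, seed = ms2embed:::derive_seed(3, "init")))
})

test_that("short pretraining is seed-deterministic and reduces the loss", {
  runs <- dplyr::bind_rows(lapply(1:2, function(s) {
    generate_run(sim_config(seed = s, n_ms1 = 5, ms2_per_ms1 = 4))
  }))
  ms2 <- dplyr::filter(runs, ms_level == 2)
  cfg <- tiny_encoder_cfg(c_bins = 100, n_peaks = 12)
  pc <- pretrain_config(c_bins = 100, n_peaks = 12, batch_size = 4, lr = 3e-3)
  m1 <- pretrain(ms2, cfg, pc, steps = 25, seed = 5)
  m2 <- pretrain(ms2, cfg, pc, steps = 25, seed = 5)
  expect_identical(tidy(m1), tidy(m2))
  tr <- tidy(m1)
  expect_lt(mean(tail(tr$loss, 5)), mean(utils::head(tr$loss, 5)))
  expect_true(all(is.finite(tr$loss)))
})

test_that("linear probe separates separable labels and not random ones", {
  set.seed(6)
  n <- 120
  emb <- matrix(rnorm(n * 8), n, 8)
  w_true <- matrix(rnorm(8 * 5), 8, 5)
  bits <- (emb %*% w_true > 0) * 1L
  res <- probe_fingerprints(emb, bits, epochs = 200, seed = 2)
  expect_gt(res$recall, 0.8)
  rand_bits <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  res_rand <- probe_fingerprints(emb, rand_bits, epochs = 50, seed = 2)
  expect_lt(res_rand$recall, res$recall)
})
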