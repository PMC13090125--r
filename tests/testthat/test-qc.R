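test_that("accuracy estimation matches the brute-force oracle", {
  for (sigma in c(0, 1e-3, 5e-3)) {
    run <- generate_run(sim_config(jitter_sigma = sigma, n_ms1 = 50, seed = 7))
    expect_equal(estimate_instrument_accuracy(run), oracle_accuracy(run),
                 tolerance = 1e-12)
  }
  # zero jitter means zero dispersion
  run0 <- generate_run(sim_config(jitter_sigma = 0, n_ms1 = 20, seed = 2))
  expect_equal(estimate_instrument_accuracy(run0), 0)
})

test_that("accuracy is undefined below five XIC points and errors without MS1", {
  run3 <- generate_run(sim_config(n_ms1 = 3, seed = 1))
  expect_true(is.na(estimate_instrument_accuracy(run3)))
  ms2_only <- spectra_tibble(mz = list(c(1, 2)), intensity = list(c(1, 1)),
                             ms_level = 2L, precursor_mz = 10)
  expect_error(estimate_instrument_accuracy(ms2_only),
               class = "ms2embed_qc_error")
})

test_that("accuracy grows monotonically with injected jitter", {
  sigmas <- c(0, 1e-4, 1e-3, 1e-2)
  est <- vapply(sigmas, function(s) {
    estimate_instrument_accuracy(
      generate_run(sim_config(jitter_sigma = s, n_ms1 = 40, seed = 11)))
  }, numeric(1))
  expect_false(is.unsorted(est))
})

test_that("spectrum-type classification matches hand-executed cases", {
  mz7 <- c(100.0, 499.98, 499.99, 500.00, 500.01, 500.02, 1000.0)
  expect_equal(classify_spectrum_type(mz7, c(0, .6, .9, 1, .8, .6, 0)),
               "PROFILE")
  expect_equal(classify_spectrum_type(mz7, c(.1, .6, .9, 1, .8, .6, .1)),
               "THRESHOLDED")
  expect_equal(classify_spectrum_type(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "CENTROID")
  # wide half-max window relative to the spectrum span: sticks
  expect_equal(classify_spectrum_type(c(100, 200, 300, 400, 500),
                                      c(.6, .8, 1, .9, .7)), "CENTROID")
})

test_that("spectrum-type classification agrees with the literal oracle on a
           constructed battery", {
  battery <- list()
  # narrow profile clusters, thresholded variants, sticks, small spectra
  for (center in c(150, 200, 350, 500, 800)) {
    base <- c(center - 0.02, center - 0.01, center, center + 0.01, center + 0.02)
    battery[[length(battery) + 1]] <-
      list(mz = c(100, base, 900), intensity = c(0, .6, .9, 1, .8, .6, 0))
    battery[[length(battery) + 1]] <-
      list(mz = c(100, base, 900), intensity = c(.2, .6, .9, 1, .8, .6, .2))
    battery[[length(battery) + 1]] <-
      list(mz = seq(center - 200, center + 200, by = 40),
           intensity = c(rep(.3, 5), 1, rep(.3, 5)))
  }
  for (n_pk in 1:4) {
    battery[[length(battery) + 1]] <-
      list(mz = seq_len(n_pk) * 100, intensity = rep(1, n_pk))
  }
  # wide cluster failing the span criterion
  battery[[length(battery) + 1]] <-
    list(mz = c(100, 300, 400, 500, 600, 900), intensity = c(0, .7, .9, 1, .8, 0))
  # zero-bearing narrow cluster with span barely inside the limit
  battery[[length(battery) + 1]] <-
    list(mz = c(100, 499.9, 499.95, 500, 500.05, 500.1, 1000),
         intensity = c(0, .51, .9, 1, .9, .51, 0))
  expect_gte(length(battery), 20)
  for (case in battery) {
    expect_equal(classify_spectrum_type(case$mz, case$intensity),
                 oracle_spectrum_type(case$mz, case$intensity))
  }
})

test_that("file-level criteria catch ordering and level violations", {
  bad_rt <- spectra_tibble(mz = list(c(1, 2), c(1, 2), c(1, 2)),
                           intensity = list(c(1, 1), c(1, 1), c(1, 1)),
                           ms_level = c(1L, 1L, 1L), rt = c(10, 5, 20))
  rep1 <- check_file_criteria(bad_rt)
  expect_false(rep1$file_pass)
  expect_true("unordered retention times" %in% rep1$reasons)

  bad_lv <- spectra_tibble(mz = list(c(1, 2), c(1, 2), c(1, 2)),
                           intensity = list(c(1, 1), c(1, 1), c(1, 1)),
                           ms_level = c(1L, 3L, 3L), rt = c(1, 2, 3))
  expect_true("invalid MS-level sequence" %in% check_file_criteria(bad_lv)$reasons)

  short <- spectra_tibble(mz = list(c(1, 2)), intensity = list(c(1, 1)),
                          ms_level = 1L, rt = 1)
  expect_true("fewer than 3 spectra" %in% check_file_criteria(short)$reasons)

  ok <- generate_run(sim_config(seed = 5))
  rep_ok <- check_file_criteria(ok)
  expect_true(rep_ok$file_pass)
  expect_length(rep_ok$reasons, 0)
})

test_that("tier filters exclude by precursor mass, charge and mode", {
  run <- generate_run(sim_config(seed = 4, n_ms1 = 10))
  ms2_idx <- which(run$ms_level == 2L)
  run$precursor_mz[ms2_idx[1]] <- 1200
  run$precursor_charge[ms2_idx[2]] <- 2L
  run$mode[ms2_idx[3]] <- "negative"
  res <- filter_spectra(run, tier_config("B"))
  rep <- res$report
  expect_equal(rep$reason[1], "precursor m/z too high")
  expect_equal(rep$reason[2], "non-single precursor charge")
  expect_equal(rep$reason[3], "not positive ionization mode")
  expect_true(all(rep$pass[-(1:3)]))
})

test_that("tier presets are nested: A subset of B subset of C", {
  run <- generate_run(sim_config(seed = 9, jitter_sigma = 1e-4, n_ms1 = 20))
  ms2_idx <- which(run$ms_level == 2L)
  run$precursor_charge[ms2_idx[seq(1, 20, by = 4)]] <- NA_integer_
  pass <- lapply(c("A", "B", "C"), function(t) {
    filter_spectra(run, tier_config(t))$report$pass
  })
  expect_true(all(!pass[[1]] | pass[[2]]))
  expect_true(all(!pass[[2]] | pass[[3]]))
})
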