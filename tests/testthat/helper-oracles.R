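# Independent brute-force oracles, deliberately implemented differently from
# the package code paths they cross-check.

# Accuracy oracle: rebuilds both XIC rounds with plain loops over scans.
oracle_accuracy <- function(spectra) {
  ms1 <- spectra[spectra$ms_level == 1L & spectra$valid, ]
  base <- mapply(function(m, i) m[which.max(i)], ms1$mz, ms1$intensity)
  oracle_xic <- function(seed_mz, tol) {
    pts <- c()
    for (r in seq_len(nrow(ms1))) {
      mzv <- ms1$mz[[r]]
      cand <- mzv[abs(mzv - seed_mz) <= tol]
      if (length(cand)) {
        pts <- c(pts, cand[which.min(abs(cand - seed_mz))])
      }
    }
    pts
  }
  dedupe <- function(x, tol) {
    keep <- c()
    for (v in x) if (!length(keep) || min(abs(keep - v)) > tol) keep <- c(keep, v)
    keep
  }
  seeds2 <- c()
  for (m in dedupe(base, 0.5)) {
    x <- oracle_xic(m, 0.5)
    if (length(x) >= 5) seeds2 <- c(seeds2, median(x))
  }
  accs <- c()
  for (m in dedupe(seeds2, 0.01)) {
    x <- oracle_xic(m, 0.01)
    if (length(x) >= 5) accs <- c(accs, sd(x))
  }
  if (!length(accs)) NA_real_ else median(accs)
}

# Spectrum-type oracle: literal transcription of the decision procedure with
# an explicit index-set construction for the half-max window.
oracle_spectrum_type <- function(mz, intensity) {
  n <- length(mz)
  if (n < 5) return("CENTROID")
  b <- which.max(intensity)
  in_window <- intensity > intensity[b] / 2
  members <- b
  s <- b
  while (s > 1 && in_window[s - 1]) { s <- s - 1; members <- c(s, members) }
  s <- b
  while (s < n && in_window[s + 1]) { s <- s + 1; members <- c(members, s) }
  narrow <- (max(members) - min(members)) < 3
  wide <- (mz[max(members)] - mz[min(members)]) > (max(mz) - min(mz)) / 1000
  if (narrow || wide) return("CENTROID")
  if (any(intensity == 0)) "PROFILE" else "THRESHOLDED"
}

# Tiny encoder configuration used across the neural-net tests.
tiny_encoder_cfg <- function(c_bins = 50, n_peaks = 6) {
  encoder_config(d = 16, d_m = 12, d_p = 4, layers = 2, heads = 2,
                 c_bins = c_bins, n_peaks = n_peaks, ffn_f_depth = 2,
                 ffn_f_hidden = 10, ffn_p_hidden = 4, ffn_hidden = 24,
                 grid = fourier_grid(0.1, 5, 1))
}

# A handful of deterministic spectra for reuse.
toy_spectrum <- function() {
  list(mz = c(100.0, 180.5, 250.25, 310.1), intensity = c(20, 100, 55, 10))
}
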