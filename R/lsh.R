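#' Random-projection LSH model for binned spectra
#'
#' Hashing a binned spectrum against `n_planes` standard-normal hyperplanes
#' gives an `n_planes`-bit key; two spectra collide on a single hyperplane
#' with probability `1 - acos(cos_sim) / pi`, so exact-key grouping clusters
#' near-duplicate spectra in linear time. Two presets ship: `"gems-dedup"`
#' (64 hyperplanes, the deduplication configuration) and `"gems-subset"`
#' (30 hyperplanes, the subset-construction configuration); both bin 1 Da
#' windows over `[0, 1000)`.
#'
#' @param n_planes number of random hyperplanes (hash bits).
#' @param bin_width m/z bin width in Da.
#' @param mz_range half-open `[low, high)` m/z range covered by the bins.
#' @param seed RNG seed; the model is fully reproducible from it.
#' @param preset optional preset name overriding `n_planes`.
#' @return an `lsh_model` with the hyperplane matrix (`n_planes` x `n_bins`).
#' @export
lsh_model <- function(n_planes = 64, bin_width = 1, mz_range = c(0, 1000),
                      seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    n_planes <- switch(match.arg(preset, c("gems-dedup", "gems-subset")),
                       "gems-dedup" = 64, "gems-subset" = 30)
  }
  stop_if_not(n_planes >= 1, "need at least one hyperplane")
  stop_if_not(mz_range[2] > mz_range[1], "empty m/z range")
  n_bins <- as.integer(round((mz_range[2] - mz_range[1]) / bin_width))
  stop_if_not(n_bins >= 1, "n_bins must be >= 1")
  w <- with_seed(seed, matrix(rnorm(n_planes * n_bins), nrow = n_planes))
  structure(list(hyperplanes = w, n_planes = n_planes, n_bins = n_bins,
                 bin_width = bin_width, mz_range = mz_range, seed = seed),
            class = "lsh_model")
}

#' Bin a spectrum onto an equal-width m/z grid
#'
#' Intensities are summed within each half-open bin `[low_i, high_i)`; peaks
#' outside the range are dropped. Binned vectors are not normalized: the hash
#' is sign-based and cosine similarity is scale-free.
#'
#' @param mz,intensity peak vectors of one spectrum.
#' @param n_bins number of bins.
#' @param mz_range half-open range covered.
#' @return numeric vector of length `n_bins`.
#' @export
bin_spectrum <- function(mz, intensity, n_bins = 1000, mz_range = c(0, 1000)) {
  stop_if_not(n_bins >= 1, "n_bins must be >= 1")
  stop_if_not(mz_range[2] > mz_range[1], "empty m/z range")
  width <- (mz_range[2] - mz_range[1]) / n_bins
  idx <- floor((mz - mz_range[1]) / width) + 1
  keep <- mz >= mz_range[1] & mz < mz_range[2]
  out <- numeric(n_bins)
  if (any(keep)) {
    agg <- tapply(intensity[keep], idx[keep], sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Bin every spectrum in a table
#'
#' @param spectra a spectra tibble.
#' @param model an [lsh_model()] supplying the binning grid.
#' @return matrix with one row per spectrum, `model$n_bins` columns.
#' @export
bin_spectra <- function(spectra, model) {
  t(mapply(bin_spectrum, spectra$mz, spectra$intensity,
           MoreArgs = list(n_bins = model$n_bins, mz_range = model$mz_range)))
}

#' Hash binned spectra to LSH keys
#'
#' Bit k of the key is 1 exactly when hyperplane k dotted with the binned
#' vector is `>= 0` (a zero dot product hashes to 1).
#'
#' @param binned numeric vector of length `n_bins`, or a matrix with one such
#'   row per spectrum.
#' @param model an [lsh_model()].
#' @return character vector of bit-string keys (one per spectrum).
#' @export
hash_spectra <- function(binned, model) {
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = 1)
  stop_if_not(ncol(binned) == model$n_bins,
              sprintf("binned width %d does not match model n_bins %d",
                      ncol(binned), model$n_bins))
  bits <- (model$hyperplanes %*% t(binned)) >= 0   # n_planes x n_spectra
  apply(bits, 2, function(b) paste0(as.integer(b), collapse = ""))
}

#' Group spectra by exact hash key, capping cluster size
#'
#' Spectra sharing a key form one cluster; within each cluster at most `cap`
#' members are retained by seeded uniform sampling (the published subsets used
#' caps of 10 and 1000 representatives).
#'
#' @param keys character hash keys.
#' @param cap maximum retained members per cluster (`Inf` keeps all).
#' @param seed RNG seed for the within-cluster sampling.
#' @return tibble with `index`, `key`, `cluster` (integer id) and `retained`.
#' @export
cluster_by_hash <- function(keys, cap = Inf, seed = 1) {
  stop_if_not(cap >= 1, "cap must be >= 1")
  cl <- match(keys, unique(keys))
  retained <- logical(length(keys))
  with_seed(seed, {
    for (g in split(seq_along(keys), cl)) {
      keep <- if (length(g) <= cap) g else sample(g, cap)
      retained[keep] <- TRUE
    }
  })
  tibble(index = seq_along(keys), key = keys, cluster = cl,
         retained = retained)
}

#' Clustering quality metrics for an LSH clustering
#'
#' Reports, per configuration, the mean intra-cluster modified cosine
#' similarity (over multi-member clusters), the mean per-cluster precursor m/z
#' standard deviation, and the cluster-count fraction (number of clusters over
#' number of spectra).
#'
#' @param spectra the clustered spectra tibble.
#' @param clusters output of [cluster_by_hash()] aligned with `spectra`.
#' @param mz_tol fragment matching tolerance for the modified cosine (Da).
#' @return one-row tibble with `mean_intra_cosine`, `mean_precursor_sd`,
#'   `cluster_fraction`, `n_clusters`.
#' @export
lsh_cluster_metrics <- function(spectra, clusters, mz_tol = 0.1) {
  groups <- split(seq_len(nrow(spectra)), clusters$cluster)
  multi <- groups[lengths(groups) > 1]
  intra <- purrr::map_dbl(multi, function(g) {
    pairs <- utils::combn(g, 2)
    mean(apply(pairs, 2, function(p) {
      modified_cosine(spectra$mz[[p[1]]], spectra$intensity[[p[1]]],
                      spectra$precursor_mz[p[1]],
                      spectra$mz[[p[2]]], spectra$intensity[[p[2]]],
                      spectra$precursor_mz[p[2]], mz_tol = mz_tol)
    }))
  })
  psd <- purrr::map_dbl(groups, function(g) {
    if (length(g) < 2) 0 else sd(spectra$precursor_mz[g])
  })
  tibble(
    mean_intra_cosine = if (length(intra)) mean(intra) else NA_real_,
    mean_precursor_sd = mean(psd),
    cluster_fraction = length(groups) / nrow(spectra),
    n_clusters = length(groups)
  )
}
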