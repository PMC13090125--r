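#' Build a tidy table of tandem mass spectra
#'
#' The package represents an LC-MS/MS acquisition (and any collection of
#' spectra) as a tibble with one row per spectrum and list-columns holding the
#' peak vectors. All user-facing functions take and return this shape, so
#' pipelines compose with the pipe.
#'
#' @param mz list of numeric vectors of m/z values (Da), one per spectrum.
#' @param intensity list of numeric vectors of peak intensities, matched to
#'   `mz`.
#' @param ms_level integer MS level (1 for survey scans, 2 for fragment
#'   spectra).
#' @param rt retention time in seconds.
#' @param precursor_mz precursor ion m/z in Da (`NA` for MS1 scans).
#' @param precursor_charge integer precursor charge; `NA` when unknown.
#' @param mode ionization mode: `"positive"`, `"negative"` or `"unknown"`.
#' @param scan acquisition index within the source run.
#' @param source_id opaque run identifier (e.g. the source file name).
#'
#' @return A tibble of class `ms_spectra` with columns `scan`, `ms_level`,
#'   `rt`, `precursor_mz`, `precursor_charge`, `mode`, `mz`, `intensity`,
#'   `source_id`, `valid` and `invalid_reason`. Spectra violating the peak-list
#'   invariants (matching lengths, strictly increasing positive m/z,
#'   nonnegative intensities) are carried with `valid = FALSE` and a reason,
#'   never silently dropped: downstream quality control must be able to see
#'   them.
#' @export
spectra_tibble <- function(mz, intensity, ms_level = 2L, rt = NA_real_,
                           precursor_mz = NA_real_,
                           precursor_charge = NA_integer_,
                           mode = "positive", scan = NULL,
                           source_id = "memory") {
  if (!is.list(mz)) mz <- list(mz)
  if (!is.list(intensity)) intensity <- list(intensity)
  n <- length(mz)
  scan <- scan %||% seq_len(n)
  out <- tibble(
    scan = as.integer(rep_len(scan, n)),
    ms_level = as.integer(rep_len(ms_level, n)),
    rt = as.numeric(rep_len(rt, n)),
    precursor_mz = as.numeric(rep_len(precursor_mz, n)),
    precursor_charge = as.integer(rep_len(precursor_charge, n)),
    mode = rep_len(mode, n),
    mz = lapply(mz, as.numeric),
    intensity = lapply(intensity, as.numeric),
    source_id = rep_len(source_id, n)
  )
  out <- validate_spectra(out)
  class(out) <- c("ms_spectra", class(out))
  out
}

#' Flag invalid spectra
#'
#' Checks every spectrum against the peak-list invariants and records the
#' first violated one. Corrupted spectra (empty peak lists, negative
#' intensities, duplicated or non-increasing m/z values) are representable on
#' purpose so that quality control can detect and report them.
#'
#' @param spectra a spectra tibble (see [spectra_tibble()]).
#' @return `spectra` with refreshed `valid` / `invalid_reason` columns.
#' @export
validate_spectra <- function(spectra) {
  reason <- purrr::map2_chr(spectra$mz, spectra$intensity, function(m, i) {
    if (length(m) != length(i)) return("mz/intensity length mismatch")
    if (length(m) == 0) return("empty spectrum")
    if (anyNA(m) || anyNA(i)) return("missing peak values")
    if (any(i < 0)) return("negative intensity")
    if (any(m <= 0)) return("non-positive mz")
    if (anyDuplicated(m)) return("duplicate identical mz")
    if (is.unsorted(m, strictly = TRUE)) return("mz not strictly increasing")
    NA_character_
  })
  spectra$valid <- is.na(reason)
  spectra$invalid_reason <- reason
  spectra
}

# Keep the n most intense peaks; ties broken by lower m/z first.
top_n_peaks <- function(mz, intensity, n) {
  if (length(mz) <= n) {
    keep <- seq_along(mz)
  } else {
    ord <- order(-intensity, mz)
    keep <- sort(ord[seq_len(n)])
  }
  list(mz = mz[keep], intensity = intensity[keep])
}

#' Convert one spectrum to the model input matrix
#'
#' Builds the 2 x (n + 1) input of the encoder: the first column is the
#' precursor token `(m0, 1.1)`, whose sentinel intensity 1.1 lies outside the
#' `[0, 1]` range of relative peak intensities and marks the aggregation
#' token. The remaining columns hold up to `n` peaks as (m/z, relative
#' intensity) pairs, relative to the base peak, ordered by ascending m/z.
#' Spectra with more than `n` peaks keep the `n` most intense; shorter spectra
#' are zero-padded with `pad_mask` set.
#'
#' @param mz,intensity numeric peak vectors of one spectrum.
#' @param precursor_mz precursor m/z in Da (required).
#' @param n number of peak columns (60 for pre-training, 100 for fine-tuning
#'   in the reference configuration).
#' @return list with `values` (2 x (n+1) matrix, row 1 m/z, row 2 intensity)
#'   and `pad_mask` (logical length n+1, `TRUE` on padded columns).
#' @export
spectrum_matrix <- function(mz, intensity, precursor_mz, n = 60) {
  stop_if_not(length(mz) >= 1, "spectrum has no peaks")
  stop_if_not(length(mz) == length(intensity), "mz/intensity length mismatch")
  stop_if_not(is.finite(precursor_mz), "missing precursor_mz")
  kept <- top_n_peaks(mz, intensity, n)
  ord <- order(kept$mz)
  pk_mz <- kept$mz[ord]
  pk_int <- kept$intensity[ord] / max(intensity)
  n_real <- length(pk_mz)
  values <- matrix(0, nrow = 2, ncol = n + 1)
  values[, 1] <- c(precursor_mz, 1.1)
  if (n_real > 0) {
    values[1, 1 + seq_len(n_real)] <- pk_mz
    values[2, 1 + seq_len(n_real)] <- pk_int
  }
  pad_mask <- c(FALSE, rep(FALSE, n_real), rep(TRUE, n - n_real))
  structure(list(values = values, pad_mask = pad_mask),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  n_real <- sum(!x$pad_mask) - 1
  cat(sprintf("<spectrum_matrix: %d real peaks + precursor, %d padded>\n",
              n_real, sum(x$pad_mask)))
  invisible(x)
}
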