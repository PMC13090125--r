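#' Write spectra to the columnar tensor store
#'
#' The store is the package's deep-learning-oriented on-disk format: a
#' directory holding an Arrow/Feather table of fixed-width, zero-padded peak
#' tensors plus per-spectrum metadata vectors (precursor m/z, retention time,
#' charge, file id, estimated accuracy, LSH key), and a JSON sidecar with the
#' schema version, `max_peaks` and the file-id mapping. All datasets share the
#' leading dimension and round-trip bit-exactly for finite values.
#'
#' @param spectra a spectra tibble; every row must be valid
#'   ([validate_spectra()]).
#' @param path output directory (created; overwritten if it exists).
#' @param max_peaks fixed peak-tensor width; spectra with more peaks keep the
#'   `max_peaks` most intense ones, shorter spectra are zero-padded.
#' @param accuracy optional per-spectrum estimated instrument accuracy (Da).
#' @param lsh optional per-spectrum LSH hash keys (character).
#' @return `path`, invisibly.
#' @export
write_spectra_store <- function(spectra, path, max_peaks = 60,
                                accuracy = NULL, lsh = NULL) {
  stop_if_not(max_peaks >= 1, "max_peaks must be >= 1")
  spectra <- validate_spectra(spectra)
  if (!all(spectra$valid)) {
    bad <- which(!spectra$valid)
    abort(sprintf("invalid spectra at indices: %s",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "ms2embed_store_error")
  }
  n <- nrow(spectra)
  padded <- purrr::map2(spectra$mz, spectra$intensity, function(m, i) {
    kept <- top_n_peaks(m, i, max_peaks)
    k <- length(kept$mz)
    list(mz = c(kept$mz, rep(0, max_peaks - k)),
         intensity = c(kept$intensity, rep(0, max_peaks - k)))
  })
  file_levels <- unique(spectra$source_id)
  tab <- tibble(
    mz = lapply(padded, `[[`, "mz"),
    intensity = lapply(padded, `[[`, "intensity"),
    precursor_mz = spectra$precursor_mz,
    rt = spectra$rt,
    charge = spectra$precursor_charge,
    file_id = match(spectra$source_id, file_levels),
    accuracy = if (is.null(accuracy)) rep(NA_real_, n) else rep_len(accuracy, n),
    lsh = if (is.null(lsh)) rep(NA_character_, n) else rep_len(lsh, n)
  )
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  arrow::write_feather(tab, file.path(path, "data.feather"))
  jsonlite::write_json(
    list(format = "ms2embed-store", version = 1L, max_peaks = max_peaks,
         n_spectra = n, files = as.list(file_levels)),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read spectra back from a tensor store
#'
#' Inverse of [write_spectra_store()]: zero padding is stripped back to ragged
#' peak lists.
#'
#' @param path store directory.
#' @return a spectra tibble with `accuracy` and `lsh` columns.
#' @export
read_spectra_store <- function(path) {
  data_path <- file.path(path, "data.feather")
  meta_path <- file.path(path, "meta.json")
  stop_if_not(file.exists(data_path) && file.exists(meta_path),
              sprintf("not a spectra store: %s", path),
              class = "ms2embed_schema_error")
  meta <- jsonlite::read_json(meta_path)
  stop_if_not(identical(meta$format, "ms2embed-store"),
              "unrecognized store format", class = "ms2embed_schema_error")
  tab <- as_tibble(arrow::read_feather(data_path))
  needed <- c("mz", "intensity", "precursor_mz", "rt", "charge", "file_id",
              "accuracy", "lsh")
  missing <- setdiff(needed, names(tab))
  stop_if_not(length(missing) == 0,
              sprintf("store missing datasets: %s", paste(missing, collapse = ", ")),
              class = "ms2embed_schema_error")
  widths <- unique(c(lengths(tab$mz), lengths(tab$intensity)))
  stop_if_not(length(widths) <= 1,
              "store datasets have mismatched leading dimensions",
              class = "ms2embed_schema_error")
  if (nrow(tab) == 0) {
    out <- spectra_tibble(mz = list(), intensity = list())
    out$accuracy <- numeric(0)
    out$lsh <- character(0)
    return(out)
  }
  files <- unlist(meta$files)
  ragged <- purrr::map2(tab$mz, tab$intensity, function(m, i) {
    keep <- !(m == 0 & i == 0)
    list(mz = as.numeric(m[keep]), intensity = as.numeric(i[keep]))
  })
  out <- spectra_tibble(
    mz = lapply(ragged, `[[`, "mz"),
    intensity = lapply(ragged, `[[`, "intensity"),
    ms_level = 2L,
    rt = tab$rt,
    precursor_mz = tab$precursor_mz,
    precursor_charge = as.integer(tab$charge),
    source_id = files[tab$file_id]
  )
  out$accuracy <- tab$accuracy
  out$lsh <- tab$lsh
  out
}
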