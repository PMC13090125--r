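#' Read an LC-MS/MS run from an mzML or mzXML file
#'
#' Spectra are returned in acquisition (file) order. Corrupted spectra --
#' negative intensities, duplicated identical m/z values, empty peak lists --
#' are kept with `valid = FALSE` and a reason so that quality control can
#' report them; they are never silently dropped.
#'
#' @param path path to a `.mzML` or `.mzXML` file.
#' @return a spectra tibble (see [spectra_tibble()]).
#' @export
read_msrun <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path),
              class = "ms2embed_io_error")
  ext <- tolower(tools::file_ext(path))
  stop_if_not(ext %in% c("mzml", "mzxml"),
              sprintf("unsupported extension '.%s' (expected .mzML/.mzXML)", ext),
              class = "ms2embed_format_error")
  stop_if_not(requireNamespace("mzR", quietly = TRUE),
              "reading mzML/mzXML requires the mzR package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  mode <- dplyr::case_when(
    hdr$polarity > 0 ~ "positive",
    hdr$polarity == 0 ~ "negative",
    .default = "unknown"
  )
  charge <- hdr$precursorCharge
  charge[!is.na(charge) & charge == 0] <- NA_integer_
  out <- spectra_tibble(
    mz = lapply(pks, function(p) as.numeric(p[, 1])),
    intensity = lapply(pks, function(p) as.numeric(p[, 2])),
    ms_level = hdr$msLevel,
    rt = hdr$retentionTime,
    precursor_mz = hdr$precursorMZ,
    precursor_charge = charge,
    mode = mode,
    scan = hdr$seqNum,
    source_id = basename(path)
  )
  attr(out, "path") <- path
  out
}

#' Write a spectra tibble to mzML
#'
#' Thin wrapper over `mzR::writeMSData()`, used mostly to materialize
#' synthetic runs as standard files.
#'
#' @param spectra a spectra tibble.
#' @param path output `.mzML` path.
#' @return `path`, invisibly.
#' @export
write_msrun <- function(spectra, path) {
  stop_if_not(requireNamespace("mzR", quietly = TRUE),
              "writing mzML requires the mzR package")
  n <- nrow(spectra)
  pks <- purrr::map2(spectra$mz, spectra$intensity,
                     function(m, i) cbind(mz = m, intensity = i))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = spectra$ms_level,
    polarity = ifelse(spectra$mode == "positive", 1L,
                      ifelse(spectra$mode == "negative", 0L, -1L)),
    peaksCount = lengths(spectra$mz),
    totIonCurrent = vapply(spectra$intensity, sum, numeric(1)),
    retentionTime = spectra$rt,
    basePeakMZ = purrr::map2_dbl(spectra$mz, spectra$intensity, function(m, i) {
      if (length(m) == 0) return(0)
      m[which.max(i)]
    }),
    basePeakIntensity = vapply(spectra$intensity, function(i) {
      if (length(i) == 0) 0 else max(i)
    }, numeric(1)),
    collisionEnergy = NA_real_, ionisationEnergy = 0,
    lowMZ = vapply(spectra$mz, function(m) if (length(m)) min(m) else 0, numeric(1)),
    highMZ = vapply(spectra$mz, function(m) if (length(m)) max(m) else 0, numeric(1)),
    precursorScanNum = NA_integer_,
    precursorMZ = spectra$precursor_mz,
    precursorCharge = spectra$precursor_charge,
    precursorIntensity = ifelse(spectra$ms_level > 1, 100, NA_real_),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_
  )
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Read an annotated spectral library from MGF
#'
#' Parses the subset of the MGF dialect the package writes: `BEGIN IONS` /
#' `END IONS` blocks with `PEPMASS`, `CHARGE`, `RTINSECONDS` and free-form
#' `KEY=value` annotations (`SMILES`, `MOLECULE_KEY`, `FLUORINE`, ...).
#'
#' @param path path to an `.mgf` file.
#' @return a spectra tibble with one extra character column per annotation key
#'   found in the file.
#' @export
read_mgf <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path),
              class = "ms2embed_io_error")
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stop_if_not(length(starts) == length(ends), "malformed MGF: unbalanced blocks",
              class = "ms2embed_format_error")
  records <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                            character(1)),
                     vapply(kv, `[[`, character(1), 1))
    peak_rows <- block[!is_kv & nzchar(trimws(block))]
    pk <- do.call(rbind, lapply(strsplit(trimws(peak_rows), "[ \t]+"),
                                function(x) as.numeric(x[1:2])))
    list(meta = meta, pk = pk)
  })
  meta_keys <- unique(unlist(lapply(records, function(r) names(r$meta))))
  get_meta <- function(key) {
    vapply(records, function(r) r$meta[key] %||% NA_character_, character(1),
           USE.NAMES = FALSE)
  }
  pepmass <- suppressWarnings(as.numeric(vapply(
    strsplit(get_meta("PEPMASS"), " "), `[[`, character(1), 1)))
  charge <- suppressWarnings(as.integer(sub("\\+$", "", get_meta("CHARGE"))))
  rt <- suppressWarnings(as.numeric(get_meta("RTINSECONDS")))
  out <- spectra_tibble(
    mz = lapply(records, function(r) r$pk[, 1]),
    intensity = lapply(records, function(r) r$pk[, 2]),
    ms_level = 2L, rt = rt, precursor_mz = pepmass,
    precursor_charge = charge, mode = "positive",
    source_id = basename(path)
  )
  extra <- setdiff(meta_keys, c("PEPMASS", "CHARGE", "RTINSECONDS", "TITLE"))
  for (key in extra) out[[tolower(key)]] <- get_meta(key)
  out
}

#' Write an annotated spectral library to MGF
#'
#' @param spectra a spectra tibble; character/numeric scalar columns beyond
#'   the core ones are emitted as `KEY=value` annotations.
#' @param path output `.mgf` path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  core <- c("scan", "ms_level", "rt", "precursor_mz", "precursor_charge",
            "mode", "mz", "intensity", "source_id", "valid", "invalid_reason")
  extra <- setdiff(names(spectra), core)
  extra <- extra[vapply(spectra[extra], function(x) !is.list(x), logical(1))]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(spectra))) {
    lines <- c("BEGIN IONS",
               sprintf("TITLE=%s.%d", spectra$source_id[i], spectra$scan[i]),
               sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]))
    if (!is.na(spectra$precursor_charge[i])) {
      lines <- c(lines, sprintf("CHARGE=%d+", spectra$precursor_charge[i]))
    }
    if (!is.na(spectra$rt[i])) {
      lines <- c(lines, sprintf("RTINSECONDS=%.4f", spectra$rt[i]))
    }
    for (key in extra) {
      val <- spectra[[key]][i]
      if (!is.na(val)) lines <- c(lines, sprintf("%s=%s", toupper(key), val))
    }
    lines <- c(lines,
               sprintf("%.6f %.6f", spectra$mz[[i]], spectra$intensity[[i]]),
               "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}
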