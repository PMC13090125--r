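#' Synthetic LC-MS/MS simulation configuration
#'
#' The generator emulates exactly the statistical structure the rest of the
#' package assumes: a fragment vocabulary with deterministic per-molecule
#' co-occurrence (so masked-peak prediction is information-theoretically
#' solvable), per-instrument MS1 m/z jitter (driving accuracy estimation),
#' centroid / profile / thresholded MS2 peak shapes (driving spectrum-type
#' classification), monotone retention-time models (driving order labels),
#' uniform low-intensity noise peaks, and a proton adduct shift. Everything is
#' deterministic given the seed.
#'
#' @param n_fragments fragment vocabulary size.
#' @param mz_range m/z range of fragment masses (Da).
#' @param fragments_per_molecule fragments per molecule (contiguous window of
#'   the vocabulary, so co-occurrence identifies the molecule).
#' @param n_molecules number of distinct molecules.
#' @param jitter_sigma MS1 base-peak m/z jitter standard deviation (Da).
#' @param noise_peak_rate expected uniform noise peaks per MS2 spectrum;
#'   noise intensities sit below the 10th percentile of signal intensities.
#' @param peak_shape `"centroid"`, `"profile"` or `"thresholded"` MS2 shape.
#' @param n_ms1,ms2_per_ms1 scan counts (MS1 survey scans, MS2 per cycle).
#' @param rt_start,rt_step retention-time model (seconds; strictly monotone).
#' @param adduct_shift precursor adduct shift in Da (proton by default).
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(n_fragments = 60, mz_range = c(80, 900),
                       fragments_per_molecule = 8, n_molecules = 40,
                       jitter_sigma = 0, noise_peak_rate = 2,
                       peak_shape = c("centroid", "profile", "thresholded"),
                       n_ms1 = 10, ms2_per_ms1 = 6, rt_start = 10,
                       rt_step = 1, adduct_shift = 1.007276, seed = 1) {
  peak_shape <- match.arg(peak_shape)
  stop_if_not(n_fragments >= fragments_per_molecule, "vocabulary too small")
  stop_if_not(n_molecules >= 1 && n_ms1 >= 1, "invalid counts")
  structure(list(n_fragments = n_fragments, mz_range = mz_range,
                 fragments_per_molecule = fragments_per_molecule,
                 n_molecules = n_molecules, jitter_sigma = jitter_sigma,
                 noise_peak_rate = noise_peak_rate, peak_shape = peak_shape,
                 n_ms1 = n_ms1, ms2_per_ms1 = ms2_per_ms1,
                 rt_start = rt_start, rt_step = rt_step,
                 adduct_shift = adduct_shift, seed = seed),
            class = "sim_config")
}

# Fragment vocabulary and molecule windows; deterministic given cfg$seed.
sim_vocabulary <- function(cfg) {
  frags <- with_seed(derive_seed(cfg$seed, "vocab"), {
    sort(round(runif(cfg$n_fragments, cfg$mz_range[1], cfg$mz_range[2]), 4))
  })
  starts <- ((seq_len(cfg$n_molecules) - 1) %%
               (cfg$n_fragments - cfg$fragments_per_molecule + 1)) + 1
  members <- lapply(starts, function(s) s:(s + cfg$fragments_per_molecule - 1))
  # base fragment carries weight 1; all others stay below half the base so
  # centroided spectra classify as CENTROID
  # non-base weights stay below 0.5 even after the (0.85, 1.15) replicate
  # multiplier, so the base-peak half-max window never absorbs a neighbor
  weights <- c(1, seq(0.42, 0.15, length.out = cfg$fragments_per_molecule - 1))
  list(fragments = frags, members = members, weights = weights)
}

#' Generate a synthetic LC-MS/MS run with ground truth
#'
#' Interleaves MS1 survey scans (base peak at 500 Da jittered by
#' `jitter_sigma`, plus fixed minor peaks) with MS2 scans of the configured
#' molecules. Returns a spectra tibble carrying a `molecule` ground-truth
#' column (NA on MS1 rows).
#'
#' @param cfg a [sim_config()].
#' @return a spectra tibble.
#' @export
generate_run <- function(cfg = sim_config()) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  voc <- sim_vocabulary(cfg)
  # jitter is sigma * a fixed standard-normal draw, so runs differing only in
  # sigma share the noise realization and accuracy grows monotonically
  jit <- with_seed(derive_seed(cfg$seed, "ms1jitter"), rnorm(cfg$n_ms1))
  rows <- list()
  rt <- cfg$rt_start
  scan <- 0L
  mol_cycle <- 0L
  with_seed(derive_seed(cfg$seed, "run"), {
    for (cyc in seq_len(cfg$n_ms1)) {
      scan <- scan + 1L
      base <- 500 + cfg$jitter_sigma * jit[cyc]
      ms1_mz <- c(150.0, 300.0, base, 620.0)
      ms1_int <- c(10, 25, 100, 5)
      ord <- order(ms1_mz)
      rows[[length(rows) + 1]] <- tibble(
        scan = scan, ms_level = 1L, rt = rt, precursor_mz = NA_real_,
        precursor_charge = NA_integer_, mode = "positive",
        mz = list(ms1_mz[ord]), intensity = list(ms1_int[ord]),
        molecule = NA_integer_)
      rt <- rt + cfg$rt_step
      for (s2 in seq_len(cfg$ms2_per_ms1)) {
        scan <- scan + 1L
        mol_cycle <- mol_cycle + 1L
        # molecules elute in blocks, so retention order is predictable from
        # spectral content (the retention-time model is monotone in molecule)
        mol <- ((mol_cycle - 1L) * cfg$n_molecules) %/%
          (cfg$n_ms1 * cfg$ms2_per_ms1) + 1L
        sp <- sim_ms2_spectrum(mol, voc, cfg)
        rows[[length(rows) + 1]] <- tibble(
          scan = scan, ms_level = 2L,
          rt = cfg$rt_start + cfg$rt_step * (cfg$n_ms1 * cfg$ms2_per_ms1) +
            mol * cfg$rt_step + 0.01 * scan,
          precursor_mz = sp$precursor, precursor_charge = 1L,
          mode = "positive", mz = list(sp$mz), intensity = list(sp$intensity),
          molecule = mol)
        rt <- rt + 0
      }
    }
  })
  tab <- dplyr::bind_rows(rows)
  # MS2 retention times above follow the molecule-level monotone model but
  # must stay ordered within the file: reassign file order times increasing
  tab$rt <- cfg$rt_start + cfg$rt_step * (seq_len(nrow(tab)) - 1)
  out <- spectra_tibble(mz = tab$mz, intensity = tab$intensity,
                        ms_level = tab$ms_level, rt = tab$rt,
                        precursor_mz = tab$precursor_mz,
                        precursor_charge = tab$precursor_charge,
                        mode = tab$mode, scan = tab$scan,
                        source_id = sprintf("sim-run-%d", cfg$seed))
  out$molecule <- tab$molecule
  out
}

# One MS2 spectrum of molecule `mol` (uses the current RNG state).
sim_ms2_spectrum <- function(mol, voc, cfg) {
  frag_mz <- voc$fragments[voc$members[[mol]]]
  frag_int <- voc$weights * (0.85 + 0.3 * runif(length(frag_mz)))
  frag_int[1] <- 1  # the window's first fragment is the base peak
  base_idx <- 1
  n_noise <- stats::rpois(1, cfg$noise_peak_rate)
  if (n_noise > 0) {
    q10 <- quantile(frag_int, 0.1)
    noise_mz <- runif(n_noise, cfg$mz_range[1], cfg$mz_range[2])
    noise_int <- runif(n_noise, 0.2, 0.9) * q10
    frag_mz <- c(frag_mz, noise_mz)
    frag_int <- c(frag_int, noise_int)
  }
  ord <- order(frag_mz)
  mz <- frag_mz[ord]
  int <- frag_int[ord]
  dup <- duplicated(round(mz, 6))
  mz <- mz[!dup]
  int <- int[!dup]
  if (cfg$peak_shape != "centroid") {
    b <- which.max(int)
    cl_mz <- mz[b] + c(-0.02, -0.01, 0.01, 0.02)
    cl_int <- int[b] * c(0.6, 0.9, 0.8, 0.6)
    mz <- c(mz, cl_mz)
    int <- c(int, cl_int)
    # edge points widen the total span so the half-max window always looks
    # narrow relative to it; zero-valued for profile, floor-valued otherwise
    edge_int <- if (cfg$peak_shape == "profile") 0 else 0.05 * max(int)
    mz <- c(mz, cfg$mz_range[1] - 5, cfg$mz_range[2] + 5)
    int <- c(int, edge_int, edge_int)
    if (cfg$peak_shape == "thresholded") {
      int <- pmax(int, 0.05 * max(int))
    }
    ord <- order(mz)
    mz <- mz[ord]
    int <- int[ord]
  }
  list(mz = mz, intensity = int,
       precursor = max(voc$fragments[voc$members[[mol]]]) + cfg$adduct_shift)
}

# SMILES building blocks for the annotated library generator. Cores are
# deliberately large relative to the decorations so molecules within a family
# stay far more similar to each other than to any other family (the premise
# of scaffold-aware splitting); decorations are small substituents.
SIM_CORES <- c(
  naphthalene = "c1ccc2cc(%s)ccc2c1",
  anthracene = "c1ccc2cc3cc(%s)ccc3cc2c1",
  diphenyl_ether = "c1ccc(Oc2ccc(%s)cc2)cc1",
  phenylcyclohexane = "C1CCC(c2ccc(%s)cc2)CC1",
  quinoline = "c1ccc2nc(%s)ccc2c1",
  terphenyl = "c1ccc(-c2ccc(-c3ccc(%s)cc3)cc2)cc1"
)

SIM_SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "N", "CO", "CN",
                      "C(C)C", "CCO", "CCN", "OCC")

SIM_F_SUBSTITUENTS <- c("F", "CF", "C(F)(F)F", "CCF")

#' Generate a synthetic annotated spectral library
#'
#' Builds `n_molecules` real (parseable) molecules from scaffold-family
#' templates decorated with varying substituents, computes their true
#' fingerprints, properties and fluorine flags from the structures, and
#' simulates `spectra_per_molecule` replicate spectra per molecule from
#' deterministic pseudo-fragments of the precursor mass. When `decoys` is
#' enabled, consecutive molecule pairs receive precursor masses within 0.02 Da
#' of each other, providing hard negatives for triplet mining. Exactly
#' `round(fluorine_fraction * n_molecules)` molecules carry fluorine.
#'
#' @param n_molecules number of distinct molecules (>= 2).
#' @param spectra_per_molecule replicate spectra per molecule.
#' @param fluorine_fraction fraction of fluorinated molecules.
#' @param decoys plant same-nominal-mass decoy pairs.
#' @param seed RNG seed.
#' @return an annotated spectra tibble with `smiles`, `molecule_key` (14-char
#'   synthetic identity key), `fingerprint` and `properties` list-columns,
#'   `fluorine`, `collision_energy` and `adduct` columns.
#' @export
generate_annotated_library <- function(n_molecules = 40,
                                       spectra_per_molecule = 3,
                                       fluorine_fraction = 0.2, decoys = TRUE,
                                       seed = 1) {
  stop_if_not(n_molecules >= 2, "need at least 2 molecules")
  n_f <- round(fluorine_fraction * n_molecules)
  smiles <- character(n_molecules)
  for (i in seq_len(n_molecules)) {
    core <- SIM_CORES[[((i - 1) %% length(SIM_CORES)) + 1]]
    sub_pool <- if (i <= n_f) SIM_F_SUBSTITUENTS else SIM_SUBSTITUENTS
    sub <- sub_pool[[((i - 1) %/% length(SIM_CORES)) %% length(sub_pool) + 1]]
    smiles[i] <- sprintf(core, sub)
  }
  mols <- parse_smiles(smiles)
  mass <- molecular_mass(mols)
  fps <- morgan_fingerprint(mols)
  props <- molecular_properties(mols)
  flags <- contains_fluorine(mols)
  key <- vapply(smiles, function(s) {
    h1 <- string_hash(s)
    h2 <- string_hash(paste0("k2:", s))
    paste0(c(LETTERS[(h1 %/% 26^(0:6)) %% 26 + 1],
             LETTERS[(h2 %/% 26^(0:6)) %% 26 + 1]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  precursor <- mass + 1.007276
  if (decoys) {
    for (i in seq(1, n_molecules - 1, by = 2)) {
      precursor[i + 1] <- precursor[i] + 0.02
    }
  }
  rt_mol <- 60 + 2 * rank(mass, ties.method = "first")
  rows <- with_seed(derive_seed(seed, "library"), {
    purrr::map(seq_len(n_molecules), function(i) {
      # molecule-specific deterministic fragment ladder of the precursor
      offs <- (string_hash(paste0(smiles[i], ":", 1:6)) %% 1000) / 2500
      frac <- c(0.92, 0.81, 0.67, 0.55, 0.43, 0.31)
      frag <- sort(unique(round(precursor[i] * frac + offs, 4)))
      purrr::map(seq_len(spectra_per_molecule), function(rep_i) {
        int <- seq(1, 0.3, length.out = length(frag)) *
          exp(rnorm(length(frag), 0, 0.15))
        tibble(mz = list(frag), intensity = list(int / max(int)),
               precursor_mz = precursor[i],
               rt = rt_mol[i] + 0.1 * rep_i, molecule = i,
               collision_energy = c(20, 40, 60)[((rep_i - 1) %% 3) + 1])
      })
    })
  })
  tab <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  out <- spectra_tibble(mz = tab$mz, intensity = tab$intensity,
                        ms_level = 2L, rt = tab$rt,
                        precursor_mz = tab$precursor_mz,
                        precursor_charge = 1L, mode = "positive",
                        source_id = sprintf("sim-library-%d", seed))
  out$smiles <- smiles[tab$molecule]
  out$molecule_key <- key[tab$molecule]
  out$fingerprint <- fps[tab$molecule]
  out$properties <- lapply(tab$molecule, function(i) unlist(props[i, ]))
  out$fluorine <- flags[tab$molecule]
  out$collision_energy <- tab$collision_energy
  out$adduct <- "[M+H]+"
  out
}
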