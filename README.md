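# ms2embed

Self-supervised transformer embeddings for tandem mass spectra, in R.

Untargeted metabolomics produces millions of MS/MS spectra whose molecules
are mostly unknown; spectral libraries annotate only a small fraction.
ms2embed implements, at sizes a single CPU can exercise, a complete
self-supervised stack for learning molecular structure directly from
unannotated spectra:

- **Mining & QC** — mzML/mzXML readers, file-level checks (retention-time
  order, MS-level sequences), two-round XIC estimation of instrument m/z
  accuracy, centroid/profile/thresholded spectrum typing, and nested A/B/C
  quality tiers, feeding a columnar tensor store.
- **LSH deduplication** — random-projection hashing of binned spectra,
  `h(s) = [Ws >= 0]`, with collision probability `1 - acos(cos(s_i, s_j))/pi`
  per hyperplane, and capped exact-key clustering.
- **Murcko-histogram splitting** — scaffold rings binned by (fused-neighbor
  count, adjacent-linker count); train/validation folds with relocation so no
  two related molecules cross folds.
- **The encoder** — peaks as (m/z, intensity) tokens plus a precursor token
  with sentinel intensity 1.1; mass-tolerant Fourier features
  `sin/cos(2 pi b_i m)` on a fixed 6000-frequency grid; pre-norm transformer
  layers whose attention scores carry an additive bias from pairwise
  Fourier-feature differences (neutral losses); heads for masked-mass
  classification, retention order, fingerprints, properties, fluorine and
  contrastive embeddings. Forward pass, analytic backprop and Adam are plain
  R matrix code, finite-difference-verified.
- **Objectives** — masked-peak modeling (30% intensity-weighted masking,
  sentinel -1.0, cross-entropy over 20000 mass bins) plus retention-order
  prediction, weighted 0.8/0.2; triplet margin loss on same-mass hard
  negatives, fingerprint cosine loss, property MSE, focal fluorine loss.
- **Atlas** — exact cosine k-NN graphs over embeddings, BFS collapse of
  neighborhoods above similarity 0.9, path statistics to spectral-library
  nodes, GraphML export.
- **Synthetic data** — a seeded generator for runs and annotated libraries
  with the statistical structure every module assumes, so the whole package
  is testable without downloads.

## Worked example

```r
library(ms2embed)
library(dplyr)

# simulate two LC-MS/MS runs and quality-control them
run <- generate_run(sim_config(seed = 1, jitter_sigma = 1e-3, n_ms1 = 40))
estimate_instrument_accuracy(run)
#> [1] 0.0009210869          # recovers the injected 1e-3 Da jitter

qc <- filter_spectra(run, tier_config("A"))
nrow(qc$spectra)
#> [1] 146                   # of 240 MS2 scans; tier A's amplitude rule is
                            # strict on spectra that drew no noise peaks

# hash and deduplicate
model <- lsh_model(preset = "gems-dedup", seed = 1)
keys <- hash_spectra(bin_spectra(qc$spectra, model), model)
clusters <- cluster_by_hash(keys, cap = 10, seed = 1)
n_distinct(clusters$cluster)
#> [1] 140                   # 64-bit hashing is high-precision, low-recall:
                            # only near-duplicate replicates collide

# scaffold-aware splitting of an annotated library
lib <- generate_annotated_library(n_molecules = 40, seed = 1)
folds <- split_by_murcko(lib, val_fraction = 0.2, seed = 1)
count(folds, fold)
#> # A tibble: 2 x 2
#>   fold      n
#>   <chr> <int>
#> 1 train    99
#> 2 val      21

# desk-scale pre-training of a tiny encoder
cfg <- encoder_config(d = 64, d_m = 56, d_p = 8, layers = 2, heads = 4,
                      c_bins = 1000, n_peaks = 30, ffn_f_hidden = 112,
                      grid = fourier_grid(0.01, 100, 2))
ms2 <- filter(run, ms_level == 2)
fit <- pretrain(ms2, cfg, pretrain_config(c_bins = 1000, n_peaks = 30,
                                          batch_size = 16, lr = 3e-3),
                steps = 100, seed = 1)
glance(fit)$final_loss    # weighted masked-mass + retention-order loss
#> [1] 10.90497
emb <- embed_spectra(ms2, fit)
dim(emb)
#> [1] 240  64

# atlas over the embeddings
graph <- build_knn_graph(emb, k = 3)
atlas <- collapse_neighborhoods(graph, threshold = 0.9)
```

The masked-mass loss starts at the uniform baseline `ln(c)` and falls as the
model learns which fragment masses co-occur; `embed_spectra()` returns the
final representation of each spectrum's precursor token, whose cosine
similarities drive clustering, retrieval and the atlas.

A command-line wrapper over the same functions ships at
`inst/cli/ms2embed.R` (subcommands `simulate`, `qc`, `cluster`, `split`,
`pretrain`, `embed`, `atlas`; every output gets a JSON run manifest).

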