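Package: ms2embed
Title: Self-Supervised Transformer Embeddings for Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-controlled mining of LC-MS/MS runs into a columnar tensor
    store, locality-sensitive-hash deduplication of spectra, Murcko-histogram
    scaffold splitting of annotated libraries, a Fourier-feature transformer
    encoder for tandem mass spectra with masked-peak and retention-order
    self-supervision, fine-tuning objectives for spectral similarity,
    fingerprint, property and fluorine prediction, and construction of
    similarity-graph atlases over spectrum embeddings. Ships a seeded synthetic
    data generator so the full pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    arrow,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    ChemmineR,
    ChemmineOB,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
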