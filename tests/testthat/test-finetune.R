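test_that("triplet mining enumerates exactly the valid triples", {
  lib <- tibble::tibble(
    molecule_key = c("AAA", "AAA", "BBB"),
    precursor_mz = c(200.00, 200.01, 200.03))
  trips <- mine_triplets(lib)
  # references 1 and 2 pair with each other as positives; 3 is the only
  # in-window negative
  expect_equal(nrow(trips), 2)
  expect_setequal(trips$reference, c(1, 2))
  expect_true(all(trips$negative == 3))
  # the negative is never the reference's own molecule
  expect_false(any(lib$molecule_key[trips$negative] ==
                     lib$molecule_key[trips$reference]))
  # no negative within the window: no triples
  lib2 <- lib
  lib2$precursor_mz[3] <- 300
  expect_equal(nrow(mine_triplets(lib2)), 0)
})

test_that("triplet loss hinge cases", {
  cfg <- finetune_config(margin = 0.1)
  # orthogonal construction with known cosines
  z <- c(1, 0)
  z_pos <- c(1, 0)        # cos = 1
  z_neg <- c(0, 1)        # cos = 0
  expect_equal(triplet_loss(z, z_pos, z_neg, cfg), 0)
  expect_equal(triplet_loss(z, c(0, 1), c(0, 1), cfg), 0.1)
  expect_equal(triplet_loss(z, c(1, 0.01), c(-1, 0), cfg), 0)
  # invariance to positive rescaling
  expect_equal(triplet_loss(3 * z, c(0, 2), c(0, 5), cfg),
               triplet_loss(z, c(0, 1), c(0, 1), cfg), tolerance = 1e-9)
})

test_that("fingerprint cosine loss on hand vectors", {
  y <- c(1, 1, 0, 0)
  expect_equal(fingerprint_loss(y, y), 0, tolerance = 1e-7)
  expect_equal(fingerprint_loss(c(0, 0, 1, 1), y), 1, tolerance = 1e-7)
  # cos = 0.5 construction
  a <- c(1, 0)
  b <- c(cos(pi / 3), sin(pi / 3))
  expect_equal(fingerprint_loss(a, b), 0.5, tolerance = 1e-7)
  expect_error(fingerprint_loss(a, c(0, 0)), "zero-vector")
})

test_that("property loss and min-max scaling", {
  expect_equal(property_loss(rep(1, 11), rep(0, 11)), 1)
  expect_equal(property_loss(1:5, 1:5), 0)
  train <- tibble::tibble(a = c(1, 3, 5), b = c(10, 20, 40))
  sc <- property_scaler(train)
  scaled <- scale_properties(sc, train)
  expect_equal(range(scaled$a), c(0, 1))
  expect_equal(range(scaled$b), c(0, 1))
  val <- scale_properties(sc, tibble::tibble(a = 7, b = 10))
  expect_equal(val$a, 1.5)   # outside the training range, by design
  expect_error(property_scaler(tibble::tibble(a = c(2, 2))),
               class = "ms2embed_scale_error")
})

test_that("focal loss evaluates the printed cases and reduces to BCE/2", {
  cfg <- finetune_config(focal_alpha = 0.8, focal_gamma = 0.5)
  expect_equal(focal_loss(1, 1, cfg), 0, tolerance = 1e-7)
  expect_equal(focal_loss(0.5, 1, cfg), 0.8 * sqrt(0.5) * log(2),
               tolerance = 1e-9)
  expect_equal(0.8 * sqrt(0.5) * log(2), 0.3921, tolerance = 1e-4)
  # negative class uses weight 1 - alpha
  expect_equal(focal_loss(0.5, 0, cfg) / focal_loss(0.5, 1, cfg), 0.2 / 0.8,
               tolerance = 1e-9)
  cfg_bce <- finetune_config(focal_alpha = 0.5, focal_gamma = 0)
  for (p in c(0.1, 0.4, 0.9)) {
    for (y in 0:1) {
      bce <- -(y * log(p) + (1 - y) * log(1 - p))
      expect_equal(focal_loss(p, y, cfg_bce), bce / 2, tolerance = 1e-9)
    }
  }
})

test_that("evaluation metrics on hand-checked cases", {
  expect_equal(evaluate_similarity(1:5, 2 * (1:5) + 3), 1)
  expect_equal(evaluate_binary_ranking(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.75)
  expect_equal(evaluate_binary_ranking(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_error(evaluate_similarity(rep(1, 4), 1:4),
               class = "ms2embed_metric_error")
  # retrieval: positive ranked third counts at k >= 5 only
  pool <- list(predicted = c(1, 0, 0),
               candidates = rbind(c(1, 0, 0), c(0.9, 0.1, 0), c(0.8, 0.2, 0)),
               positive = c(FALSE, FALSE, TRUE))
  acc <- evaluate_retrieval(list(pool), k = c(1, 5))
  expect_equal(acc$accuracy, c(0, 1))
})

test_that("zero-step fine-tuning leaves weights unchanged and leaky folds
           abort", {
  skip_if_not_installed("ChemmineOB")
  lib <- generate_annotated_library(n_molecules = 10, spectra_per_molecule = 2,
                                    seed = 8)
  sp <- split_by_murcko(lib, val_fraction = 0.3, seed = 1)
  train <- sp[sp$fold == "train", ]
  val <- sp[sp$fold == "val", ]
  skip_if(nrow(val) == 0)
  cfg <- tiny_encoder_cfg(c_bins = 50, n_peaks = 10)
  model <- structure(list(params = init_params(cfg, seed = 1), model_cfg = cfg,
                          task = "pretrain"),
                     class = "ms2_model")
  ft <- finetune(model, "fluorine", train, val,
                 finetune_config(n_peaks = 10, batch_size = 2), steps = 0)
  expect_identical(ft$params, model$params)
  expect_error(
    finetune(model, "fluorine", train, train,
             finetune_config(n_peaks = 10, batch_size = 2), steps = 0),
    class = "ms2embed_leakage_error")
})

test_that("fine-tuning the fingerprint head improves validation cosine", {
  skip_if_not_installed("ChemmineOB")
  lib <- generate_annotated_library(n_molecules = 12, spectra_per_molecule = 2,
                                    seed = 4)
  sp <- split_by_murcko(lib, val_fraction = 0.25, seed = 3)
  train <- sp[sp$fold == "train", ]
  val <- sp[sp$fold == "val", ]
  skip_if(nrow(val) == 0)
  cfg <- tiny_encoder_cfg(c_bins = 50, n_peaks = 10)
  fcfg <- finetune_config(n_peaks = 10, batch_size = 8, lr = 3e-3)
  improved <- 0
  for (seed in 1:3) {
    model <- structure(list(params = init_params(cfg, seed = seed),
                            model_cfg = cfg, task = "pretrain"),
                       class = "ms2_model")
    before <- ms2embed:::evaluate_task(model$params, cfg, "fingerprint", val,
                                       fcfg)
    ft <- finetune(model, "fingerprint", train, val, fcfg, steps = 30,
                   eval_every = 10, patience = 10, seed = seed)
    after <- ft$val_metric
    if (!is.null(after) && after > before) improved <- improved + 1
  }
  expect_gte(improved, 2)
})
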