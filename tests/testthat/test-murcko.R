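test_that("hand-derived histograms for the reference molecules", {
  skip_if_not_installed("ChemmineOB")
  expect_equal(unclass(murcko_histogram("c1ccccc1")),
               unclass(mh(c("0,0" = 1L))))
  expect_equal(unclass(murcko_histogram("c1ccc2ccccc2c1")),
               unclass(mh(c("1,0" = 2L))))
  expect_length(murcko_histogram("CC"), 0)
  expect_equal(unclass(murcko_histogram("c1ccccc1Cc1ccccc1")),
               unclass(mh(c("0,1" = 2L))))
})

test_that("scaffold pruning drops decorations but keeps linkers", {
  skip_if_not_installed("ChemmineOB")
  # toluene reduces to benzene's histogram; a long chain between rings is a
  # linker path whose interior atoms count for adjacent rings only
  expect_equal(unclass(murcko_histogram("Cc1ccccc1")),
               unclass(mh(c("0,0" = 1L))))
  expect_equal(unclass(murcko_histogram("c1ccccc1CCc1ccccc1")),
               unclass(mh(c("0,1" = 2L))))
})

test_that("subhistogram relation follows the worked cases", {
  h_a <- mh(c("0,0" = 1L))
  expect_true(subhistogram_related(h_a, mh(c("0,0" = 1L))))
  expect_false(subhistogram_related(h_a, mh(c("1,0" = 2L))))
  expect_true(subhistogram_related(mh(c("1,0" = 4L)), mh(c("1,1" = 4L))))
  expect_false(subhistogram_related(mh(c("0,0" = 4L)), mh(c("1,0" = 9L))))
})

test_that("subhistogram relation is reflexive and symmetric", {
  set.seed(3)
  rand_hist <- function() {
    n <- sample(1:4, 1)
    keys <- unique(sprintf("%d,%d", sample(0:3, n, TRUE), sample(0:2, n, TRUE)))
    mh(setNames(sample(1:5, length(keys), TRUE), keys))
  }
  for (i in 1:50) {
    h1 <- rand_hist()
    h2 <- rand_hist()
    expect_true(subhistogram_related(h1, h1))
    expect_equal(subhistogram_related(h1, h2), subhistogram_related(h2, h1))
  }
})

test_that("splitting leaves no related cross-fold pair and is deterministic", {
  skip_if_not_installed("ChemmineOB")
  lib <- generate_annotated_library(n_molecules = 30, spectra_per_molecule = 1,
                                    seed = 5)
  sp1 <- split_by_murcko(lib, val_fraction = 0.3, seed = 2)
  sp2 <- split_by_murcko(lib, val_fraction = 0.3, seed = 2)
  expect_identical(sp1$fold, sp2$fold)
  vi <- which(sp1$fold == "val")
  ti <- which(sp1$fold == "train")
  expect_gt(length(vi), 0)
  for (v in vi) {
    for (t in ti) {
      expect_false(subhistogram_related(sp1$murcko_histogram[[v]],
                                        sp1$murcko_histogram[[t]]))
    }
  }
})

test_that("a single histogram group keeps validation empty", {
  skip_if_not_installed("ChemmineOB")
  sp <- split_by_murcko(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1"),
                        val_fraction = 0.4, seed = 1)
  expect_true(all(sp$fold == "train"))
})

test_that("two unrelated groups split one per fold at half fraction", {
  skip_if_not_installed("ChemmineOB")
  smiles <- c(rep("c1ccccc1", 2), rep("c1ccc2ccccc2c1", 2))
  sp <- split_by_murcko(smiles, val_fraction = 0.5, seed = 4)
  expect_setequal(unique(sp$fold), c("train", "val"))
  expect_equal(length(unique(sp$fold[sp$smiles == sp$smiles[1]])), 1)
})

test_that("fold leakage guard aborts on related folds", {
  skip_if_not_installed("ChemmineOB")
  expect_error(assert_fold_disjoint("c1ccccc1", "c1ccccc1"),
               class = "ms2embed_leakage_error")
  expect_true(assert_fold_disjoint("c1ccccc1", "c1ccc2ccccc2c1"))
})

test_that("fingerprints separate scaffold families", {
  skip_if_not_installed("ChemmineOB")
  fps <- morgan_fingerprint(c("c1ccccc1", "Cc1ccccc1", "C1CCCCC1"))
  expect_true(all(vapply(fps, length, integer(1)) == 4096))
  expect_gt(tanimoto(fps[[1]], fps[[2]]), tanimoto(fps[[1]], fps[[3]]))
  expect_equal(tanimoto(fps[[1]], fps[[1]]), 1)
})

test_that("graph descriptors behave sensibly", {
  skip_if_not_installed("ChemmineOB")
  pr <- molecular_properties(c("c1ccccc1", "c1ccc2ccccc2c1", "OCCF"))
  expect_equal(ncol(pr), 11)
  expect_equal(pr$n_rings[1:2], c(1, 2))
  expect_equal(pr$halogens[3], 1)
  expect_gt(pr$mol_weight[2], pr$mol_weight[1])
  expect_equal(contains_fluorine(c("OCCF", "CCO")), c(1L, 0L))
  expect_equal(molecular_mass("CO"), 32.0262, tolerance = 1e-3)
})
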