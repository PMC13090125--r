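make_embeddings <- function(n, d = 5, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

test_that("k-NN graph agrees with exhaustive search", {
  emb <- make_embeddings(40)
  g <- build_knn_graph(emb, k = 1)
  norms <- sqrt(rowSums(emb^2))
  sims <- tcrossprod(emb / norms)
  diag(sims) <- -Inf
  for (i in 1:40) {
    expect_equal(g$edges$to[g$edges$from == i], which.max(sims[i, ]))
  }
  g3 <- build_knn_graph(emb, k = 3)
  for (i in 1:40) {
    nb <- g3$edges$to[g3$edges$from == i]
    expect_setequal(nb, order(-sims[i, ])[1:3])
  }
})

test_that("k >= n - 1 yields the complete directed graph; duplicates get
           similarity-1 edges", {
  emb <- make_embeddings(5)
  g <- build_knn_graph(emb, k = 4)
  expect_equal(nrow(g$edges), 5 * 4)
  emb2 <- rbind(emb, emb[1, ])
  g2 <- build_knn_graph(emb2, k = 1)
  expect_equal(g2$edges$similarity[g2$edges$from == 6], 1, tolerance = 1e-9)
  expect_equal(g2$edges$to[g2$edges$from == 6], 1)
  expect_error(build_knn_graph(emb[1:3, ], k = 3),
               class = "ms2embed_graph_error")
  # no self-edges, similarities within [-1, 1]
  expect_false(any(g$edges$from == g$edges$to))
  expect_true(all(abs(g$edges$similarity) <= 1))
})

test_that("BFS collapse follows both stop rules on the chain fixture", {
  # chain a-b-c with sim(a,b)=sim(b,c)=0.95 and sim(a,c)=0.85: even though
  # every edge clears the threshold, c is too far from the start node a
  sims <- matrix(c(1, 0.95, 0.85,
                   0.95, 1, 0.95,
                   0.85, 0.95, 1), 3, 3)
  ch <- chol(sims)
  emb <- t(ch)
  g <- build_knn_graph(emb, k = 1)
  g$edges <- tibble::tibble(from = c(1L, 2L, 3L), to = c(2L, 3L, 2L),
                            similarity = c(0.95, 0.95, 0.95))
  assign <- collapse_neighborhoods(g, threshold = 0.9)
  expect_equal(assign$representative[1], assign$representative[2])
  expect_false(assign$representative[3] == assign$representative[1])
})

test_that("collapse produces a partition with self-mapped representatives", {
  emb <- make_embeddings(30, seed = 4)
  g <- build_knn_graph(emb, k = 3)
  assign <- collapse_neighborhoods(g, threshold = 0.9)
  expect_setequal(assign$node, 1:30)
  reps <- unique(assign$representative)
  expect_true(all(assign$representative[reps] == reps))
  # random gaussian embeddings rarely exceed 0.9 cosine: all singletons
  if (max(g$edges$similarity) < 0.9) {
    expect_equal(assign$representative, 1:30)
  }
})

test_that("a mutually similar clique collapses into one cluster and planted
           structure is recovered", {
  set.seed(8)
  centers <- diag(3)                       # three orthogonal directions
  emb <- do.call(rbind, lapply(1:3, function(ci) {
    t(replicate(5, centers[ci, ] + rnorm(3, 0, 0.02)))
  }))
  g <- build_knn_graph(emb, k = 3)
  assign <- collapse_neighborhoods(g, threshold = 0.9)
  planted <- rep(1:3, each = 5)
  expect_equal(length(unique(assign$representative)), 3)
  for (cl in 1:3) {
    expect_equal(length(unique(assign$representative[planted == cl])), 1)
  }
  reb <- rebuild_on_representatives(g, assign, k = 1)
  expect_equal(reb$graph$n, 3)
})

test_that("library path statistics on a hand-traced chain", {
  # path 1-2-3-4-5 with known similarities; query 1, library {4, 5}
  g <- structure(list(
    edges = tibble::tibble(from = 1:4, to = 2:5,
                           similarity = c(0.99, 0.7, 0.95, 0.8)),
    k = 1, n = 5, embeddings = make_embeddings(5)),
    class = "embedding_graph")
  st <- library_path_stats(g, query = 1, library = c(4, 5))
  expect_equal(st$hops, 3)
  expect_equal(st$min_similarity, 0.7)
  adj1 <- library_path_stats(g, query = 2, library = 3)
  expect_equal(adj1$hops, 1)
  # disconnected query
  g2 <- g
  g2$edges <- g$edges[g$edges$from != 3, ]
  st2 <- library_path_stats(g2, query = 1, library = 5)
  expect_equal(st2$hops, Inf)
  expect_error(library_path_stats(g, query = 1, library = 1), "disjoint")
})

test_that("blank samples are excluded case-insensitively", {
  sp <- spectra_tibble(mz = list(c(1, 2), c(1, 2), c(1, 2)),
                       intensity = list(c(1, 1), c(1, 1), c(1, 1)),
                       source_id = c("Sample_A.mzML", "BLANK_01.mzML",
                                     "wash-2.mzML"))
  kept <- exclude_blank_samples(sp)
  expect_equal(kept$source_id, "Sample_A.mzML")
})

test_that("GraphML export writes similarity edge attributes", {
  emb <- make_embeddings(6)
  g <- build_knn_graph(emb, k = 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_true("similarity" %in% igraph::edge_attr_names(back))
})
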