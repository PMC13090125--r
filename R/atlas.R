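#' Build a k-nearest-neighbor graph over spectrum embeddings
#'
#' Directed k-NN graph under cosine similarity. At desk scale the neighbors
#' are found by exact (vectorized brute-force) search, so the graph agrees
#' with exhaustive search by construction; the published repository-scale
#' variant uses approximate search, which this package deliberately does not
#' re-implement.
#'
#' @param embeddings numeric matrix, one embedding per row.
#' @param k neighbors per node (3 in the reference atlas).
#' @return an `embedding_graph`: list with `edges` (tibble `from`, `to`,
#'   `similarity`), `k`, `n` and the embeddings.
#' @export
build_knn_graph <- function(embeddings, k = 3) {
  n <- nrow(embeddings)
  stop_if_not(n >= k + 1, "need at least k + 1 embeddings",
              class = "ms2embed_graph_error")
  norms <- sqrt(rowSums(embeddings^2))
  sims <- tcrossprod(embeddings / pmax(norms, 1e-12))
  sims <- pmin(pmax(sims, -1), 1)
  diag(sims) <- -Inf
  edges <- purrr::map(seq_len(n), function(i) {
    nb <- order(-sims[i, ])[seq_len(min(k, n - 1))]
    tibble(from = i, to = nb, similarity = sims[i, nb])
  })
  structure(list(edges = dplyr::bind_rows(edges), k = k, n = n,
                 embeddings = embeddings),
            class = "embedding_graph")
}

#' @export
print.embedding_graph <- function(x, ...) {
  cat(sprintf("<embedding_graph: %d nodes, %d directed edges (k=%d)>\n",
              x$n, nrow(x$edges), x$k))
  invisible(x)
}

# Undirected adjacency list with edge similarities.
graph_adjacency <- function(graph) {
  und <- dplyr::bind_rows(
    graph$edges,
    tibble(from = graph$edges$to, to = graph$edges$from,
           similarity = graph$edges$similarity))
  und <- dplyr::distinct(und, .data$from, .data$to, .keep_all = TRUE)
  split(und[c("to", "similarity")], factor(und$from, levels = seq_len(graph$n)))
}

#' Collapse high-similarity neighborhoods into clusters
#'
#' Iterates nodes in descending out-degree order (ties broken by node id; in
#' a pure k-NN graph all out-degrees equal k, so iteration is by node id) and
#' runs a breadth-first search from each still-unassigned node. Expansion
#' over an edge stops when either the edge similarity or the similarity
#' between the start node and the candidate node falls below the threshold.
#' All nodes reached collapse to the start node, which represents the
#' cluster.
#'
#' @param graph an [build_knn_graph()] result.
#' @param threshold similarity cutoff (0.9 in the reference atlas).
#' @return tibble `node`, `representative`; representatives map to
#'   themselves.
#' @export
collapse_neighborhoods <- function(graph, threshold = 0.9) {
  adj <- graph_adjacency(graph)
  emb <- graph$embeddings
  norms <- sqrt(rowSums(emb^2))
  start_sim <- function(s, v) {
    sum(emb[s, ] * emb[v, ]) / max(norms[s] * norms[v], 1e-12)
  }
  deg <- tabulate(graph$edges$from, nbins = graph$n)
  order_nodes <- order(-deg, seq_len(graph$n))
  rep_of <- rep(NA_integer_, graph$n)
  for (s in order_nodes) {
    if (!is.na(rep_of[s])) next
    rep_of[s] <- s
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- adj[[v]]
      if (!nrow(nb)) next
      for (r in seq_len(nrow(nb))) {
        w <- nb$to[r]
        if (!is.na(rep_of[w])) next
        if (nb$similarity[r] < threshold) next
        if (start_sim(s, w) < threshold) next
        rep_of[w] <- s
        queue <- c(queue, w)
      }
    }
  }
  tibble(node = seq_len(graph$n), representative = rep_of)
}

#' Rebuild the graph on cluster representatives
#'
#' Second stage of the atlas pipeline: after collapsing, the k-NN graph is
#' rebuilt over the representatives' own embeddings (not centroids).
#'
#' @param graph the original graph.
#' @param assignment output of [collapse_neighborhoods()].
#' @param k neighbors per representative.
#' @return list with the new `graph` and the `representatives` node ids.
#' @export
rebuild_on_representatives <- function(graph, assignment, k = 3) {
  reps <- sort(unique(assignment$representative))
  stop_if_not(length(reps) >= k + 1, "too few representatives for k",
              class = "ms2embed_graph_error")
  sub <- build_knn_graph(graph$embeddings[reps, , drop = FALSE], k = k)
  list(graph = sub, representatives = reps)
}

#' Shortest-path statistics from query nodes to a spectral library
#'
#' Hop distance on the undirected view from each query node to its nearest
#' library node, and the best bottleneck similarity achievable along a
#' shortest path (the maximum over shortest paths of the minimum edge
#' similarity).
#'
#' @param graph an `embedding_graph`.
#' @param query,library disjoint node id vectors.
#' @return tibble `query`, `hops` (Inf when unreachable), `min_similarity`.
#' @export
library_path_stats <- function(graph, query, library) {
  stop_if_not(length(intersect(query, library)) == 0,
              "query and library nodes must be disjoint")
  adj <- graph_adjacency(graph)
  out <- purrr::map(query, function(q) {
    dist <- rep(Inf, graph$n)
    width <- rep(-Inf, graph$n)
    dist[q] <- 0
    width[q] <- Inf
    frontier <- q
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]]
        if (!nrow(nb)) next
        for (r in seq_len(nrow(nb))) {
          w <- nb$to[r]
          cand <- min(width[v], nb$similarity[r])
          if (is.infinite(dist[w]) && !(w %in% nxt)) {
            dist[w] <- dist[v] + 1
            width[w] <- cand
            nxt <- c(nxt, w)
          } else if (dist[w] == dist[v] + 1 && cand > width[w]) {
            width[w] <- cand
          }
        }
      }
      # second sweep so equal-depth predecessors all contribute their widths
      for (v in frontier) {
        nb <- adj[[v]]
        if (!nrow(nb)) next
        for (r in seq_len(nrow(nb))) {
          w <- nb$to[r]
          if (dist[w] == dist[v] + 1) {
            width[w] <- max(width[w], min(width[v], nb$similarity[r]))
          }
        }
      }
      frontier <- nxt
    }
    reach <- library[is.finite(dist[library])]
    if (!length(reach)) {
      tibble(query = q, hops = Inf, min_similarity = NA_real_)
    } else {
      h <- min(dist[reach])
      best <- max(width[reach[dist[reach] == h]])
      tibble(query = q, hops = h, min_similarity = best)
    }
  })
  dplyr::bind_rows(out)
}

#' Exclude spectra from blank samples by filename
#'
#' Case-insensitive substring filter on the source identifier, using the
#' standard blank-run markers.
#'
#' @param spectra a spectra tibble.
#' @param markers substrings identifying blank samples.
#' @return the filtered tibble.
#' @export
exclude_blank_samples <- function(spectra,
                                  markers = c("blank", "no_inj", "noinj",
                                              "empty", "solvent", "wash")) {
  pat <- paste(markers, collapse = "|")
  dplyr::filter(spectra, !grepl(pat, tolower(.data$source_id)))
}

#' Write an embedding graph to GraphML
#'
#' @param graph an `embedding_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = seq_len(graph$n)))
  igraph::E(g)$similarity <- graph$edges$similarity
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
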