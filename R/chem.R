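# Molecular graphs from SMILES, scaffolds, ring perception, fingerprints.
#
# SMILES parsing is delegated to OpenBabel (ChemmineR/ChemmineOB); everything
# downstream -- scaffold pruning, smallest-set-of-smallest-rings, the circular
# fingerprint and the property descriptors -- operates on a plain molecular
# graph (element-labelled vertices, order-labelled edges).

MONOISOTOPIC <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                  F = 18.998403, S = 31.972071, P = 30.973762,
                  Cl = 34.968853, Br = 78.918338, I = 126.904473)

STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, H = 1)

#' Parse SMILES strings into molecular graphs
#'
#' @param smiles character vector of SMILES.
#' @return list of molecule objects: each a list with `elements` (character),
#'   `bonds` (matrix from/to/order, possibly 0 rows) and the adjacency list.
#' @export
parse_smiles <- function(smiles) {
  stop_if_not(requireNamespace("ChemmineR", quietly = TRUE) &&
                requireNamespace("ChemmineOB", quietly = TRUE),
              "SMILES parsing requires ChemmineR + ChemmineOB")
  stop_if_not(all(nzchar(smiles)), "empty SMILES string",
              class = "ms2embed_parse_error")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, seq_along(smiles)))),
    error = function(e) abort(paste("SMILES parse failure:", conditionMessage(e)),
                              class = "ms2embed_parse_error"))
  lapply(seq_along(smiles), function(i) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    if (nrow(ab) == 0) {
      abort(sprintf("unparsable SMILES: %s", smiles[i]),
            class = "ms2embed_parse_error")
    }
    elements <- sub("_[0-9]+$", "", rownames(ab))
    bb <- ChemmineR::bondblock(mol)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
      matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
    } else {
      cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
            order = as.numeric(bb[, 3]))
    }
    new_molgraph(elements, bonds)
  })
}

new_molgraph <- function(elements, bonds) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]
      b <- bonds[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  structure(list(elements = elements, bonds = bonds, adj = adj, n = n),
            class = "molgraph")
}

mol_degree <- function(mol) lengths(mol$adj)

# Sum of bond orders per atom (used for implicit hydrogen counts).
mol_order_sum <- function(mol) {
  out <- numeric(mol$n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      out[mol$bonds[r, 1]] <- out[mol$bonds[r, 1]] + mol$bonds[r, 3]
      out[mol$bonds[r, 2]] <- out[mol$bonds[r, 2]] + mol$bonds[r, 3]
    }
  }
  out
}

mol_implicit_h <- function(mol) {
  val <- STD_VALENCE[mol$elements]
  val[is.na(val)] <- 4
  pmax(0, round(val - mol_order_sum(mol)))
}

# Induced subgraph on a vertex subset, preserving original labels.
mol_subgraph <- function(mol, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(mol$n), keep)
  b <- mol$bonds
  if (nrow(b)) {
    rows <- !is.na(idx[b[, 1]]) & !is.na(idx[b[, 2]])
    b <- b[rows, , drop = FALSE]
    b[, 1] <- idx[b[, 1]]
    b[, 2] <- idx[b[, 2]]
  }
  g <- new_molgraph(mol$elements[keep], b)
  g$orig <- keep
  g
}

#' Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal (degree <= 1) atoms until only ring systems and
#' the linkers connecting them remain. Acyclic molecules reduce to the empty
#' scaffold.
#'
#' @param mol a molecule from [parse_smiles()].
#' @return a molecule graph (possibly with 0 atoms) with `orig` giving the
#'   surviving atom indices of the input.
#' @export
murcko_scaffold <- function(mol) {
  keep <- seq_len(mol$n)
  g <- mol
  repeat {
    deg <- mol_degree(g)
    drop <- which(deg <= 1)
    if (!length(drop) || g$n == 0) break
    keep_local <- setdiff(seq_len(g$n), drop)
    keep <- if (is.null(g$orig)) keep_local else g$orig[keep_local]
    g <- mol_subgraph(mol, keep)
    if (g$n == 0) break
  }
  if (is.null(g$orig)) g$orig <- seq_len(g$n)
  g
}

# Smallest set of smallest rings: for every edge find a shortest cycle
# through it (BFS on the graph minus that edge), then greedily keep cycles,
# shortest first, that are independent over GF(2) in edge space, until the
# cyclomatic number is reached.
sssr_rings <- function(mol) {
  m <- nrow(mol$bonds)
  if (m == 0 || mol$n == 0) return(list())
  comp <- n_components(mol)
  target <- m - mol$n + comp
  if (target <= 0) return(list())
  cycles <- list()
  for (r in seq_len(m)) {
    a <- mol$bonds[r, 1]
    b <- mol$bonds[r, 2]
    path <- bfs_path(mol, a, b, skip_edge = r)
    if (!is.null(path)) {
      cyc_v <- path
      cycles[[length(cycles) + 1]] <- list(vertices = cyc_v, closing = r)
    }
  }
  if (!length(cycles)) return(list())
  # edge-incidence bit vector of each candidate cycle
  edge_key <- paste(pmin(mol$bonds[, 1], mol$bonds[, 2]),
                    pmax(mol$bonds[, 1], mol$bonds[, 2]))
  cyc_edges <- lapply(cycles, function(cy) {
    v <- cy$vertices
    pairs <- cbind(v, c(v[-1], v[1]))
    match(paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])),
          edge_key)
  })
  ord <- order(lengths(cyc_edges))
  basis <- list()
  rings <- list()
  for (ci in ord) {
    vec <- logical(m)
    vec[cyc_edges[[ci]]] <- TRUE
    red <- vec
    for (bv in basis) {
      pivot <- which(bv)[1]
      if (red[pivot]) red <- xor(red, bv)
    }
    if (any(red)) {
      basis[[length(basis) + 1]] <- red
      rings[[length(rings) + 1]] <- sort(cycles[[ci]]$vertices)
      if (length(rings) == target) break
    }
  }
  rings
}

# Shortest path a -> b avoiding one edge; returns the cycle vertex sequence.
bfs_path <- function(mol, a, b, skip_edge) {
  sa <- mol$bonds[skip_edge, 1]
  sb <- mol$bonds[skip_edge, 2]
  prev <- rep(NA_integer_, mol$n)
  seen <- logical(mol$n)
  seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    if (v == b) break
    for (w in mol$adj[[v]]) {
      if ((v == sa && w == sb) || (v == sb && w == sa)) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!seen[b]) return(NULL)
  path <- b
  while (path[1] != a) path <- c(prev[path[1]], path)
  path
}

n_components <- function(mol) {
  seen <- logical(mol$n)
  comp <- 0
  for (s in seq_len(mol$n)) {
    if (seen[s]) next
    comp <- comp + 1
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in mol$adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Circular (Morgan-style) binary fingerprint
#'
#' A radius-2, 4096-bit hashed circular fingerprint authored in this package:
#' initial atom invariants (element, degree, bond-order sum, implicit-H count,
#' ring membership) are iteratively refined over bond neighborhoods and every
#' environment identifier at radii 0..radius sets one bit. It plays the role
#' of a Morgan fingerprint for splitting, probing and retrieval experiments;
#' it is not bit-compatible with any external toolkit.
#'
#' @param smiles character vector of SMILES (or a list of parsed molecules).
#' @param nbits fingerprint length.
#' @param radius neighborhood radius.
#' @return a list of 0/1 integer vectors, one per molecule.
#' @export
morgan_fingerprint <- function(smiles, nbits = 4096, radius = 2) {
  mols <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  lapply(mols, function(mol) {
    fp <- integer(nbits)
    if (mol$n == 0) return(fp)
    ring_atoms <- unique(unlist(sssr_rings(mol)))
    in_ring <- seq_len(mol$n) %in% ring_atoms
    deg <- mol_degree(mol)
    hs <- mol_implicit_h(mol)
    osum <- mol_order_sum(mol)
    ids <- string_hash(paste(mol$elements, deg, osum, hs, in_ring))
    all_ids <- ids
    if (radius >= 1) {
      for (r in seq_len(radius)) {
        new_ids <- vapply(seq_len(mol$n), function(a) {
          nb <- mol$adj[[a]]
          if (!length(nb)) return(string_hash(paste(r, ids[a])))
          ords <- vapply(nb, function(w) bond_order_between(mol, a, w), numeric(1))
          key <- paste(sort(paste0(ords, ":", ids[nb])), collapse = "|")
          string_hash(paste(r, ids[a], key))
        }, numeric(1))
        ids <- new_ids
        all_ids <- c(all_ids, ids)
      }
    }
    fp[unique(all_ids %% nbits) + 1] <- 1L
    fp
  })
}

bond_order_between <- function(mol, a, b) {
  rows <- (mol$bonds[, 1] == a & mol$bonds[, 2] == b) |
    (mol$bonds[, 1] == b & mol$bonds[, 2] == a)
  mol$bonds[which(rows)[1], 3]
}

#' Tanimoto similarity of binary fingerprints
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return intersection over union; 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Graph-based molecular property descriptors
#'
#' Computes the 11 molecular properties the fine-tuning property head predicts.
#' The descriptor set is this package's own, chosen to be computable from the
#' molecular graph alone: monoisotopic weight, heavy-atom count, ring count,
#' rotatable bonds, H-bond donors and acceptors, halogen count,
#' heteroatom fraction, sp3 carbon fraction, a normalized branching index and
#' a size-complexity score.
#'
#' @param smiles character vector of SMILES (or parsed molecules).
#' @return tibble with one row per molecule and 11 numeric columns.
#' @export
molecular_properties <- function(smiles) {
  mols <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  rows <- lapply(mols, function(mol) {
    deg <- mol_degree(mol)
    hs <- mol_implicit_h(mol)
    rings <- sssr_rings(mol)
    ring_atoms <- unique(unlist(rings))
    in_ring_edge <- edge_in_ring(mol, rings)
    heavy <- mol$n
    elements <- mol$elements
    mw <- sum(MONOISOTOPIC[elements], na.rm = TRUE) +
      sum(hs) * MONOISOTOPIC[["H"]]
    rot <- 0
    if (nrow(mol$bonds)) {
      for (r in seq_len(nrow(mol$bonds))) {
        a <- mol$bonds[r, 1]
        b <- mol$bonds[r, 2]
        if (mol$bonds[r, 3] == 1 && !in_ring_edge[r] &&
            deg[a] >= 2 && deg[b] >= 2) {
          rot <- rot + 1
        }
      }
    }
    is_c <- elements == "C"
    sp3 <- if (!any(is_c)) 0 else {
      mean(vapply(which(is_c), function(a) {
        nb <- mol$adj[[a]]
        !length(nb) ||
          all(vapply(nb, function(w) bond_order_between(mol, a, w), numeric(1)) == 1)
      }, logical(1)))
    }
    n_edges <- nrow(mol$bonds)
    tibble(
      mol_weight = mw,
      heavy_atoms = heavy,
      n_rings = length(rings),
      rotatable_bonds = rot,
      hbd = sum(elements %in% c("N", "O") & hs > 0),
      hba = sum(elements %in% c("N", "O")),
      halogens = sum(elements %in% c("F", "Cl", "Br", "I")),
      hetero_fraction = mean(!is_c),
      sp3_fraction = sp3,
      branch_index = if (n_edges == 0) 0 else sum(deg^2) / (2 * n_edges),
      complexity = (n_edges + 1) * log2(heavy + 1)
    )
  })
  dplyr::bind_rows(rows)
}

edge_in_ring <- function(mol, rings) {
  m <- nrow(mol$bonds)
  out <- logical(m)
  if (!m || !length(rings)) return(out)
  for (ring in rings) {
    for (r in seq_len(m)) {
      if (mol$bonds[r, 1] %in% ring && mol$bonds[r, 2] %in% ring) {
        out[r] <- TRUE
      }
    }
  }
  out
}

#' Does a molecule contain fluorine?
#'
#' @param smiles character vector of SMILES (or parsed molecules).
#' @return integer 0/1 vector.
#' @export
contains_fluorine <- function(smiles) {
  mols <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  vapply(mols, function(mol) as.integer("F" %in% mol$elements), integer(1))
}

#' Monoisotopic molecular mass (neutral molecule, implicit hydrogens included)
#'
#' @param smiles character vector of SMILES (or parsed molecules).
#' @return numeric vector of masses in Da.
#' @export
molecular_mass <- function(smiles) {
  mols <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  vapply(mols, function(mol) {
    sum(MONOISOTOPIC[mol$elements], na.rm = TRUE) +
      sum(mol_implicit_h(mol)) * MONOISOTOPIC[["H"]]
  }, numeric(1))
}
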