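# Evaluation metrics and classical spectral similarity.

#' Modified cosine similarity between two spectra
#'
#' Greedy one-to-one peak matching where two peaks match either directly
#' (|m1 - m2| <= tol) or after shifting by the precursor mass difference
#' (accounting for a shared neutral loss); the score is the normalized dot
#' product of square-root intensities over matched pairs.
#'
#' @param mz1,int1,pre1 peaks and precursor m/z of the first spectrum.
#' @param mz2,int2,pre2 peaks and precursor m/z of the second spectrum.
#' @param mz_tol matching tolerance in Da.
#' @return similarity in `[0, 1]`.
#' @export
modified_cosine <- function(mz1, int1, pre1, mz2, int2, pre2, mz_tol = 0.1) {
  if (!length(mz1) || !length(mz2)) return(0)
  w1 <- sqrt(int1)
  w2 <- sqrt(int2)
  shift <- pre1 - pre2
  d_direct <- abs(outer(mz1, mz2, "-"))
  d_shift <- abs(outer(mz1, mz2, "-") - shift)
  ok <- d_direct <= mz_tol | d_shift <= mz_tol
  if (!any(ok)) return(0)
  prod <- outer(w1, w2)
  cand <- which(ok, arr.ind = TRUE)
  cand <- cand[order(-prod[cand]), , drop = FALSE]
  used1 <- logical(length(mz1))
  used2 <- logical(length(mz2))
  score <- 0
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]
    j <- cand[r, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE
      used2[j] <- TRUE
      score <- score + prod[i, j]
    }
  }
  score / (sqrt(sum(w1^2)) * sqrt(sum(w2^2)))
}

#' Pearson correlation between embedding similarities and molecular similarities
#'
#' @param scores numeric vector (e.g. embedding cosine similarities per pair).
#' @param reference numeric vector of the same length (e.g. fingerprint
#'   Tanimoto similarities).
#' @return Pearson correlation coefficient.
#' @export
evaluate_similarity <- function(scores, reference) {
  stop_if_not(length(scores) == length(reference), "length mismatch")
  stop_if_not(sd(scores) > 0 && sd(reference) > 0,
              "correlation undefined for constant scores",
              class = "ms2embed_metric_error")
  cor(scores, reference)
}

#' Area under the ROC curve of a binary ranking
#'
#' Rank-based (Mann-Whitney) AUROC with midrank handling of ties.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels 0/1 (or logical) labels.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_binary_ranking <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  stop_if_not(n_pos > 0 && n_neg > 0, "need both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Retrieval accuracy at k over candidate pools
#'
#' Each pool pairs one predicted fingerprint with candidate fingerprints, at
#' least one of which is a positive. Candidates are ranked by cosine
#' similarity to the prediction; a pool counts at k when a positive appears in
#' the top k.
#'
#' @param pools list of pools; each a list with `predicted` (numeric vector),
#'   `candidates` (matrix, one candidate per row) and `positive` (logical per
#'   candidate).
#' @param k integer vector of cutoffs.
#' @return tibble with `k` and `accuracy`.
#' @export
evaluate_retrieval <- function(pools, k = c(1, 5, 10, 20, 50, 100, 200)) {
  best_rank <- purrr::map_dbl(pools, function(p) {
    stop_if_not(any(p$positive), "pool without a positive candidate")
    sims <- apply(p$candidates, 1, function(cand) cosine_sim(p$predicted, cand))
    ord <- order(-sims)
    min(which(p$positive[ord]))
  })
  tibble(k = k,
         accuracy = vapply(k, function(kk) mean(best_rank <= kk), numeric(1)))
}

# Cosine similarity with the numerical-stability floor on the norm product.
cosine_sim <- function(a, b, eps = 1e-8) {
  sum(a * b) / max(sqrt(sum(a^2)) * sqrt(sum(b^2)), eps)
}
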