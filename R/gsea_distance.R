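#' Extract the up/down signature of a PRL
#'
#' The signature of a rank list is its `n` most upregulated probes
#' (ranks `1..n`) and its `n` most downregulated probes
#' (ranks `N-n+1..N`). The default `n = 250` is the conventional empirical
#' choice; the final ranking is insensitive to moderate changes of `n`.
#'
#' @param prl A PRL (character vector in rank order).
#' @param n Signature size; requires `2 * n <= length(prl)`.
#' @param source_label Optional condition label carried on the signature.
#' @return An object of class `prl_signature`: a list with `up`, `down`,
#'   `n` and `source_label`.
#' @export
extract_signature <- function(prl, n = 250L, source_label = NULL) {
  validate_prl(prl)
  n <- as.integer(n)
  N <- length(prl)
  if (n < 1L || 2L * n > N) {
    stop("signature size must satisfy 1 <= n and 2n <= N (N = ", N, ")",
         call. = FALSE)
  }
  structure(list(up = prl[seq_len(n)],
                 down = prl[seq.int(N - n + 1L, N)],
                 n = n, source_label = source_label),
            class = "prl_signature")
}

#' Equal-weighted GSEA enrichment score
#'
#' Walks the reference PRL from rank 1 to rank `N` keeping a running sum
#' that rises by `1/n` at each hit (probe in the gene set) and falls by
#' `1/(N-n)` at each miss. The enrichment score is the signed value of the
#' running sum at its maximum absolute deviation from zero; when the
#' largest positive and negative excursions tie in magnitude the positive
#' one is returned. The sum returns to zero at rank `N` by construction,
#' and the score always lies in `[-1, 1]`: +1 when the set occupies the
#' very top of the reference, -1 when it occupies the very bottom.
#'
#' @param gene_set Character vector of `n` distinct probes, all present in
#'   the reference universe, with `0 < n < N`.
#' @param reference A PRL.
#' @return The enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(gene_set, reference) {
  validate_prl(reference)
  n <- length(gene_set)
  N <- length(reference)
  if (anyDuplicated(gene_set)) {
    stop("gene set must not contain duplicates", call. = FALSE)
  }
  if (n == 0L || n >= N) {
    stop("gene set size must satisfy 0 < n < N", call. = FALSE)
  }
  hit <- reference %in% gene_set
  if (sum(hit) != n) {
    stop("gene set contains probe(s) absent from the reference universe: ",
         paste(setdiff(gene_set, reference), collapse = ", "),
         call. = FALSE)
  }
  # Running sum over the common denominator n*(N-n): hits add (N-n), misses
  # subtract n, so every partial sum is an exactly-represented integer and
  # the extreme-deviation comparison (and its tie) is exact.
  numer <- cumsum(ifelse(hit, N - n, -n))
  smax <- max(numer)
  smin <- min(numer)
  extreme <- if (smax >= -smin) smax else smin
  extreme / (n * (N - n))
}

#' Combine per-direction enrichment scores into a two-sided score
#'
#' A signature enriched the "right way round" has its up-set near the top
#' of the reference (positive score) and its down-set near the bottom
#' (negative score), so the two-sided score is `(es_up - es_down) / 2`,
#' again in `[-1, 1]`. No same-sign zeroing is applied.
#'
#' @param es_up,es_down Per-direction enrichment scores in `[-1, 1]`.
#' @return The combined score.
#' @export
combine_enrichment_scores <- function(es_up, es_down) {
  (es_up - es_down) / 2
}

#' Score a signature against a reference PRL in both directions
#'
#' @param signature A `prl_signature` (see [extract_signature()]).
#' @param reference A PRL over the same probe universe.
#' @return A list with `es_up`, `es_down` and `combined`
#'   (`(es_up - es_down)/2`), all in `[-1, 1]`.
#' @export
combined_es <- function(signature, reference) {
  if (!inherits(signature, "prl_signature")) {
    stop("signature must come from extract_signature()", call. = FALSE)
  }
  es_up <- enrichment_score(signature$up, reference)
  es_down <- enrichment_score(signature$down, reference)
  list(es_up = es_up, es_down = es_down,
       combined = combine_enrichment_scores(es_up, es_down))
}

#' Bidirectional GSEA distance from the two combined enrichment scores
#'
#' @param es_ab Combined score of A's signature in reference PRL B.
#' @param es_ba Combined score of B's signature in reference PRL A.
#' @return `1 - (es_ab + es_ba) / 2`, in `[0, 2]`: 0 for identically
#'   regulated profiles, 2 for perfectly opposed ones.
#' @export
gsea_distance_from_es <- function(es_ab, es_ba) {
  1 - (es_ab + es_ba) / 2
}

#' Bidirectional GSEA distance between two PRLs
#'
#' Each list's top/bottom-`n` signature is scored against the other list
#' by equal-weighted GSEA and the two combined scores are folded into
#' `1 - (ES_AB + ES_BA) / 2`. Small distances mean the two profiles push
#' the same probes in the same directions.
#'
#' @param a,b PRLs over identical universes.
#' @param n Signature size (default 250).
#' @return Distance in `[0, 2]`; symmetric in `a` and `b`.
#' @export
prl_distance <- function(a, b, n = 250L) {
  check_same_universe(a, b)
  es_ab <- combined_es(extract_signature(a, n), b)$combined
  es_ba <- combined_es(extract_signature(b, n), a)$combined
  gsea_distance_from_es(es_ab, es_ba)
}

#' Pairwise GSEA distance matrix over labelled PRLs
#'
#' @param prls Named list (>= 2, unique labels) of PRLs over one universe.
#' @param n Signature size.
#' @return A symmetric matrix of distances in `[0, 2]` with zero diagonal,
#'   labelled by condition.
#' @export
distance_matrix <- function(prls, n = 250L) {
  if (!is.list(prls) || length(prls) < 2L) {
    stop("distance_matrix needs >= 2 labelled PRLs", call. = FALSE)
  }
  labels <- names(prls)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("PRLs must carry unique non-empty labels", call. = FALSE)
  }
  k <- length(prls)
  sigs <- lapply(prls, extract_signature, n = n)
  dm <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      es_ij <- combined_es(sigs[[i]], prls[[j]])$combined
      es_ji <- combined_es(sigs[[j]], prls[[i]])$combined
      dm[i, j] <- dm[j, i] <- gsea_distance_from_es(es_ij, es_ji)
    }
  }
  dm
}
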