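#' Rank perturbations by distance to a query condition
#'
#' Extracts the query row of the distance matrix and sorts all other
#' conditions by ascending distance (ties by label ascending), so the
#' perturbations whose transcriptional footprint most resembles the query
#' disease come first.
#'
#' @param dm Distance matrix (see [validate_distance_matrix()]).
#' @param query_label One of the matrix labels.
#' @param top Optional: keep only the first `top` rows.
#' @return A data frame with columns `condition` and `distance`, sorted
#'   non-decreasing by distance; the query itself is excluded.
#' @export
rank_perturbations <- function(dm, query_label, top = NULL) {
  validate_distance_matrix(dm)
  if (!query_label %in% rownames(dm)) {
    stop("unknown query label: ", query_label, call. = FALSE)
  }
  others <- setdiff(rownames(dm), query_label)
  tab <- data.frame(condition = others,
                    distance = dm[query_label, others],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$distance, tab$condition, method = "radix"), ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(top)) tab <- utils::head(tab, top)
  tab
}

#' Average-linkage clustering of a distance matrix
#'
#' Treats the matrix as a precomputed dissimilarity and runs agglomerative
#' clustering with average (UPGMA) linkage, the conventional default for
#' similarity heat maps. Returns the linkage table and the dendrogram's
#' left-to-right leaf order.
#'
#' @param dm Symmetric distance matrix with >= 2 labels.
#' @return A list with:
#'   \describe{
#'     \item{linkage}{data frame `member_a`, `member_b`, `height`, `size`;
#'       members are condition labels for singletons and `"node<k>"` for
#'       the cluster formed at step `k`.}
#'     \item{leaf_order}{condition labels in dendrogram order.}
#'     \item{hclust}{the underlying [stats::hclust] object.}
#'   }
#' @export
cluster_distance_matrix <- function(dm) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 2L) {
    stop("clustering needs at least 2 conditions", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  member_name <- function(m) {
    if (m < 0) rownames(dm)[-m] else sprintf("node%d", m)
  }
  sizes <- integer(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    sz <- function(m) if (m < 0) 1L else sizes[m]
    sizes[k] <- sz(hc$merge[k, 1L]) + sz(hc$merge[k, 2L])
  }
  linkage <- data.frame(
    member_a = vapply(hc$merge[, 1L], member_name, character(1L)),
    member_b = vapply(hc$merge[, 2L], member_name, character(1L)),
    height = hc$height,
    size = sizes,
    stringsAsFactors = FALSE)
  list(linkage = linkage, leaf_order = hc$labels[hc$order], hclust = hc)
}
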