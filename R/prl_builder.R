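#' Lower-quartile threshold pair for one sample pair
#'
#' The primary threshold is the 25th percentile of the pooled experiment and
#' control intensities (linear interpolation between order statistics, the
#' `type = 7` convention); the secondary threshold is one tenth of it.
#' Clamping at the primary threshold suppresses the unstable fold changes
#' produced by dividing by near-background intensities; the looser secondary
#' threshold is used only to break the ties the first clamp creates.
#'
#' @param experiment_values,control_values Positive numeric vectors of equal
#'   length, pooling to at least 4 values.
#' @return A list with elements `primary` and `secondary` (= `primary / 10`).
#' @export
primary_threshold <- function(experiment_values, control_values) {
  check_pair_values(experiment_values, control_values, min_len = 2L)
  pooled <- c(experiment_values, control_values)
  primary <- as.numeric(stats::quantile(pooled, probs = 0.25, type = 7,
                                        names = FALSE))
  list(primary = primary, secondary = primary / 10)
}

check_pair_values <- function(experiment, control, min_len = 4L) {
  if (length(experiment) != length(control)) {
    stop("experiment and control vectors must have equal length",
         call. = FALSE)
  }
  if (length(experiment) < min_len) {
    stop("need at least 4 probes to form a rank list", call. = FALSE)
  }
  if (any(!is.finite(experiment) | experiment <= 0) ||
      any(!is.finite(control) | control <= 0)) {
    stop("expression values must be strictly positive and finite",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Build a probe rank list from one experiment/control pair
#'
#' Implements the hierarchical threshold-and-sort procedure:
#' \enumerate{
#'   \item Compute the primary threshold (pooled lower quartile) and the
#'     secondary threshold (one tenth of it).
#'   \item Clamp both samples at the primary threshold and rank probes by
#'     descending experiment-to-control ratio of the clamped values.
#'   \item Probes whose clamped ratio equals one (the tie block the clamp
#'     creates, plus genuinely unchanged probes) are re-scored: their
#'     original values are clamped at the secondary threshold instead and
#'     the block is sub-sorted by the new ratios, in place.
#'   \item Residual ties are broken by probe id ascending, so the result is
#'     a deterministic strict permutation.
#' }
#' Rank 1 is the most upregulated probe, rank `N` the most downregulated.
#'
#' @param experiment,control Positive numeric vectors, aligned with
#'   `probe_ids`.
#' @param probe_ids Character vector of unique probe identifiers.
#' @param ratio_tol Relative tolerance for "ratio equals one" (clamping
#'   produces exact ties; the tolerance only guards representation noise).
#' @return Character vector of probe ids in rank order (a PRL).
#' @export
build_prl <- function(experiment, control, probe_ids, ratio_tol = 1e-12) {
  check_pair_values(experiment, control)
  if (length(probe_ids) != length(experiment)) {
    stop("probe_ids must align with the expression vectors", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("probe ids must be unique", call. = FALSE)
  }
  th <- primary_threshold(experiment, control)

  ratio <- pmax(experiment, th$primary) / pmax(control, th$primary)
  tied <- abs(ratio - 1) <= ratio_tol
  ratio[tied] <- 1

  # Sub-key for the tie block: ratios of the ORIGINAL values re-clamped at
  # the secondary threshold. Re-clamping the already-clamped values could
  # never move a ratio off 1.
  subratio <- numeric(length(ratio))
  subratio[tied] <- pmax(experiment[tied], th$secondary) /
    pmax(control[tied], th$secondary)

  ord <- order(-ratio, -subratio, probe_ids, method = "radix")
  probe_ids[ord]
}

#' Build one PRL per manifest entry
#'
#' @param expr Expression matrix containing every sample the manifest names.
#' @param manifest Pairing manifest (see [read_pair_manifest()]).
#' @return A named list of PRLs, one per manifest row, named
#'   `<condition>__<dataset>__<experiment_id>`.
#' @export
build_prls <- function(expr, manifest) {
  validate_expression_matrix(expr)
  validate_pair_manifest(manifest, expr)
  probes <- rownames(expr)
  prls <- lapply(seq_len(nrow(manifest)), function(i) {
    build_prl(expr[, manifest$experiment_id[i]],
              expr[, manifest$control_id[i]], probes)
  })
  names(prls) <- sprintf("%s__%s__%s", manifest$condition, manifest$dataset,
                         manifest$experiment_id)
  prls
}
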