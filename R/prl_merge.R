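#' Spearman footrule distance between two rank lists
#'
#' Sum over probes of the absolute difference of their ranks. It is the
#' agglomeration criterion of the hierarchical merge: at every step the two
#' most concordant lists are combined first, so replicate noise is averaged
#' out before discordant replicates are folded in.
#'
#' @param a,b PRLs (character vectors) over identical probe universes.
#' @return Non-negative number; 0 iff the permutations are identical.
#' @export
footrule_distance <- function(a, b) {
  check_same_universe(a, b)
  rank_b <- match(a, b)
  as.numeric(sum(abs(seq_along(a) - rank_b)))
}

check_same_universe <- function(a, b) {
  validate_prl(a)
  validate_prl(b)
  if (length(a) != length(b) || !setequal(a, b)) {
    stop("rank lists are not over the same probe universe", call. = FALSE)
  }
  invisible(NULL)
}

#' Borda (mean-rank) merge of two rank lists
#'
#' Each probe is scored with the mean of its ranks in the two lists and the
#' merged list is the probes sorted by ascending score, ties broken by
#' probe id ascending. The operation is commutative and idempotent.
#'
#' @param a,b PRLs over identical probe universes.
#' @return The merged PRL.
#' @export
borda_merge <- function(a, b) {
  check_same_universe(a, b)
  score <- (seq_along(a) + match(a, b)) / 2
  a[order(score, a, method = "radix")]
}

#' Merge replicate PRLs by hierarchical majority voting
#'
#' Repeatedly merges the closest pair of lists (Spearman footrule) with a
#' Borda merge until a single consensus list remains. Merged lists carry no
#' extra weight in later steps; ties between equally close pairs are broken
#' towards the pair whose sorted member ids come first lexicographically,
#' so the procedure is deterministic.
#'
#' @param prls Non-empty list of PRLs over identical universes. Names, if
#'   present, identify members in the trace; otherwise positions are used.
#' @return A list with elements `prl` (the consensus PRL) and `trace`, a
#'   data frame with one row per merge: `left_members`, `right_members`
#'   (comma-joined input ids) and `footrule` (the distance at the merge).
#' @export
merge_condition_prls <- function(prls) {
  if (!is.list(prls) || length(prls) == 0L) {
    stop("merge_condition_prls needs a non-empty list of PRLs",
         call. = FALSE)
  }
  ids <- names(prls)
  if (is.null(ids)) ids <- as.character(seq_along(prls))
  empty_trace <- data.frame(left_members = character(0L),
                            right_members = character(0L),
                            footrule = numeric(0L),
                            stringsAsFactors = FALSE)
  if (length(prls) == 1L) {
    validate_prl(prls[[1L]])
    return(list(prl = prls[[1L]], trace = empty_trace))
  }

  members <- lapply(ids, function(id) id)
  active <- prls
  trace <- empty_trace
  while (length(active) > 1L) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        d <- footrule_distance(active[[i]], active[[j]])
        key <- paste(sort_c(c(members[[i]], members[[j]])), collapse = ",")
        if (is.null(best) || d < best$d ||
            (d == best$d && key < best$key)) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    merged <- borda_merge(active[[best$i]], active[[best$j]])
    trace <- rbind(trace, data.frame(
      left_members = paste(sort_c(members[[best$i]]), collapse = ","),
      right_members = paste(sort_c(members[[best$j]]), collapse = ","),
      footrule = best$d, stringsAsFactors = FALSE))
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    active[[best$i]] <- merged
    members[[best$j]] <- NULL
    active[[best$j]] <- NULL
  }
  list(prl = active[[1L]], trace = trace)
}

#' Merge every condition's replicate PRLs
#'
#' Groups a named list of per-pair PRLs (named `<condition>__<dataset>__<id>`
#' as produced by [build_prls()]) by condition label and merges each group.
#'
#' @param prls Named list of PRLs.
#' @param conditions Optional character vector of condition labels aligned
#'   with `prls`; by default the prefix of each name before the first `"__"`.
#' @return Named list (one element per condition) of
#'   `list(prl = , trace = )` results.
#' @export
merge_by_condition <- function(prls, conditions = NULL) {
  if (is.null(conditions)) {
    if (is.null(names(prls))) {
      stop("prls must be named '<condition>__...' or conditions supplied",
           call. = FALSE)
    }
    conditions <- sub("__.*$", "", names(prls))
  }
  groups <- split(prls, factor(conditions, levels = unique(conditions)))
  lapply(groups, merge_condition_prls)
}
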