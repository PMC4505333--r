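#' Read a probe-level expression matrix
#'
#' Reads a probe x sample intensity table from delimited text. Two dialects
#' are understood: plain TSV (header row `probe_id<TAB>sample1<TAB>...`,
#' first column = probe identifiers) and GCT v1.2 (two header lines,
#' `Name`/`Description` columns; the `Description` column is dropped).
#' Values must be strictly positive, finite, linear-scale intensities:
#' the downstream rank-list construction computes experiment-to-control
#' ratios and lower-quartile thresholds, which are only meaningful on
#' positive linear values. Log-scale data must be exponentiated upstream.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @return A numeric matrix with probe ids as row names and sample ids as
#'   column names, in file order.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path, call. = FALSE)
  }
  skip <- 0L
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !startsWith(head2[[1L]], "#1.2")) {
      stop("not a GCT v1.2 file (missing '#1.2' version line): ", path,
           call. = FALSE)
    }
    skip <- 2L
  }
  tab <- utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(tab) < 2L) {
    stop("expression matrix needs a probe id column plus >= 1 sample column",
         call. = FALSE)
  }
  probe_ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  if (dialect == "gct") {
    # GCT column 2 is the free-text Description field
    tab <- tab[, -1L, drop = FALSE]
  }
  sample_ids <- colnames(tab)
  values <- as.matrix(tab)
  if (!is.numeric(values)) {
    bad <- which(!vapply(seq_len(ncol(values)), function(j) {
      suppressWarnings(!anyNA(as.numeric(values[, j])))
    }, logical(1L)))
    stop("non-numeric expression values in sample(s): ",
         paste(sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants every pipeline stage assumes: unique probe and
#' sample ids, and strictly positive finite values. Errors name the first
#' offending cell.
#'
#' @param x Numeric matrix with probe row names and sample column names.
#' @return `x`, invisibly.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry probe row names and sample column names",
         call. = FALSE)
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) {
    stop("duplicate probe id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[[1L]], dim(x))
    stop("expression values must be strictly positive and finite; ",
         "offending value ", x[bad[[1L]]], " at probe '", rownames(x)[i[1L]],
         "', sample '", colnames(x)[i[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' @param x Expression matrix (see [validate_expression_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  tab <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict matrices to their shared probe universe
#'
#' Probes absent from any one dataset are dropped from all of them; the
#' survivors are the intersection of the probe sets, sorted by probe id.
#' All downstream stages (rank lists, merging, enrichment) assume a single
#' shared probe universe, so harmonization runs once, up front.
#'
#' @param matrices A list of expression matrices.
#' @return A list of matrices, each restricted to the common probes and
#'   with rows sorted by probe id (C-locale order).
#' @export
harmonize_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("harmonize_probes needs a non-empty list of matrices", call. = FALSE)
  }
  lapply(matrices, validate_expression_matrix)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) {
    stop("no probe is shared by all datasets (empty probe intersection)",
         call. = FALSE)
  }
  common <- sort_c(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Read a sample-pairing manifest
#'
#' The manifest is a TSV with header
#' `experiment_id  control_id  condition  dataset`; each row pairs one
#' experiment sample with its control and tags the pair with a condition
#' label (disease or perturbation identity) and a dataset of origin.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame with those four character columns.
#' @export
read_pair_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("experiment_id", "control_id", "condition", "dataset")
  missing <- setdiff(required, colnames(tab))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, required, drop = FALSE]
  validate_pair_manifest(tab)
  tab
}

#' Validate a pairing manifest, optionally against an expression matrix
#'
#' @param manifest Data frame with columns `experiment_id`, `control_id`,
#'   `condition`, `dataset`.
#' @param expr Optional expression matrix; if given, every sample id in the
#'   manifest must be one of its columns.
#' @return `manifest`, invisibly.
#' @export
validate_pair_manifest <- function(manifest, expr = NULL) {
  required <- c("experiment_id", "control_id", "condition", "dataset")
  if (!is.data.frame(manifest) || !all(required %in% colnames(manifest))) {
    stop("manifest must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  same <- manifest$experiment_id == manifest$control_id
  if (any(same)) {
    stop("manifest pairs a sample with itself: ",
         paste(unique(manifest$experiment_id[same]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(expr)) {
    ids <- unique(c(manifest$experiment_id, manifest$control_id))
    dangling <- setdiff(ids, colnames(expr))
    if (length(dangling)) {
      stop("manifest sample id(s) absent from the expression matrix: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Write a pairing manifest as TSV
#'
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_manifest <- function(manifest, path) {
  validate_pair_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write probe rank lists
#'
#' A probe rank list (PRL) is a strict permutation of the probe universe,
#' rank 1 = most upregulated. On disk it is a two-column TSV
#' `rank<TAB>probe_id` with contiguous ranks `1..N`.
#'
#' @param prl Character vector of probe ids in rank order.
#' @param path File path.
#' @return `read_prl` returns the character vector of probe ids in rank
#'   order; `write_prl` returns `path` invisibly.
#' @export
write_prl <- function(prl, path) {
  validate_prl(prl)
  tab <- data.frame(rank = seq_along(prl), probe_id = prl,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prl
#' @export
read_prl <- function(path) {
  if (!file.exists(path)) stop("PRL file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "character"))
  if (!all(c("rank", "probe_id") %in% colnames(tab))) {
    stop("PRL file must have columns rank, probe_id: ", path, call. = FALSE)
  }
  if (!identical(tab$rank, seq_len(nrow(tab)))) {
    stop("PRL ranks must be contiguous 1..N in order: ", path, call. = FALSE)
  }
  prl <- tab$probe_id
  validate_prl(prl)
  prl
}

#' Validate a probe rank list
#'
#' @param prl Character vector of probe ids.
#' @param universe Optional probe universe the PRL must be a permutation of.
#' @return `prl`, invisibly.
#' @export
validate_prl <- function(prl, universe = NULL) {
  if (!is.character(prl) || length(prl) == 0L) {
    stop("a PRL is a non-empty character vector of probe ids", call. = FALSE)
  }
  if (anyDuplicated(prl)) {
    stop("PRL is not a permutation: duplicated probe id(s): ",
         paste(unique(prl[duplicated(prl)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(universe) && !setequal(prl, universe)) {
    stop("PRL is not a permutation of the given probe universe",
         call. = FALSE)
  }
  invisible(prl)
}

#' Read and write GSEA distance matrices
#'
#' A distance matrix is a symmetric condition x condition matrix of
#' bidirectional GSEA distances in `[0, 2]` with zero diagonal. On disk it
#' is a square TSV whose first column holds the row labels, identical to
#' the column labels. Distances survive a round trip to at least 12
#' significant digits.
#'
#' @param dm Symmetric numeric matrix with identical row/column labels.
#' @param path File path.
#' @return `read_distance_matrix` returns the matrix; `write_distance_matrix`
#'   returns `path` invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  lines <- c(
    paste(c("condition", colnames(dm)), collapse = "\t"),
    vapply(seq_len(nrow(dm)), function(i) {
      paste(c(rownames(dm)[i], sprintf("%.15g", dm[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("distance matrix file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  dm <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(dm) <- labels
  validate_distance_matrix(dm)
  dm
}

#' Validate a distance matrix
#'
#' @param dm Numeric matrix.
#' @param tol Absolute symmetry tolerance (distances are stored to 15
#'   significant digits, so round-tripped matrices stay well inside it).
#' @return `dm`, invisibly.
#' @export
validate_distance_matrix <- function(dm, tol = 1e-9) {
  if (!is.matrix(dm) || !is.numeric(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm))) {
    stop("distance matrix row and column labels must be identical",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(dm))) {
    stop("duplicate condition label(s) in distance matrix", call. = FALSE)
  }
  if (max(abs(dm - t(dm))) > tol) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(dm)) > tol)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (any(dm < -tol | dm > 2 + tol)) {
    stop("distance values must lie in [0, 2]", call. = FALSE)
  }
  invisible(dm)
}

# C-locale (radix) sort: locale-independent deterministic ordering,
# used for every probe-id tie-break in the package.
sort_c <- function(x) x[order(x, method = "radix")]
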