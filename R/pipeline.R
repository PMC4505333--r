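#' Run the signature-matching pipeline end to end
#'
#' Executes every stage in order — simulate (or ingest) the study, build one
#' PRL per experiment/control pair, merge replicate PRLs per condition,
#' compute the pairwise GSEA distance matrix, rank perturbations against the
#' query condition and cluster the matrix — writing every intermediate
#' artifact as plain TSV plus a JSON run manifest with the configuration and
#' MD5 content hashes. Re-running with an identical configuration and seed
#' reproduces byte-identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim_config A `sim_config` to simulate the study, or `NULL` to
#'   ingest `matrix_path` + `manifest_path` instead.
#' @param matrix_path,manifest_path Paths to an expression matrix TSV and a
#'   pairing manifest TSV; used when `sim_config` is `NULL`.
#' @param signature_size GSEA signature size `n`.
#' @param query Query condition label for the ranking stage; defaults to
#'   the simulated study's disease label, otherwise the first condition in
#'   the manifest.
#' @param quiet Suppress stage logging to standard error.
#' @return Invisibly, a list with the in-memory artifacts (`ranking`,
#'   `distance`, `merged`, `clustering`, `manifest_path`).
#' @export
run_pipeline <- function(out_dir, sim_config = NULL, matrix_path = NULL,
                         manifest_path = NULL, signature_size = 250L,
                         query = NULL, quiet = FALSE) {
  signature_size <- as.integer(signature_size)
  if (signature_size < 1L) {
    stop("signature_size must be >= 1", call. = FALSE)
  }
  log_stage <- function(...) {
    if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  }

  # validate the whole configuration before any stage writes anything
  if (is.null(sim_config)) {
    if (is.null(matrix_path) || is.null(manifest_path)) {
      stop("supply either sim_config or matrix_path + manifest_path",
           call. = FALSE)
    }
    if (!file.exists(matrix_path) || !file.exists(manifest_path)) {
      stop("input file(s) not found", call. = FALSE)
    }
  } else {
    if (!inherits(sim_config, "sim_config")) {
      stop("sim_config must come from simulation_config()", call. = FALSE)
    }
    if (2L * signature_size > sim_config$n_probes) {
      stop("2 * signature_size exceeds the probe universe (",
           sim_config$n_probes, " probes)", call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "prls"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "merged"), showWarnings = FALSE)

  if (is.null(sim_config)) {
    log_stage("[ingest] ", matrix_path)
    expr <- read_expression_matrix(matrix_path)
    manifest <- read_pair_manifest(manifest_path)
    ground_truth <- NULL
  } else {
    log_stage("[simulate] ", sim_config$n_conditions, " conditions, ",
              sim_config$n_probes, " probes, seed ", sim_config$seed)
    study <- simulate_study(sim_config)
    expr <- study$expr
    manifest <- study$manifest
    ground_truth <- study$ground_truth
    jsonlite::write_json(ground_truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  validate_pair_manifest(manifest, expr)
  expr <- harmonize_probes(list(expr))[[1L]]
  if (2L * signature_size > nrow(expr)) {
    stop("2 * signature_size exceeds the probe universe (", nrow(expr),
         " probes)", call. = FALSE)
  }
  write_expression_matrix(expr, file.path(out_dir, "matrix.tsv"))
  write_pair_manifest(manifest, file.path(out_dir, "manifest.tsv"))

  log_stage("[build-prl] ", nrow(manifest), " sample pairs")
  prls <- build_prls(expr, manifest)
  for (nm in names(prls)) {
    write_prl(prls[[nm]], file.path(out_dir, "prls",
                                    paste0(nm, ".prl.tsv")))
  }

  log_stage("[merge] ", length(unique(manifest$condition)), " conditions")
  merged <- merge_by_condition(prls)
  for (cond in names(merged)) {
    write_prl(merged[[cond]]$prl,
              file.path(out_dir, "merged", paste0(cond, ".prl.tsv")))
    utils::write.table(merged[[cond]]$trace,
                       file.path(out_dir, "merged",
                                 paste0(cond, ".merge_trace.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_stage("[distance] signature size ", signature_size)
  dm <- distance_matrix(lapply(merged, `[[`, "prl"), n = signature_size)
  write_distance_matrix(dm, file.path(out_dir, "distance_matrix.tsv"))

  if (is.null(query)) {
    query <- if (!is.null(ground_truth)) ground_truth$disease
             else manifest$condition[[1L]]
  }
  log_stage("[rank] query = ", query)
  ranking <- rank_perturbations(dm, query)
  utils::write.table(ranking, file.path(out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("[cluster] average linkage, ", nrow(dm), " conditions")
  clustering <- cluster_distance_matrix(dm)
  utils::write.table(clustering$linkage, file.path(out_dir, "linkage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(clustering$leaf_order, file.path(out_dir, "leaf_order.txt"))

  manifest_path_out <- write_run_manifest(out_dir, sim_config,
                                          signature_size, query)
  log_stage("[done] artifacts in ", out_dir)
  invisible(list(ranking = ranking, distance = dm, merged = merged,
                 clustering = clustering, manifest_path = manifest_path_out))
}

# JSON provenance record: configuration plus MD5 of every TSV/TXT artifact.
write_run_manifest <- function(out_dir, sim_config, signature_size, query) {
  files <- sort_c(list.files(out_dir, recursive = TRUE,
                             pattern = "\\.(tsv|txt|json)$"))
  files <- setdiff(files, "run_manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(
    signature_size = signature_size,
    query = query,
    sim_config = if (is.null(sim_config)) NULL else unclass(sim_config),
    artifacts = hashes)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
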