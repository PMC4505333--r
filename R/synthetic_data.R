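#' Configuration for a synthetic case/control study
#'
#' Describes a self-contained two-colour-free microarray-like study: one
#' "disease" condition plus decoy and designated perturbation conditions,
#' each observed as replicate experiment/control sample pairs over a shared
#' probe universe. Intensities are log-normal; differential probes are
#' planted multiplicatively; noise is multiplicative log-normal — the
#' statistical structure the ratio/threshold rank-list construction assumes.
#'
#' @param n_probes Size of the probe universe.
#' @param n_conditions Total conditions: 1 disease + (`n_conditions` - 1)
#'   perturbations.
#' @param replicates_per_condition Experiment/control pairs per condition.
#' @param signature_size_planted Number of probes planted up AND down per
#'   condition.
#' @param fold_change Multiplicative effect (> 1) for planted probes.
#' @param noise_sigma Log-scale SD of the multiplicative noise applied to
#'   every experiment sample.
#' @param overlap_fraction Share of the disease's planted up and down sets
#'   reused, same direction, by the designated perturbation; decoys never
#'   touch the disease's planted probes.
#' @param seed Integer seed; identical configs give identical studies.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_probes = 2000L,
                              n_conditions = 21L,
                              replicates_per_condition = 3L,
                              signature_size_planted = 100L,
                              fold_change = 4,
                              noise_sigma = 0.2,
                              overlap_fraction = 0.8,
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_conditions = as.integer(n_conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              signature_size_planted = as.integer(signature_size_planted),
              fold_change = fold_change,
              noise_sigma = noise_sigma,
              overlap_fraction = overlap_fraction,
              seed = as.integer(seed))
  if (2L * cfg$signature_size_planted > cfg$n_probes) {
    stop("planted sets do not fit: need 2 * signature_size_planted <= n_probes",
         call. = FALSE)
  }
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$fold_change <= 1) stop("fold_change must exceed 1", call. = FALSE)
  if (cfg$n_conditions < 2L) {
    stop("need the disease plus at least one perturbation", call. = FALSE)
  }
  if (cfg$replicates_per_condition < 1L || cfg$n_probes < 4L) {
    stop("need >= 1 replicate pair and >= 4 probes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a control sample
#'
#' I.i.d. log-normal intensities (log-mean 6, log-sd 1 by default),
#' mimicking positive linear-scale array intensities with a long right
#' tail; about a quarter of the values fall below the pooled lower
#' quartile, so the thresholding branch of the rank-list builder is always
#' exercised.
#'
#' @param n_probes Number of probes (>= 4).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param meanlog,sdlog Log-scale location and scale.
#' @return Positive numeric vector of length `n_probes`.
#' @export
simulate_control <- function(n_probes, seed = NULL, meanlog = 6, sdlog = 1) {
  if (n_probes < 4L) stop("n_probes must be >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::rlnorm(n_probes, meanlog = meanlog, sdlog = sdlog)
}

#' Simulate a perturbed experiment sample from its control
#'
#' Planted up-probes are multiplied by `fold_change`, planted down-probes
#' divided by it, everything else left at the control value; the whole
#' vector is then multiplied element-wise by `exp(N(0, noise_sigma))`.
#'
#' @param control Named positive vector (names = probe ids).
#' @param up_probes,down_probes Disjoint probe id sets.
#' @param fold_change Multiplicative effect (> 1).
#' @param noise_sigma Log-scale noise SD (0 = noise-free).
#' @param seed Optional integer seed.
#' @return Positive vector aligned with `control`.
#' @export
simulate_perturbation <- function(control, up_probes, down_probes,
                                  fold_change = 4, noise_sigma = 0.2,
                                  seed = NULL) {
  if (length(intersect(up_probes, down_probes))) {
    stop("up and down planted sets must be disjoint", call. = FALSE)
  }
  if (is.null(names(control))) {
    stop("control vector must carry probe ids as names", call. = FALSE)
  }
  if (!all(c(up_probes, down_probes) %in% names(control))) {
    stop("planted probes must exist in the control vector", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  experiment <- control
  experiment[up_probes] <- experiment[up_probes] * fold_change
  experiment[down_probes] <- experiment[down_probes] / fold_change
  if (noise_sigma > 0) {
    experiment <- experiment *
      exp(stats::rnorm(length(experiment), 0, noise_sigma))
  }
  experiment
}

#' Simulate a full multi-condition study
#'
#' Generates one disease condition plus `n_conditions - 1` perturbation
#' conditions, each with `replicates_per_condition` experiment/control
#' pairs over a shared probe universe. Exactly one designated perturbation
#' reuses `overlap_fraction` of the disease's planted up and down sets in
#' the same directions (its remaining planted probes, and all decoy
#' planted sets, are drawn from probes the disease leaves untouched), so
#' the study carries a known ground truth for recovery experiments.
#'
#' @param config A `sim_config` (see [simulation_config()]).
#' @return A list with:
#'   \describe{
#'     \item{expr}{expression matrix, columns
#'       `<condition>_r<k>_exp` / `<condition>_r<k>_ctl`.}
#'     \item{manifest}{pairing manifest data frame.}
#'     \item{ground_truth}{list: `designated` label, `disease` label, and
#'       `planted` (per-condition `up`/`down` probe id sets).}
#'   }
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must come from simulation_config()", call. = FALSE)
  }
  k <- config$signature_size_planted
  n_pert <- config$n_conditions - 1L
  probes <- sprintf("P%05d", seq_len(config$n_probes))
  free_pool_size <- config$n_probes - 2L * k
  if (n_pert > 1L && free_pool_size < 2L * k) {
    stop("planted sets cannot fit disjointly from the disease's sets: ",
         "need n_probes >= 4 * signature_size_planted for decoys",
         call. = FALSE)
  }

  set.seed(config$seed)
  disease <- "disease"
  pert_labels <- sprintf("pert%02d", seq_len(n_pert))
  designated <- pert_labels[[1L]]

  disease_planted <- sample(probes, 2L * k)
  planted <- list()
  planted[[disease]] <- list(up = disease_planted[seq_len(k)],
                             down = disease_planted[seq.int(k + 1L, 2L * k)])
  pool <- setdiff(probes, disease_planted)

  n_shared <- as.integer(round(config$overlap_fraction * k))
  for (lab in pert_labels) {
    if (lab == designated) {
      up <- c(planted[[disease]]$up[seq_len(n_shared)],
              if (n_shared < k) sample(pool, k - n_shared))
      pool_left <- setdiff(pool, up)
      down <- c(planted[[disease]]$down[seq_len(n_shared)],
                if (n_shared < k) sample(pool_left, k - n_shared))
    } else {
      fresh <- sample(pool, 2L * k)
      up <- fresh[seq_len(k)]
      down <- fresh[seq.int(k + 1L, 2L * k)]
    }
    planted[[lab]] <- list(up = up, down = down)
  }

  conditions <- c(disease, pert_labels)
  n_pairs <- length(conditions) * config$replicates_per_condition
  expr <- matrix(NA_real_, config$n_probes, 2L * n_pairs)
  rownames(expr) <- probes
  col_names <- character(2L * n_pairs)
  manifest <- data.frame(experiment_id = character(n_pairs),
                         control_id = character(n_pairs),
                         condition = character(n_pairs),
                         dataset = character(n_pairs),
                         stringsAsFactors = FALSE)
  row <- 0L
  for (lab in conditions) {
    for (r in seq_len(config$replicates_per_condition)) {
      row <- row + 1L
      ctl <- simulate_control(config$n_probes)
      names(ctl) <- probes
      exp_v <- simulate_perturbation(ctl, planted[[lab]]$up,
                                     planted[[lab]]$down,
                                     fold_change = config$fold_change,
                                     noise_sigma = config$noise_sigma)
      exp_id <- sprintf("%s_r%d_exp", lab, r)
      ctl_id <- sprintf("%s_r%d_ctl", lab, r)
      expr[, 2L * row - 1L] <- exp_v
      expr[, 2L * row] <- ctl
      col_names[c(2L * row - 1L, 2L * row)] <- c(exp_id, ctl_id)
      manifest[row, ] <- list(exp_id, ctl_id, lab,
                              sprintf("%s_ds%d", lab, r))
    }
  }
  colnames(expr) <- col_names
  validate_expression_matrix(expr)
  validate_pair_manifest(manifest, expr)
  list(expr = expr, manifest = manifest,
       ground_truth = list(designated = designated, disease = disease,
                           planted = planted))
}
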