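test_that("simulate_control is seed-reproducible with the stated log-normal law", {
  expect_identical(simulate_control(100, seed = 5), simulate_control(100, seed = 5))
  expect_false(identical(simulate_control(100, seed = 5),
                         simulate_control(100, seed = 6)))
  v <- simulate_control(1e4, seed = 7)
  expect_true(all(v > 0))
  expect_lt(abs(mean(log(v)) - 6), 0.05)
})

test_that("simulate_perturbation plants multiplicative effects then noise", {
  ctl <- simulate_control(500, seed = 8)
  names(ctl) <- sprintf("P%03d", 1:500)

  expect_identical(
    simulate_perturbation(ctl, character(0), character(0), noise_sigma = 0),
    ctl)

  one_up <- simulate_perturbation(ctl, "P001", character(0),
                                  fold_change = 4, noise_sigma = 0)
  expect_equal(one_up[["P001"]] / ctl[["P001"]], 4)
  expect_identical(one_up[-1], ctl[-1])

  up <- names(ctl)[1:250]
  down <- names(ctl)[251:500]
  noisy <- simulate_perturbation(ctl, up, down, fold_change = 4,
                                 noise_sigma = 0.2, seed = 9)
  ratio <- noisy / ctl
  expect_true(all(noisy > 0))
  med_up <- stats::median(ratio[up])
  expect_gte(med_up, 3); expect_lte(med_up, 5.3)
  med_down <- stats::median(ratio[down])
  expect_gte(med_down, 1 / 5.3); expect_lte(med_down, 1 / 3)

  expect_error(simulate_perturbation(ctl, "P001", "P001"), "disjoint")
})

test_that("simulated studies honour the planted design and pass validation", {
  cfg <- simulation_config(n_probes = 400, n_conditions = 4,
                           replicates_per_condition = 2,
                           signature_size_planted = 40,
                           overlap_fraction = 0.5, seed = 10)
  study <- simulate_study(cfg)
  expect_silent(validate_expression_matrix(study$expr))
  expect_silent(validate_pair_manifest(study$manifest, study$expr))
  expect_identical(nrow(study$manifest), 4L * 2L)
  gt <- study$ground_truth
  expect_identical(sort(names(gt$planted)),
                   sort(c("disease", "pert01", "pert02", "pert03")))
  # designated shares exactly round(0.5 * 40) planted probes per direction
  expect_length(intersect(gt$planted$disease$up,
                          gt$planted[[gt$designated]]$up), 20)
  expect_length(intersect(gt$planted$disease$down,
                          gt$planted[[gt$designated]]$down), 20)
  # decoys never touch the disease's planted probes
  for (lab in setdiff(names(gt$planted), c("disease", gt$designated))) {
    expect_length(intersect(unlist(gt$planted[[lab]]),
                            unlist(gt$planted$disease)), 0)
  }
  # determinism under a fixed seed
  expect_identical(simulate_study(cfg)$expr, study$expr)

  # emitted artifacts survive the expr_io round trip
  mp <- withr::local_tempfile(); fp <- withr::local_tempfile()
  write_expression_matrix(study$expr, mp)
  write_pair_manifest(study$manifest, fp)
  expect_equal(read_expression_matrix(mp), study$expr, tolerance = 1e-12)
  expect_identical(read_pair_manifest(fp), study$manifest)
})

test_that("full overlap without noise makes the designated perturbation closest", {
  cfg <- simulation_config(n_probes = 500, n_conditions = 6,
                           replicates_per_condition = 2,
                           signature_size_planted = 50,
                           overlap_fraction = 1, noise_sigma = 0, seed = 11)
  study <- simulate_study(cfg)
  merged <- merge_by_condition(build_prls(study$expr, study$manifest))
  disease <- merged$disease$prl
  labs <- setdiff(names(merged), "disease")
  d <- vapply(labs, function(l) prl_distance(disease, merged[[l]]$prl, 50),
              numeric(1))
  expect_identical(names(which.min(d)), study$ground_truth$designated)
  expect_true(all(d[setdiff(labs, study$ground_truth$designated)] >
                    d[study$ground_truth$designated]))
})

test_that("impossible configurations are rejected up front", {
  expect_error(simulation_config(n_probes = 100, signature_size_planted = 60),
               "planted sets do not fit")
  expect_error(simulation_config(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(simulation_config(fold_change = 1), "fold_change")
  expect_error(simulate_study(simulation_config(n_probes = 300,
                                                signature_size_planted = 100,
                                                n_conditions = 3)),
               "disjointly")
})
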