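test_that("TSV expression matrices are read with order and values preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_tsv(tiny_expr(), path)
  m <- read_expression_matrix(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("PA", "PB", "PC"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(as.numeric(t(m)), as.numeric(1:6))
})

test_that("invalid expression values and duplicate probes are rejected by name", {
  m <- tiny_expr()
  m["PB", "s2"] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_tsv(m, path)
  expect_error(read_expression_matrix(path), "PB.*s2")

  m2 <- tiny_expr()
  rownames(m2) <- c("PA", "PA", "PC")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_tsv(m2, path2)
  expect_error(read_expression_matrix(path2), "duplicate probe")
})

test_that("GCT and TSV dialects of the same data yield identical matrices", {
  m <- tiny_expr()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gct <- withr::local_tempfile(fileext = ".gct")
  write_tiny_tsv(m, tsv)
  write_tiny_gct(m, gct)
  expect_identical(read_expression_matrix(tsv, "tsv"),
                   read_expression_matrix(gct, "gct"))
  expect_error(read_expression_matrix(tsv, "gct"), "1\\.2")
})

test_that("harmonize_probes restricts to the sorted common universe", {
  mk <- function(probes) {
    matrix(seq_along(probes) + 0.5, ncol = 1,
           dimnames = list(probes, paste0("s", probes[1])))
  }
  out <- harmonize_probes(list(mk(c("A", "B", "C")), mk(c("B", "C", "D"))))
  expect_identical(rownames(out[[1]]), c("B", "C"))
  expect_identical(rownames(out[[2]]), c("B", "C"))

  # single matrix: identity up to row sorting
  single <- harmonize_probes(list(mk(c("C", "A", "B"))))[[1]]
  expect_identical(rownames(single), c("A", "B", "C"))

  # nested sets: smallest retained; result idempotent and shared
  nested <- list(mk(c("A", "B", "C", "D")), mk(c("B", "C", "D")),
                 mk(c("C", "D")))
  out2 <- harmonize_probes(nested)
  expect_true(all(vapply(out2, function(m) {
    identical(rownames(m), c("C", "D"))
  }, logical(1))))
  expect_identical(harmonize_probes(out2), out2)

  expect_error(harmonize_probes(list(mk(c("A")), mk(c("B")))),
               "empty probe intersection")
})

test_that("pair manifests are parsed, grouped and validated against matrices", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment_id\tcontrol_id\tcondition\tdataset",
               "s1\ts2\tUC\tds1",
               "e2\tc2\tsiRNA\tds2"), path)
  manifest <- read_pair_manifest(path)
  expect_identical(nrow(manifest), 2L)
  expect_identical(sort(unique(manifest$condition)), c("UC", "siRNA"))

  # five entries sharing one condition form one group of five
  m5 <- data.frame(experiment_id = paste0("e", 1:5),
                   control_id = paste0("c", 1:5),
                   condition = "siRNA", dataset = paste0("d", 1:5))
  expect_identical(unname(table(m5$condition)["siRNA"]), 5L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("experiment_id\tcondition\tdataset", "a\tx\ty"), bad)
  expect_error(read_pair_manifest(bad), "missing column.*control_id")

  expr <- tiny_expr()
  expect_error(validate_pair_manifest(manifest, expr), "e2")
  expect_silent(validate_pair_manifest(manifest[1, ], expr))
  manifest$control_id[1] <- manifest$experiment_id[1]
  expect_error(validate_pair_manifest(manifest), "itself")
})

test_that("PRL files round-trip bit-exactly and reject non-permutations", {
  withr::local_seed(11)
  prl <- random_prl(50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prl(prl, path)
  expect_identical(read_prl(path), prl)

  writeLines(c("rank\tprobe_id", "1\tP1", "2\tP1"), path)
  expect_error(read_prl(path), "permutation")
  writeLines(c("rank\tprobe_id", "1\tP1", "3\tP2"), path)
  expect_error(read_prl(path), "contiguous")
})

test_that("distance matrices round-trip to 12 significant digits", {
  withr::local_seed(12)
  k <- 106
  half <- matrix(stats::runif(k * k, 0, 2), k, k)
  dm <- (half + t(half)) / 2
  diag(dm) <- 0
  dimnames(dm) <- list(sprintf("cond%03d", 1:k), sprintf("cond%03d", 1:k))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path)
  back <- read_distance_matrix(path)
  expect_identical(dimnames(back), dimnames(dm))
  expect_equal(back, dm, tolerance = 1e-12)

  dm_bad <- dm
  dm_bad[1, 2] <- dm_bad[1, 2] + 0.5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  # bypass the writer's own validation to plant the asymmetry on disk
  lines <- c(paste(c("condition", colnames(dm_bad)), collapse = "\t"),
             vapply(seq_len(k), function(i) {
               paste(c(rownames(dm_bad)[i], sprintf("%.15g", dm_bad[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path2)
  expect_error(read_distance_matrix(path2), "not symmetric")
})

test_that("all writers produce files their readers accept (round-trip property)", {
  withr::local_seed(13)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    prl <- random_prl(n)
    p1 <- withr::local_tempfile()
    write_prl(prl, p1)
    expect_identical(read_prl(p1), prl)

    expr <- matrix(stats::rlnorm(n * 4, 6, 1), n, 4,
                   dimnames = list(sort(prl), paste0("s", 1:4)))
    p2 <- withr::local_tempfile()
    write_expression_matrix(expr, p2)
    expect_equal(read_expression_matrix(p2), expr, tolerance = 1e-12)
  }
})
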