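# Shared fixtures and independent oracles, built in code at test time.

random_prl <- function(n, probes = sprintf("P%04d", seq_len(n))) {
  sample(probes)
}

# Naive per-position membership-test oracle for the equal-weighted GSEA
# running sum: walks the reference one rank at a time, testing membership
# at each position. Kept deliberately independent of enrichment_score().
# Partial sums are carried as integer numerators over n*(N-n) so the
# extreme-deviation tie rule (positive wins) is decided exactly.
es_oracle <- function(gene_set, reference) {
  n <- length(gene_set)
  N <- length(reference)
  s <- 0
  best <- 0
  for (i in seq_len(N)) {
    s <- if (reference[[i]] %in% gene_set) s + (N - n) else s - n
    if (abs(s) > abs(best) || (abs(s) == abs(best) && s > best)) best <- s
  }
  best / (n * (N - n))
}

tiny_expr <- function() {
  m <- matrix(as.numeric(1:6), nrow = 3, byrow = TRUE,
              dimnames = list(c("PA", "PB", "PC"), c("s1", "s2")))
  m
}

write_tiny_tsv <- function(m, path) {
  lines <- c(paste(c("probe_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  path
}

write_tiny_gct <- function(m, path) {
  lines <- c("#1.2",
             paste(nrow(m), ncol(m), sep = "\t"),
             paste(c("Name", "Description", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], "na", m[i, ]), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  path
}

# Rank of the designated perturbation among all perturbations, by GSEA
# distance of merged condition PRLs to the merged disease PRL.
designated_rank <- function(seed, overlap_fraction,
                            signature_size = 100L) {
  cfg <- simulation_config(overlap_fraction = overlap_fraction, seed = seed)
  study <- simulate_study(cfg)
  merged <- merge_by_condition(build_prls(study$expr, study$manifest))
  disease <- merged[[study$ground_truth$disease]]$prl
  labs <- setdiff(names(merged), study$ground_truth$disease)
  d <- vapply(labs, function(l) {
    prl_distance(disease, merged[[l]]$prl, signature_size)
  }, numeric(1L))
  ordered <- labs[order(d, labs, method = "radix")]
  match(study$ground_truth$designated, ordered)
}
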