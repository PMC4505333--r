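# sigmatch

Rank-based matching of transcriptional signatures between a disease and a
panel of perturbations (for example siRNA gene-silencing experiments), for
computational target nomination: if silencing a gene reshapes the
transcriptome the way the disease does, that gene's activity is a candidate
driver of the disease state.

The package is aimed at computational biologists working with positive,
linear-scale probe-level expression data (classic two-condition microarray
case/control designs). It compares profiles by *rank*, never by magnitude,
so studies from different labs, platforms within a shared probe universe,
and cell types remain comparable.

## The method

**1. Probe rank lists (PRLs).** Each experiment/control sample pair is
reduced to a strict permutation of the probe universe, rank 1 = most
upregulated. Let *t* be the lower quartile of the pooled intensities of the
two samples and *t/10* the secondary threshold. Probes are ranked by
descending ratio

&nbsp;&nbsp;&nbsp;&nbsp;r(p) = max(e(p), t) / max(c(p), t)

and the block with r(p) = 1 (mostly probes clamped on both sides, i.e.
near-background noise) is sub-sorted by the same ratio re-computed with the
original values clamped at *t/10*. Residual ties break by probe id, so the
list is deterministic. The clamp suppresses the wild fold changes produced
by dividing near-zero intensities.

**2. Hierarchical majority voting.** Replicate PRLs of one condition are
merged into a consensus list: repeatedly find the pair of lists with the
smallest Spearman footrule distance Σ|rank_a(p) − rank_b(p)| and replace it
by its Borda merge (probes re-ranked by mean rank), until one list remains.
Concordant replicates are averaged before discordant ones join.

**3. Bidirectional GSEA distance.** The signature of a PRL is its top-*n*
and bottom-*n* probes (*n* = 250 by default). Scoring a probe set against a
reference PRL walks the reference keeping a running sum that rises 1/n at
hits and falls 1/(N−n) at misses; the enrichment score ES ∈ [−1, 1] is the
signed extreme deviation from zero. A signature's two-sided score is
(ES_up − ES_down)/2 and the distance between PRLs A and B is

&nbsp;&nbsp;&nbsp;&nbsp;D(A, B) = 1 − (ES_AB + ES_BA)/2 ∈ [0, 2],

0 for identically regulated profiles, 2 for perfectly opposed ones.
Perturbations are ranked by ascending distance to the disease query, and
the full distance matrix is clustered with average linkage.

## Worked example

A synthetic study with one disease, five perturbations (three replicate
pairs each, 1000 probes), where `pert01` shares 80% of the disease's
planted up/down probes and the rest are decoys:

```r
library(sigmatch)

cfg <- simulation_config(n_probes = 1000, n_conditions = 6,
                         replicates_per_condition = 3,
                         signature_size_planted = 80,
                         fold_change = 4, noise_sigma = 0.2,
                         overlap_fraction = 0.8, seed = 42)
study  <- simulate_study(cfg)
prls   <- build_prls(study$expr, study$manifest)
merged <- merge_by_condition(prls)
dm     <- distance_matrix(lapply(merged, `[[`, "prl"), n = 80)
print(rank_perturbations(dm, "disease"), digits = 3)
#>   condition distance
#> 1    pert01    0.407
#> 2    pert02    0.926
#> 3    pert03    0.928
#> 4    pert04    1.037
#> 5    pert05    1.058
```

The designated perturbation `pert01` sits far below the decoys, which
hover near 1 — the expected distance for unrelated profiles (their
signatures are random with respect to each other, so both enrichment
scores are near zero). `cluster_distance_matrix(dm)` returns the
average-linkage linkage table and dendrogram leaf order for the same
matrix.

The same pipeline runs in one call, writing every intermediate artifact
(per-pair PRLs, merged PRLs, merge traces, distance matrix, ranking,
linkage, run manifest with content hashes):

```r
run_pipeline("run_out", sim_config = cfg, signature_size = 80)
```

or from a shell via the thin CLI in `inst/scripts/sigmatch`
(subcommands `simulate`, `build-prl`, `merge`, `distance`, `rank`,
`cluster`, `run`).

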