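---
title: "Rank-based signature matching: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based signature matching: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmatch)
```

## The problem and the model

Given case/control expression profiles of a disease and of a panel of
gene-silencing perturbations, we want to rank the perturbations by how
closely their transcriptional footprint resembles the disease's. A
perturbation whose profile matches the disease in *both* direction and
composition of regulation points at its silenced gene as a candidate
player in the disease state. All comparisons are rank-based: the only
assumption on the data is that intensities are positive, finite and on a
linear scale, and that all profiles share one probe universe.
`harmonize_probes()` enforces the shared universe once, before anything
else runs, by intersecting probe sets across datasets — probes missing
from any dataset carry no cross-study information and are dropped.

### Stage 1: probe rank lists

For one experiment/control pair with intensities $e(p)$, $c(p)$, let $t$
be the lower quartile of the pooled $2N$ values and $t/10$ the secondary
threshold. `build_prl()` ranks probes by descending

$$r(p) = \frac{\max(e(p), t)}{\max(c(p), t)},$$

then re-scores the block with $r(p) = 1$ using the *original* values
clamped at $t/10$ and sub-sorts that block in place. The clamp exists
because raw ratios explode when the denominator sits at background; the
quartile is a robust, pair-specific estimate of where background ends.
The secondary pass recovers ordering information inside the clamped
block at a ten-fold looser threshold: re-clamping the already-clamped
values would be a no-op, which is why the original values are used.
Ratios of exactly one arising from genuinely equal unclamped values are
treated the same as clamp-induced ones — the procedure cannot, and does
not try to, distinguish them.

### Stage 2: consensus over replicates

Replicate lists of one condition are merged by hierarchical majority
voting (`merge_condition_prls()`): repeatedly merge the two closest
lists until one remains. The scheme itself leaves two choices open, and
we instantiate the canonical pair: the agglomeration criterion is the
Spearman footrule $\sum_p |\mathrm{rank}_a(p) - \mathrm{rank}_b(p)|$ — a
true metric on permutations, cheap and interpretable — and the merge
function is the Borda (mean-rank) merge, which is commutative and
idempotent. Merged lists carry no extra weight at later steps; the
alternative (weighting by absorbed list count) remains comparable later
because the full merge order and distances are recorded in the trace.

### Stage 3: bidirectional enrichment distance

The signature of a PRL is its top-$n$ and bottom-$n$ probes. Scoring a
size-$n$ set against a reference list of length $N$ uses the
equal-weighted running sum (up $1/n$ at hits, down $1/(N-n)$ at misses);
the enrichment score is the signed extreme deviation from zero, in
$[-1, 1]$. A signature's two-sided score is $(ES_{up} - ES_{down})/2$,
and the distance between lists $A$ and $B$ is

$$D(A,B) = 1 - \frac{ES_{AB} + ES_{BA}}{2} \in [0, 2].$$

Two unrelated profiles have both enrichment scores near zero and hence
$D \approx 1$; concordant regulation pushes $D$ toward 0, opposed
regulation toward 2. No same-sign zeroing is applied to the two-sided
score: the combination is always $(ES_{up} - ES_{down})/2$, which is the
arithmetic consistent with the published per-direction scores this
package reproduces in its acceptance check. No null distribution is
computed for $D$; the method is a ranking device, not a significance
test.

## Tunable parameters

* `n` (signature size, default **250** probes): the conventional
  empirical value for genome-scale universes (~22k probes). The final
  ranking is insensitive to moderate changes; for small synthetic
  universes scale it with the planted effect size (the tests use
  `n = 100` on 2000 probes). Must satisfy $2n \le N$.
* Secondary threshold ratio (fixed at one tenth of the primary): part of
  the procedure's definition, not exposed as a knob.
* Linkage for `cluster_distance_matrix()`: average (UPGMA), the
  conventional default for similarity heat maps; the matrix is treated
  as a precomputed dissimilarity.

## Numerical choices

* **Quantile convention.** "Lower quartile" uses linear interpolation
  between order statistics (`stats::quantile` type 7), reproducible in
  any numerical environment; any fixed convention preserves the method.
* **Ratio-equals-one test.** Exact equality after clamping creates the
  tie block, with a relative guard of `1e-12` against representation
  noise; guarded ratios are snapped to exactly 1 so the block sub-sorts
  as a unit.
* **Exact running sum.** Enrichment partial sums are carried as integer
  numerators over the common denominator $n(N-n)$ (hits add $N-n$,
  misses subtract $n$), so the extreme-deviation comparison — and its
  tie rule, *positive wins at equal magnitude* — is decided exactly
  rather than at the mercy of floating-point accumulation order. The
  returned score is the chosen numerator divided by $n(N-n)$.
* **Tie-breaks.** Every residual tie in the package (ranks, Borda
  scores, ranking tables, merge-pair selection) is broken by C-locale
  lexicographic id order, making all outputs byte-deterministic across
  platforms and locales.
* **Degenerate inputs.** Non-positive or non-finite intensities,
  duplicate ids, universes that do not match, signatures with $2n > N$,
  empty probe intersections and asymmetric distance matrices are all
  rejected with named errors before any computation runs.

## What the synthetic generator emulates — and what it does not

`simulate_study()` draws control intensities i.i.d. log-normal
(log-mean 6, log-sd 1), multiplies planted up/down probes by a fold
change (default 4) and applies multiplicative log-normal noise
(log-sd 0.2) to every experiment sample. These defaults give a realistic
long-tailed positive intensity distribution in which roughly a quarter
of values fall below the pooled lower quartile, so both threshold
branches of the PRL builder are exercised in every run. One designated
perturbation reuses a controllable fraction (default 0.8) of the
disease's planted sets in the same directions; decoys plant disjoint
random sets. The default study (2000 probes, 1 disease + 20
perturbations, 3 replicate pairs each, planted size 100) is the
condition under which the recovery tests run.

The generator does **not** emulate probe-level correlation, batch or
lab effects, platform-specific probe behaviour, cell-type heterogeneity
or background-correction artifacts. Passing the recovery tests therefore
demonstrates that the pipeline's machinery recovers a planted shared
signature under realistic noise — not that real cross-study, cross-cell
comparisons reach a given accuracy.

## Problem sizes in the test suite

The suite verifies the enrichment score against a naive per-position
oracle on 500 random instances ($N \le 1000$), distance axioms on 100
random list pairs ($N = 1000$, $n = 100$), merge metric axioms on 200
random permutation triples ($N = 50$), planted-signature recovery over
100 seeded default studies (requiring the designated perturbation at
rank 1 in at least 95) plus a 200-seed zero-overlap null in which its
rank is uniform (chi-square goodness of fit), and byte-identical
artifacts across repeated pipeline runs. These sizes were chosen as the
smallest at which each property is statistically meaningful.

## Known limitations

* The distance carries no significance estimate; interpret rankings
  relatively, and expect decoys to concentrate near $D = 1$.
* The merge is unweighted, so a condition with many concordant
  replicates is not up-weighted against a discordant straggler beyond
  what merge order already provides.
* Rank lists discard magnitude entirely: a uniform small shift and a
  focused large one can produce similar lists.
* Probe-to-gene annotation is out of scope; inputs and outputs speak
  probe ids.
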