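Package: sigmatch
Title: Rank-Based Transcriptional Signature Matching Between Disease and
    Perturbation Expression Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a connectivity-style pipeline for comparing bulk
    expression profiles by rank: probe rank lists (PRLs) are built from
    experiment/control sample pairs with a hierarchical lower-quartile
    threshold-and-sort procedure, replicate PRLs are merged by hierarchical
    majority voting (Spearman footrule agglomeration with Borda rank
    averaging), and profile similarity is scored with a bidirectional
    equal-weighted GSEA enrichment distance in [0, 2]. Includes readers and
    writers for the plain-text interchange formats (TSV expression matrices,
    GCT, pairing manifests, PRLs, distance matrices), perturbation ranking
    and average-linkage clustering of the distance matrix, a seeded
    log-normal synthetic-study generator with planted up/down-regulated
    probe sets, and an end-to-end pipeline driver with a reproducible run
    manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
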