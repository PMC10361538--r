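Package: tilmotif
Title: TCR Repertoire Diversity, Clonal Expansion and Tumor-Associated
    CDR3 Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of bulk TCR-beta sequencing repertoires from tumor,
    healthy tissue, peripheral blood and tumor-infiltrating lymphocyte
    (TIL) expansion products. Reads AIRR, immunoSEQ-style and plain TSV
    clonotype tables; applies productive-only, minimum-depth, singleton
    and seeded hypergeometric downsampling filters; computes clonality
    and diversity indices (Gini, inverse Simpson, Chao1, Shannon,
    clonality); tracks clonotypes across samples and tests clonal
    expansion between paired repertoires with two-sided Fisher exact
    tests under Benjamini-Hochberg control; discovers shared CDR3-beta
    local motifs (contiguous k-mers with an optional single wildcard)
    enriched over a naive reference, classifies motifs as
    tumor-exclusive or tumor-enriched by Wilcoxon rank-sum testing of
    pooled per-sample motif frequencies, prunes against control motif
    sets, quantifies motif burden in arbitrary repertoires, and assigns
    dominant immunophenotypes to motifs from single-cell
    clonotype-phenotype tables by largest odds ratio, with binned
    control-gene module scoring of expression matrices. A synthetic
    cohort generator with a ground-truth manifest makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
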