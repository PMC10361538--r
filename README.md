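# tilmotif

Analysis of T-cell receptor (TCR) beta-chain repertoires from tumors and
tumor-infiltrating lymphocyte (TIL) therapy products: repertoire
diversity and clonality, clonotype tracking and clonal-expansion testing
between paired samples, discovery of tumor-associated CDR3β motifs,
quantification of motif-bearing TCRs across repertoires, and odds-ratio
assignment of immunophenotypes to motifs from single-cell data. It is
aimed at computational immunologists working with bulk TCRβ-seq
(AIRR / immunoSEQ-style clonotype tables) and paired scRNA+TCRαβ-seq
data, in particular around adoptive TIL therapy, where the central
question is whether the clones expanded into the infusion product are
tumor-reactive or bystanders.

## What it computes

* **Diversity / clonality** per repertoire: Gini index of the
  clone-frequency distribution, inverse Simpson 1/Σpᵢ², Shannon entropy
  H, Chao1 richness S + F₁²/(2F₂) (bias-corrected fallback when F₂ = 0),
  and clonality 1 − H/ln S.
* **Clonal expansion** between paired repertoires (e.g. pre-REP vs REP
  TIL): per clonotype, a two-sided Fisher exact test on
  [c_A, N_A−c_A; c_B, N_B−c_B] with Benjamini–Hochberg correction over
  the union of clonotypes; a clone is expanded when p_adj < 0.05 and its
  frequency is ≥ 0.1% in at least one sample.
* **Motif discovery** (GLIPH2-style local motifs): contiguous 3–4-mers
  of the trimmed CDR3β core, plus single-wildcard patterns, clustered
  over distinct CDR3aa+V carriers and tested for enrichment against a
  naive background (one-sided Fisher, BH, fold ≥ 10, cluster ≥ 3).
* **Tumor association**: motifs found only in the tumor cohort are
  tumor-exclusive; motifs shared with healthy kidney or blood are
  tumor-enriched when a two-sided Wilcoxon rank-sum on per-sample pooled
  motif frequencies (zeros included) gives p_adj < 0.05 with
  log₂ fold change > 1; control-cohort and viral motif lists are pruned.
* **Motif burden**: the fraction of a repertoire's reads carried by
  TCRs bearing an associated motif at its discovery location, with
  per-motif contributions and ratios against exactly-annotated
  anti-viral TCR fractions.
* **Phenotype assignment**: for motifs with ≥ 5 supporting single cells,
  per-phenotype odds ratios from the motif × phenotype 2×2 table; the
  largest odds ratio names the dominant phenotype. Tirosh-style binned
  control-gene module scores (cytotoxicity, exhaustion, tissue
  residency) are included.
* **Synthetic cohorts**: a seeded generator with a ground-truth manifest
  (Zipf clone sizes, planted tumor-biased motifs, designated TIL
  expansions, viral spike-ins, phenotype-biased single cells) so the
  whole pipeline is testable end to end; see the methods vignette.

## Worked example

```r
library(tilmotif)

cfg <- generator_config(n_tumor = 6, n_healthy = 4, n_pb = 4,
                        n_til_pairs = 2, clones_per_sample = 150,
                        reads_per_sample = 20000)
cohort <- simulate_cohort(cfg, seed = 42)

diversity_summary(cohort$tumor[[1]])
#>   sample_id   tissue patient_id  gini inverse_simpson chao1 shannon clonality
#> 1 pt001_tumor tumor  pt001      0.766            10.2   153    3.43     0.318
```

A Gini of 0.77 with inverse Simpson ≈ 10 says this simulated tumor
repertoire is dominated by a handful of clones — about ten clones'
worth of effective diversity over 153 observed clonotypes.

```r
pair <- cohort$til[[1]]
ex <- test_expansion(pair$pre_rep, pair$rep)
head(ex[ex$expanded_in != "none",
        c("key", "freq_a", "freq_b", "p_adjusted", "expanded_in")], 3)
#>   key                                 freq_a  freq_b p_adjusted expanded_in
#> 1 CASTEHTEAFF|TRBV19|TRBJ1-1         0.00025 0.00465   1.63e-19 b
#> 2 CASTYNNEQFF|TRBV19|TRBJ2-1         0.00015 0.0038    5.04e-17 b
#> 3 CASRLVVHRWANRYGYTF|TRBV6-2|TRBJ1-2 0.00015 0.0026    1.98e-10 b
```

Three clonotypes that were tiny in the pre-REP culture (0.015–0.025%)
expanded 15–20-fold into the REP product (`expanded_in = "b"`), exactly
the clones the generator's manifest designated.

```r
ref   <- build_motif_reference(default_reference_repertoire())
idx_t <- discover_cohort_motifs(cohort$tumor, ref, tissue = "tumor")
idx_h <- discover_cohort_motifs(cohort$healthy, ref, tissue = "healthy_kidney")
idx_p <- discover_cohort_motifs(cohort$pb, ref, tissue = "pb")
assoc <- classify_motifs(idx_t, list(healthy_kidney = idx_h, pb = idx_p),
                         cohort$tumor,
                         list(healthy_kidney = cohort$healthy, pb = cohort$pb))
assoc <- prune_against_controls(assoc, cohort$manifest$control_sets)
table(assoc$status)
#> exclusive    pruned
#>        35         2
```

The 35 tumor-exclusive motifs are the six planted motifs plus their
sub-patterns and wildcard variants (which ride on the same carrier
clones); the two pruned motifs are exactly the ones the manifest planted
into the control sets.

```r
rcc <- associated_motifs(assoc)
b   <- motif_burden(cohort$til[[1]]$rep, rcc)
ann <- annotate_against_reference(cohort$til[[1]]$rep, viral_reference())
c(burden = b$fraction_reads, antiviral = ann$annotated_read_fraction,
  ratio = burden_ratio(b, ann$annotated_read_fraction))
#>    burden antiviral     ratio
#>     0.307    0.0045    68.2
```

In this REP product 30.7% of reads carry a tumor-associated motif,
against 0.45% annotated anti-viral — a 68× excess of putatively
tumor-reactive over bystander anti-viral TCRs.

The whole chain (filters → diversity → expansion → discovery →
association → burden → phenotype) also runs as one call with per-stage
TSV outputs and a provenance record:

```r
res <- run_pipeline(list(out_dir = "out", seed = 1))
```

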