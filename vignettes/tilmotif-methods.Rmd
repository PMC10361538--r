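---
title: "Methods: repertoire metrics, motif discovery and phenotype assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire metrics, motif discovery and phenotype assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilmotif)
```

## Scope and data model

`tilmotif` analyses bulk TCR-beta sequencing repertoires from tumor
material, healthy tissue, peripheral blood (PB), and tumor-infiltrating
lymphocyte (TIL) cultures before ("pre-REP") and after ("REP") the rapid
expansion protocol, together with single-cell clonotype–phenotype tables.
The unit container is the `clonotype_table`: one row per unique TCR-beta
rearrangement (CDR3 nucleotide and amino-acid sequence, V/J calls,
template count, productive flag) with sample-level metadata. Three keying
granularities are supported and used deliberately: CDR3 amino-acid
sequence alone for cross-sample clonotype tracking, CDR3aa + V + J for
bulk overlap and expansion analyses, and the exact CDR3 nucleotide
sequence for joins against single-cell clonotypes, where nucleotide
identity is the strict clonotype definition.

Offsets into CDR3 sequences are 1-based throughout, the native R string
convention; a motif "at offset 5" starts at the fifth residue of the full
CDR3.

## Filters

Repertoires pass a standard filter chain before analysis: only
productive (in-frame, stop-free) rearrangements are kept; samples with
fewer than 10,000 total reads are excluded; singletons (TCRs with exactly
one read) are removed from blood samples before motif quantification; and
samples are optionally downsampled to a common depth. Downsampling is a
without-replacement multivariate hypergeometric subsample realised by
sequential conditional hypergeometric draws, seeded and exact: output
counts always sum to the requested depth and never exceed the input
counts. Without-replacement is the conservative choice for template
counts — multinomial resampling would add extra-Poisson noise that the
data do not contain.

## Diversity and clonality

Per sample the package reports the Gini index of the clone-frequency
distribution (half the mean absolute pairwise difference over the mean;
0 for a perfectly even repertoire), inverse Simpson diversity
(`1 / sum(p^2)`), Shannon entropy, Chao1 richness
(`S + F1^2 / (2 F2)`, with the bias-corrected fallback
`S + F1(F1-1) / (2(F2+1))` when no doubletons exist), and a clonality
index defined as one minus Pielou evenness (`1 - H / ln S`). Gini is
computed over observed clonotypes only, with no unseen-species
correction, matching the convention of the common repertoire toolkits.
Because "clonality index" has no single accepted formula, the choice is
documented here and isolated in one function. Chao1 is the only index
that is not scale-invariant in the counts; diversity comparisons across
tissue groups therefore offer a downsample-within-group mode that
rarefies every sample to its group's smallest repertoire.

## Expansion testing

Clonal expansion between two repertoires (typically a pre-REP/REP TIL
pair) is tested per clonotype on the 2x2 table of (reads in sample A,
other reads in A; reads in B, other reads in B) with a two-sided Fisher
exact test. The two-sided p-value sums hypergeometric point
probabilities not exceeding that of the observed table — stated
explicitly because implementations differ — with a 1e-7 relative guard
against floating-point ties. Benjamini-Hochberg correction runs across
all clonotypes present in either sample (the union universe). A
clonotype is called expanded when its adjusted p is below 0.05 *and* its
frequency reaches 0.1% in at least one of the two samples (the
`>=` reading of the threshold); direction is the sample with the higher
frequency. Expansion testing is meant for full, non-downsampled
repertoires. Odds ratios use the Haldane–Anscombe +0.5 correction on all
four cells when any cell is zero, keeping ratios finite.

## Motif discovery

Discovery reimplements the *concept* behind local-motif specificity
clustering (as popularised by GLIPH2): short shared CDR3-beta patterns
enriched over a naive background. It is deliberately not a port — the
reference implementation is a black box with bundled reference data —
so exact output equality with that tool is a non-goal; the parameters
(k-mer lengths, trimming, fold, alpha) default to documented
GLIPH2-like values.

Each CDR3 is trimmed (3 residues head, 2 tail; both configurable) and
all contiguous 3- and 4-mers of the core are enumerated, plus, for each
k, the patterns of length k+1 with exactly one internal residue replaced
by the wildcard `*`. Unique TCRs (distinct CDR3aa + V) are pooled across
the cohort's samples; a motif's cluster is the set of distinct TCRs
carrying it anywhere in the trimmed core. Enrichment against a
background repertoire uses a one-sided Fisher exact test on
carrier/total TCR counts, BH-corrected across all candidate motifs with
cluster size of at least three. Retained motifs need fold >= 10 (with a
single-pseudocount guard for motifs absent from the background) and
adjusted p < 0.05, and record the union of observed start offsets.

Internally motifs are packed as base-27 integers (20 amino acids plus
the wildcard; codes of different widths cannot collide because every
digit is nonzero), which makes the grouping of hundreds of thousands of
candidate patterns a radix sort rather than a string sort. The public
enumeration API returns strings; tests assert the two representations
enumerate identical sets.

The default background is a deterministic synthetic naive repertoire
(2,000 clonotypes, fixed seed, no planted motifs) generated in code by
the package's own generator; it is user-replaceable by any
`clonotype_table`. Generating rather than shipping it keeps the
repository free of data files while remaining bit-reproducible.

## Tumor association and pruning

Motifs discovered in the tumor cohort but absent from the healthy-kidney
and PB discovery indexes are *tumor-exclusive*. Motifs shared with a
comparator index are tested by a two-sided Wilcoxon rank-sum on
per-sample pooled motif frequencies — all TCRs carrying the motif pooled
per sample, samples without the motif entered as zero — BH-corrected
across motifs within each comparator; *tumor-enriched* requires adjusted
p < 0.05 and log2 fold change > 1 against at least one comparator (the
"either comparator suffices" reading; an all-comparators mode is
provided). The fold change compares group means of the pooled
frequencies (median optionally), using the smallest nonzero pooled
frequency in the pool as pseudocount when a group mean is zero; a motif
at zero everywhere is rejected with an undefined fold change. The
rank-sum test uses the exact null for small tie-free groups and the
tie-corrected normal approximation otherwise; adding zero-frequency
comparator samples can nudge p by a few percent exactly at the
exact-to-approximate switch, and strictly helps beyond it — the
property tests encode precisely this guarantee.

Pruning then removes any motif whose string appears in a control set
(motif lists from unrelated validation cohorts, or viral-epitope motif
lists), increasing the signal-to-noise ratio of the surviving
tumor-associated set (exclusive plus enriched). Pruning is idempotent
and order-independent.

## Burden quantification

The burden of a motif set in a repertoire is the fraction of reads (and,
co-reported, of unique clonotypes) carried by TCRs bearing at least one
motif *at an allowed offset* — the "same location" rule: a match counts
only where the motif sat in the discovery cohort, the most literal
reading of location-restricted matching, with the alternatives
switchable. Per-motif contributions are reported alongside the union
fraction (a TCR carrying two motifs contributes to both). Provenance
filters are applied by the caller through one helper: non-singleton TCRs
only for blood, a 100-read minimum for thin external samples, and
40,000-read downsampling for deep external cohorts. Burden ratios
against a reference fraction (e.g. the exactly-annotated anti-viral read
fraction) quantify how strongly tumor-associated TCRs outnumber
bystander anti-viral clones.

## Phenotype assignment and module scores

For single-cell data, a motif's supporting cells are those whose
CDR3-beta carries it at an allowed offset. Motifs with at least five
supporting cells receive a call: per phenotype the motif-by-phenotype
2x2 table over all phenotyped cells yields an odds ratio
(Haldane–Anscombe corrected so the argmax is always defined), and the
phenotype with the largest odds ratio is dominant, with ties broken by
supporting-cell count then lexicographically. Phenotype labels are an
input column: clustering and annotation are upstream concerns and out of
scope, which also lets externally published phenotypes be used directly.

Module scores follow the binned control-gene procedure: genes are ranked
by average expression into 24 bins; each module gene draws 100 control
genes with replacement from its bin (module genes excluded from control
pools, so small matrices do not contaminate their own controls); the
per-cell score is the mean module expression minus the mean control
expression. The shipped panels are cytotoxicity (GZMB, GZMA, GZMH, PRF1,
GNLY, FGFBP2), exhaustion (PDCD1, LAG3, CTLA4, TIGIT, TOX, HAVCR2) and
tissue residency (ITGA1, ITGAE, ZNF683, CD69, IFNG, CCR5).

## The synthetic cohort generator

Every stage is testable without external data through a generator whose
manifest is sufficient to recompute all truth labels, and whose defaults
*are* the study conditions for the package's statistical validation:

* **Clone sizes** follow a Zipf law, exponent 1.2, 200 clonotypes and
  30,000 reads per bulk sample (400 clonotypes in TIL backbones). This
  reproduces the dominance structure of clonal repertoires without
  claiming a measured exponent; the sampled depth sits above the
  10,000-read exclusion threshold. These sizes keep a hundred simulated
  cohorts within minutes of CPU time while leaving every test statistic
  far from its decision boundary.
* **CDR3s** are built as a conserved 4-residue V head, a stochastic
  cysteine-free core, and a conserved 5-residue J tail, lengths 11–19.
* **Planted motifs**: six motifs (widths 4–5, two with one internal
  wildcard) at fixed offsets 5–6, carried by 6%/3% of tumor-sample
  clones and one tenth of that in healthy kidney and PB — the ten-fold
  tumor incidence under which discovery and classification are
  validated. Carrier counts are binomial with a floor of three carriers
  per tumor sample so every planted motif is discoverable under the
  cluster-size filter (audited, not assumed).
* **TIL pairs** share one clone backbone; the pre-REP member boosts its
  top ten clones three-fold (top-clone dominance), and motif carriers
  sit in the high-rank window so carrier mass is highest pre-REP.
  Designated expansions multiply three small clones (pre-REP frequency
  0.02–0.05%) by a uniform 10–20x fold, so their product frequency
  crosses the 0.1% rule; the added mass is balanced by zeroing
  sub-threshold sink clones (all below 0.05%), leaving every
  non-designated clone at an *identical* underlying frequency — a clean
  null under which the Fisher/BH expansion test's error rates are
  meaningful. Setting `rep_carrier_decay < 1` instead models rapid
  expansion favouring non-carrier clones (burden dilution in the
  product); that mode renormalises globally and is used for structural
  checks, not for error-rate calibration.
* **Viral spikes**: three clones per tumor/TIL sample drawn from a
  packaged, clearly synthetic VDJdb-style reference at 0.05–0.2%
  frequency each, identical in both members of a TIL pair.
* **Cells**: 2,000 cells over eight phenotype labels; each planted motif
  is carried by 20–60 cells across a handful of clonotypes and assigned
  its designated phenotype with probability 0.9. Expression is a
  negative-binomial background with per-gene log-normal baselines;
  panel genes are elevated log-normally (mean 3-fold) in their
  designated phenotypes.

What the generator does **not** emulate: the deep singleton tail of real
repertoires (at the default depth no clone samples to one read, so
Chao1's correction term is usually inactive on synthetic data), V/D/J
recombination statistics and generation probabilities, sequencing error,
HLA structure, or batch effects in expression. Passing tests therefore
demonstrate the correctness and calibration of the statistical
machinery under the generator's assumptions, not performance on any
particular patient cohort.

### Scoring discovery against the manifest

A discovered motif is counted as *planted-derived* when the majority of
its carrier TCRs in the pooled tumor cohort are manifest carrier clones.
This matters because discovery legitimately returns sub-patterns and
one-residue scaffold-overhang variants of a planted motif — their
clusters are exactly the planted carriers — and a string-containment
rule would miscount that recovered signal as false discovery. Chance
background motifs draw carriers from the whole repertoire and fail the
majority rule.

## Pipeline and reproducibility

`run_pipeline()` chains filtering, diversity, expansion testing,
per-tissue discovery, classification, pruning, burden and phenotype
stages, writing one TSV per stage plus a JSON provenance record (seed,
thresholds, per-sample totals, package version). All randomness descends
from one integer seed; two runs with the same configuration are
byte-identical, which the test suite asserts on file checksums. Stage
failures abort with the stage name; completed outputs are retained.

The statistical validation suite (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) runs at these problem sizes:
100 simulated discovery cohorts of 20 tumor / 20 healthy / 20 PB samples
for motif recovery; 200 TIL pairs for expansion error rates; 20 cell
tables of 2,000 cells for phenotype concordance; exhaustive Fisher
enumeration for all small-margin tables plus random tables with margins
to 200; and full-pipeline structural and determinism checks.

## Known limitations

* Discovery sensitivity for motifs shared between tumor and comparator
  tissues depends on the comparator cohort's own discovery power; at
  the default comparator incidence the planted motifs usually fall
  below the comparator index's BH threshold and are classified
  tumor-exclusive rather than tumor-enriched. Both statuses count as
  tumor-associated.
* The Wilcoxon normal approximation near the exact/approximate boundary
  can move p-values by a few percent (see above).
* Burden weighting ("proportion of TCRs") is read-weighted by default;
  unique-clonotype weighting is always co-reported because the two can
  differ materially in clonal samples.
* `nt_strict` keying requires nucleotide sequences; tables lacking them
  fail fast rather than silently falling back to amino-acid keys.
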