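#' Motif burden of a repertoire
#'
#' Fraction of a repertoire carried by TCRs bearing at least one motif of a
#' motif set at its allowed offsets ("same location" rule). Reported both
#' read-weighted (the repertoire proportion, default headline number) and
#' unique-clonotype-weighted, together with per-motif contributions (a TCR
#' carrying several motifs contributes to each, so contributions can sum to
#' more than the union fraction).
#'
#' Cohort filters appropriate to the sample's provenance (non-singleton for
#' blood, minimum 100 reads for thin external samples, optional 40,000-read
#' downsampling) are applied by the caller; see [apply_tissue_filters()].
#'
#' @param x A `clonotype_table`.
#' @param motifs A tibble with columns `motif` and `offsets` (list column),
#'   e.g. from [associated_motifs()] or a read motif index.
#' @param params A [motif_params()] bundle (trim convention).
#' @return A one-row tibble of class `motif_burden`: sample metadata,
#'   `fraction_reads`, `fraction_unique`, `n_distinct_motifs` (motifs with at
#'   least one carrier), and a `per_motif` list column of per-motif read
#'   fractions.
#' @export
motif_burden <- function(x, motifs, params = motif_params()) {
  if (is.null(motifs) || nrow(motifs) == 0) {
    abort("motif set is empty", class = "tilmotif_config_error")
  }
  tot_reads <- total_reads(x)
  any_hit <- logical(nrow(x))
  per_motif <- numeric(nrow(motifs))
  names(per_motif) <- motifs$motif
  for (i in seq_len(nrow(motifs))) {
    hit <- motif_matches(x$cdr3_aa, motifs$motif[i], motifs$offsets[[i]],
                         head = params$head, tail = params$tail)
    any_hit <- any_hit | hit
    per_motif[i] <- if (tot_reads == 0) 0 else sum(x$count[hit]) / tot_reads
  }
  bind_cols(
    sample_meta(x)[, c("sample_id", "tissue", "patient_id")],
    tibble(fraction_reads = if (tot_reads == 0) 0
           else sum(x$count[any_hit]) / tot_reads,
           fraction_unique = if (nrow(x) == 0) 0 else mean(any_hit),
           n_distinct_motifs = sum(per_motif > 0),
           per_motif = list(per_motif))
  )
}

#' Apply provenance-appropriate filters before burden quantification
#'
#' Blood samples keep only non-singleton TCRs; thin samples below
#' `min_reads` are rejected (`NULL` returned); deep samples are optionally
#' downsampled to `downsample_to` reads.
#'
#' @param x A `clonotype_table`.
#' @param drop_singletons Remove count-1 TCRs (use for peripheral blood).
#' @param min_reads Minimum reads to keep the sample, or `NULL` to skip.
#' @param downsample_to Target depth, or `NULL` to skip (applied only when
#'   the sample is deeper than the target).
#' @param seed Seed for the downsampling draw.
#' @return A filtered `clonotype_table`, or `NULL` when the sample fails
#'   `min_reads`.
#' @export
apply_tissue_filters <- function(x, drop_singletons = FALSE,
                                 min_reads = NULL, downsample_to = NULL,
                                 seed = NULL) {
  if (drop_singletons) x <- remove_singletons(x)
  if (!is.null(min_reads) && total_reads(x) < min_reads) {
    inform(sprintf("sample %s below %d reads; excluded from burden analysis",
                   attr(x, "sample_id"), min_reads))
    return(NULL)
  }
  if (!is.null(downsample_to) && total_reads(x) > downsample_to) {
    x <- downsample_repertoire(x, downsample_to, seed = seed)
  }
  x
}

#' Compare motif burden between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on the read-weighted burden
#' fractions of two or more groups of samples.
#'
#' @param groups Named list; each element either a tibble of
#'   [motif_burden()] rows or a bare numeric vector of burden fractions.
#' @return A tibble with one row per group pair: medians, direction and
#'   two-sided p.
#' @export
compare_burden <- function(groups) {
  if (length(groups) < 2) {
    abort("need at least two groups", class = "tilmotif_config_error")
  }
  vals <- lapply(groups, function(g) {
    v <- if (is.data.frame(g)) g$fraction_reads else as.numeric(g)
    if (length(v) == 0) {
      abort("groups must be non-empty", class = "tilmotif_config_error")
    }
    v
  })
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    p <- if (all(c(a, b) == c(a, b)[1])) 1
         else suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value)
    tibble(group_a = pr[1], group_b = pr[2],
           median_a = median(a), median_b = median(b),
           higher = if (median(a) == median(b)) "tie"
                    else ifelse(median(a) > median(b), pr[1], pr[2]),
           p_value = p)
  }))
}

#' Burden ratio against a reference fraction
#'
#' E.g. the ratio of tumor-associated-motif burden to the anti-viral TCR
#' read fraction in the same sample.
#' @param burden A [motif_burden()] row or a numeric burden fraction.
#' @param reference_fraction Positive reference fraction (e.g. the annotated
#'   anti-viral read fraction).
#' @return `fraction / reference_fraction`; `NA` (with a warning) when the
#'   reference is zero.
#' @export
burden_ratio <- function(burden, reference_fraction) {
  f <- if (is.data.frame(burden)) burden$fraction_reads else as.numeric(burden)
  if (reference_fraction <= 0) {
    warn("reference fraction is zero; ratio undefined")
    return(NA_real_)
  }
  f / reference_fraction
}
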