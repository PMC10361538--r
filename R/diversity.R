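#' Gini index of clonal inequality
#'
#' Gini coefficient of the clone-frequency distribution: half the mean
#' absolute pairwise difference divided by the mean frequency (equivalently
#' one minus twice the area under the Lorenz curve). 0 for a perfectly even
#' repertoire; values approaching 1 denote domination by few clones. Computed
#' over observed clonotypes only, with no unseen-species correction (the
#' convention of standard repertoire toolkits).
#'
#' @param x A `clonotype_table`, or a numeric vector of counts/frequencies.
#' @return Gini coefficient in `[0, 1)`. A single-clone repertoire returns 0
#'   (degenerate case).
#' @export
gini_index <- function(x) {
  p <- diversity_counts(x)
  n <- length(p)
  if (n == 1) return(0)
  p <- sort(p)
  # G = 2*sum(i*x_i)/(n*sum(x)) - (n+1)/n  for sorted x
  2 * sum(seq_len(n) * p) / (n * sum(p)) - (n + 1) / n
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` over clone frequencies; equals the number of clonotypes
#' for a perfectly even repertoire.
#' @inheritParams gini_index
#' @return Inverse Simpson index, in `[1, n_clonotypes]`.
#' @export
inverse_simpson <- function(x) {
  p <- diversity_counts(x)
  unname(vegan::diversity(p, index = "invsimpson"))
}

#' Shannon entropy of the clone distribution
#' @inheritParams gini_index
#' @return Shannon entropy (natural log), `>= 0`.
#' @export
shannon_entropy <- function(x) {
  p <- diversity_counts(x)
  unname(vegan::diversity(p, index = "shannon"))
}

#' Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` where `F1`/`F2` are the numbers of singleton and
#' doubleton clonotypes; when `F2 = 0` the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used. Requires observed counts
#' (not frequencies) and, unlike the other indices, is not invariant to
#' rescaling counts.
#' @param x A `clonotype_table` or a vector of integer counts.
#' @return Chao1 estimate, `>=` observed richness.
#' @export
chao1 <- function(x) {
  counts <- diversity_counts(x)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Clonality index
#'
#' One minus Pielou evenness: `1 - H / ln(S)` with `H` the Shannon entropy
#' and `S` the observed clonotype count. 0 for a uniform repertoire, 1 in the
#' monoclonal limit. For a single-clone repertoire the index is defined as 1.
#' @inheritParams gini_index
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(x) {
  counts <- diversity_counts(x)
  s <- length(counts)
  if (s == 1) return(1)
  1 - shannon_entropy(counts) / log(s)
}

#' Summarise repertoire diversity
#'
#' One row of all supported indices for a sample; the per-sample unit of the
#' cohort diversity table.
#' @param x A `clonotype_table`.
#' @return A one-row tibble: sample metadata plus `gini`, `inverse_simpson`,
#'   `chao1`, `shannon`, `clonality`, `n_clonotypes`, `total_reads`.
#' @export
diversity_summary <- function(x) {
  bind_cols(sample_meta(x)[, c("sample_id", "tissue", "patient_id")],
            tibble(gini = gini_index(x),
                   inverse_simpson = inverse_simpson(x),
                   chao1 = chao1(x),
                   shannon = shannon_entropy(x),
                   clonality = clonality(x),
                   n_clonotypes = nrow(x),
                   total_reads = total_reads(x)))
}

#' Cohort diversity table
#'
#' Computes [diversity_summary()] for every sample, optionally after
#' downsampling every sample within a tissue group to that group's smallest
#' repertoire (so indices are compared at matched depth).
#'
#' @param tables List of `clonotype_table`s.
#' @param downsample_within_group If `TRUE`, each sample is downsampled to
#'   the minimum total-read count of its tissue group first.
#' @param seed Seed for the downsampling draws.
#' @return A tibble with one row per sample.
#' @export
cohort_diversity <- function(tables, downsample_within_group = FALSE,
                             seed = NULL) {
  if (downsample_within_group) {
    tissues <- vapply(tables, function(t) attr(t, "tissue"), character(1))
    totals <- vapply(tables, total_reads, numeric(1))
    mins <- tapply(totals, tissues, min)
    tables <- lapply(seq_along(tables), function(i) {
      downsample_repertoire(tables[[i]], mins[[tissues[i]]],
                            seed = if (is.null(seed)) NULL else seed + i)
    })
  }
  bind_rows(lapply(tables, diversity_summary))
}

# accept a clonotype_table or a bare positive numeric vector
diversity_counts <- function(x) {
  counts <- if (inherits(x, "clonotype_table")) x$count else x
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0 || any(counts <= 0)) {
    abort("diversity indices require a non-empty vector of positive counts",
          class = "tilmotif_empty_error")
  }
  as.numeric(counts)
}
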