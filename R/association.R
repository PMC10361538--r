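#' Pooled motif frequency in a sample
#'
#' All TCRs carrying the motif (at an allowed offset, under the discovery
#' trim convention) are pooled; the pooled frequency is their summed
#' read-weighted frequency (`weighting = "reads"`, default) or the fraction
#' of unique clonotypes carrying the motif (`"unique"`). Samples without the
#' motif score 0 — zeros are data points, not missing values, in downstream
#' group comparisons.
#'
#' @param x A `clonotype_table`.
#' @param motif Motif string.
#' @param offsets Allowed 1-based start offsets.
#' @param weighting `"reads"` or `"unique"`.
#' @param params A [motif_params()] bundle (trim convention).
#' @return Pooled frequency in `[0, 1]`.
#' @export
pooled_motif_frequency <- function(x, motif, offsets,
                                   weighting = c("reads", "unique"),
                                   params = motif_params()) {
  weighting <- match.arg(weighting)
  if (length(offsets) == 0) {
    abort("motif has no recorded offsets", class = "tilmotif_config_error")
  }
  if (nrow(x) == 0) return(0)
  hit <- motif_matches(x$cdr3_aa, motif, offsets,
                       head = params$head, tail = params$tail)
  if (weighting == "reads") sum(x$count[hit]) / sum(x$count)
  else sum(hit) / nrow(x)
}

# per-sample pooled-frequency matrix: motifs (rows of `index`) x samples
pooled_frequency_matrix <- function(index, samples, weighting = "reads",
                                    params = motif_params()) {
  mat <- matrix(0, nrow = nrow(index), ncol = length(samples),
                dimnames = list(index$motif, NULL))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    tot <- if (weighting == "reads") sum(s$count) else nrow(s)
    if (tot == 0) next
    for (i in seq_len(nrow(index))) {
      hit <- motif_matches(s$cdr3_aa, index$motif[i], index$offsets[[i]],
                           head = params$head, tail = params$tail)
      mat[i, j] <- if (weighting == "reads") sum(s$count[hit]) / tot
                   else sum(hit) / tot
    }
  }
  mat
}

#' Classify motifs as tumor-exclusive or tumor-enriched
#'
#' Motifs discovered in the tumor cohort but absent from every comparator
#' index are *exclusive*. Motifs shared with a comparator index are tested by
#' a two-sided Wilcoxon rank-sum of per-sample pooled frequencies (zeros
#' included) in tumor vs that comparator, Benjamini-Hochberg corrected across
#' motifs within the comparator; a shared motif is *enriched* when, for at
#' least one comparator (default; `rule = "all"` requires every comparator),
#' the adjusted p is below `alpha` and the log2 fold change of the group
#' mean (or median) pooled frequency exceeds `min_log2fc`. Shared motifs
#' failing this are *rejected*. The log2 fold change uses the smallest
#' nonzero pooled frequency in the pool as a pseudocount when a group mean is
#' zero; a motif with zero frequency everywhere is rejected with `log2fc`
#' `NA`.
#'
#' @param tumor_index `motif_index` from the tumor cohort discovery.
#' @param comparator_indexes Named list of `motif_index`es from comparator
#'   cohorts (e.g. healthy kidney, peripheral blood).
#' @param tumor_samples List of tumor `clonotype_table`s.
#' @param comparator_samples Named list (same names as
#'   `comparator_indexes`) of lists of comparator `clonotype_table`s.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_log2fc Minimum log2 fold change (default 1).
#' @param rule `"any"` (either comparator suffices, default) or `"all"`.
#' @param weighting Pooled-frequency weighting (default `"reads"`).
#' @param center `"mean"` (default) or `"median"` group summary for the fold
#'   change.
#' @param params A [motif_params()] bundle.
#' @return A tibble of class `motif_association`: `motif`, `offsets`,
#'   `status` (`exclusive`/`enriched`/`rejected`), `wilcoxon_p`,
#'   `p_adjusted`, `log2fc` (statistics of the best comparator),
#'   `comparator`, plus `tumor_mean` and a `freqs` list column holding the
#'   per-sample pooled frequencies used.
#' @export
classify_motifs <- function(tumor_index, comparator_indexes, tumor_samples,
                            comparator_samples, alpha = 0.05,
                            min_log2fc = 1.0, rule = c("any", "all"),
                            weighting = c("reads", "unique"),
                            center = c("mean", "median"),
                            params = motif_params()) {
  rule <- match.arg(rule)
  weighting <- match.arg(weighting)
  center <- match.arg(center)
  centre_fun <- if (center == "mean") mean else median
  if (length(comparator_indexes) != length(comparator_samples) ||
      !setequal(names(comparator_indexes), names(comparator_samples))) {
    abort("comparator_indexes and comparator_samples must share names",
          class = "tilmotif_config_error")
  }
  if (any(vapply(comparator_samples, length, integer(1)) == 0)) {
    abort("every comparator must have at least one sample",
          class = "tilmotif_config_error")
  }
  if (nrow(tumor_index) == 0) {
    return(structure(tibble(motif = character(0), offsets = list(),
                            status = character(0), wilcoxon_p = numeric(0),
                            p_adjusted = numeric(0), log2fc = numeric(0),
                            comparator = character(0),
                            tumor_mean = numeric(0), freqs = list()),
                     class = c("motif_association", class(tibble()))))
  }
  shared_with <- lapply(comparator_indexes, function(ci)
    tumor_index$motif %in% ci$motif)
  is_shared <- Reduce(`|`, shared_with)

  tumor_freq <- pooled_frequency_matrix(tumor_index, tumor_samples,
                                        weighting, params)
  comp_freq <- lapply(comparator_samples, function(ss)
    pooled_frequency_matrix(tumor_index, ss, weighting, params))

  # Wilcoxon per shared motif per comparator, BH within comparator
  comp_stats <- lapply(names(comparator_indexes), function(nm) {
    rows <- which(shared_with[[nm]])
    if (length(rows) == 0) {
      return(tibble(row = integer(0), comparator = character(0),
                    p = numeric(0), p_adj = numeric(0), log2fc = numeric(0)))
    }
    p <- vapply(rows, function(i) {
      ft <- tumor_freq[i, ]
      fc <- comp_freq[[nm]][i, ]
      if (all(ft == ft[1]) && all(fc == ft[1])) return(1)
      suppressWarnings(wilcox.test(ft, fc, exact = NULL)$p.value)
    }, numeric(1))
    l2 <- vapply(rows, function(i) {
      ft <- centre_fun(tumor_freq[i, ])
      fc <- centre_fun(comp_freq[[nm]][i, ])
      pool <- c(tumor_freq[i, ], comp_freq[[nm]][i, ])
      eps <- suppressWarnings(min(pool[pool > 0]))
      if (!is.finite(eps)) return(NA_real_)
      log2(max(ft, eps) / max(fc, eps))
    }, numeric(1))
    tibble(row = rows, comparator = nm, p = p,
           p_adj = p.adjust(p, method = "BH"), log2fc = l2)
  })
  comp_stats <- bind_rows(comp_stats)

  n_comp <- length(comparator_indexes)
  status <- character(nrow(tumor_index))
  best <- vector("list", nrow(tumor_index))
  for (i in seq_len(nrow(tumor_index))) {
    if (!is_shared[i]) {
      status[i] <- "exclusive"
      next
    }
    st <- comp_stats[comp_stats$row == i, ]
    pass <- !is.na(st$log2fc) & st$p_adj < alpha & st$log2fc > min_log2fc
    n_needed <- if (rule == "any") 1L
                else sum(shared_with_count(shared_with, i))
    status[i] <- if (sum(pass) >= n_needed && nrow(st) > 0) "enriched"
                 else "rejected"
    best[[i]] <- st[order(st$p_adj, -abs(st$log2fc)), ][1, ]
  }
  out <- tibble(
    motif = tumor_index$motif,
    offsets = tumor_index$offsets,
    status = status,
    wilcoxon_p = vapply(best, function(b) if (is.null(b)) NA_real_ else b$p,
                        numeric(1)),
    p_adjusted = vapply(best, function(b) if (is.null(b)) NA_real_
                        else b$p_adj, numeric(1)),
    log2fc = vapply(best, function(b) if (is.null(b)) NA_real_ else b$log2fc,
                    numeric(1)),
    comparator = vapply(best, function(b) if (is.null(b)) NA_character_
                        else b$comparator, character(1)),
    tumor_mean = apply(tumor_freq, 1, centre_fun),
    freqs = lapply(seq_len(nrow(tumor_index)), function(i)
      c(list(tumor = tumor_freq[i, ]),
        lapply(comp_freq, function(m) m[i, ])))
  )
  # degenerate all-zero motifs cannot be enriched
  all_zero <- out$tumor_mean == 0 &
    vapply(seq_len(nrow(out)), function(i)
      all(vapply(comp_freq, function(m) all(m[i, ] == 0), logical(1))),
      logical(1))
  out$status[out$status == "enriched" & all_zero] <- "rejected"
  structure(out, class = c("motif_association", class(out)))
}

shared_with_count <- function(shared_with, i) {
  vapply(shared_with, function(v) v[i], logical(1))
}

#' Prune motif associations against control sets
#'
#' Any motif whose string appears in a control motif set (e.g. motifs
#' discovered in unrelated validation cohorts, or viral-epitope motif lists)
#' is marked `pruned`, with the responsible set names recorded in
#' `pruned_by`. The survivors with status `exclusive` or `enriched`
#' constitute the tumor-associated motif set. Pruning is idempotent and
#' order-independent across control sets.
#'
#' @param associations A `motif_association` tibble from [classify_motifs()].
#' @param control_sets Named list of character vectors of motif strings.
#' @return The associations with updated `status` and a `pruned_by` list
#'   column.
#' @export
prune_against_controls <- function(associations, control_sets = list()) {
  out <- associations
  if (!"pruned_by" %in% names(out)) {
    out$pruned_by <- replicate(nrow(out), character(0), simplify = FALSE)
  }
  if (length(control_sets) == 0 || nrow(out) == 0) return(out)
  for (i in seq_len(nrow(out))) {
    hits <- names(control_sets)[vapply(control_sets, function(s)
      out$motif[i] %in% s, logical(1))]
    if (length(hits) > 0) {
      out$status[i] <- "pruned"
      out$pruned_by[[i]] <- sort(union(out$pruned_by[[i]], hits))
    }
  }
  out
}

#' Extract the tumor-associated motif set
#'
#' Convenience accessor: the exclusive and enriched motifs surviving
#' pruning, as a tibble of `motif` and `offsets` ready for burden
#' quantification.
#' @param associations A `motif_association` tibble.
#' @return Tibble with `motif`, `offsets`, `status`.
#' @export
associated_motifs <- function(associations) {
  as_tibble(associations)[associations$status %in% c("exclusive", "enriched"),
                          c("motif", "offsets", "status")]
}
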