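#' Assign dominant immunophenotypes to motifs from single-cell data
#'
#' For each motif, the supporting cells are those whose CDR3-beta carries the
#' motif at an allowed offset. Motifs with at least `min_cells` supporting
#' cells (default 5) receive a call: for every phenotype label the 2x2 table
#' (motif x phenotype over all phenotyped cells) gives an odds ratio
#' (Haldane-Anscombe +0.5 on all cells when any cell is zero, so the argmax
#' stays defined), and the phenotype with the largest odds ratio is the
#' dominant phenotype. Ties are broken by the larger supporting-cell count in
#' the phenotype, then lexicographically.
#'
#' @param cells A data frame with columns `cell_id`, `cdr3_aa` and
#'   `phenotype` (non-missing for every scored cell).
#' @param motifs A tibble with columns `motif` and `offsets` (list column).
#' @param min_cells Minimum supporting cells for a call (default 5).
#' @param params A [motif_params()] bundle (trim convention for matching).
#' @return A tibble of class `motif_phenotype`: `motif`,
#'   `n_supporting_cells`, `dominant_phenotype`, `dominant_or`, and a
#'   `per_phenotype` list column of per-phenotype 2x2 counts and odds
#'   ratios. Motifs below `min_cells` are absent; their ids are kept in the
#'   `skipped` attribute.
#' @export
assign_motif_phenotypes <- function(cells, motifs, min_cells = 5,
                                    params = motif_params()) {
  cells <- as_tibble(cells)
  need <- c("cell_id", "cdr3_aa", "phenotype")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmotif_format_error")
  }
  if (anyDuplicated(cells$cell_id)) {
    abort("cell_id must be unique", class = "tilmotif_invariant_error")
  }
  if (any(is.na(cells$phenotype))) {
    abort("phenotype labels must be non-missing for scored cells",
          class = "tilmotif_invariant_error")
  }
  phenos <- sort(unique(cells$phenotype))
  n_total <- nrow(cells)
  calls <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(motifs))) {
    hit <- motif_matches(cells$cdr3_aa, motifs$motif[i], motifs$offsets[[i]],
                         head = params$head, tail = params$tail)
    n_sup <- sum(hit)
    if (n_sup < min_cells) {
      skipped <- c(skipped, motifs$motif[i])
      next
    }
    per <- bind_rows(lapply(phenos, function(p) {
      in_p <- cells$phenotype == p
      n11 <- sum(hit & in_p)
      n10 <- sum(hit & !in_p)
      n01 <- sum(!hit & in_p)
      n00 <- n_total - n11 - n10 - n01
      tibble(phenotype = p, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             odds_ratio = haldane_or(n11, n10, n01, n00))
    }))
    ord <- order(-per$odds_ratio, -per$n11, per$phenotype)
    top <- per[ord[1], ]
    calls[[length(calls) + 1]] <- tibble(
      motif = motifs$motif[i],
      n_supporting_cells = n_sup,
      dominant_phenotype = top$phenotype,
      dominant_or = top$odds_ratio,
      per_phenotype = list(per))
  }
  out <- if (length(calls) > 0) bind_rows(calls) else
    tibble(motif = character(0), n_supporting_cells = integer(0),
           dominant_phenotype = character(0), dominant_or = numeric(0),
           per_phenotype = list())
  structure(out, class = c("motif_phenotype", class(out)), skipped = skipped)
}

#' Gene-module score with expression-matched controls
#'
#' The binned control-gene scoring procedure used for cytotoxicity,
#' exhaustion and tissue-residency signatures: genes are binned into
#' `n_bins` (default 24) expression bins by their average (log-normalised)
#' expression over all cells; for each module gene, `n_control` control
#' genes (default 100) are sampled with replacement from the same bin
#' (excluding the module genes themselves, so small matrices do not
#' contaminate their own controls); the per-cell score is the mean
#' expression of the module genes minus the mean expression of the pooled
#' control genes. Deterministic given `seed`.
#'
#' @param expr Numeric matrix, genes x cells (log-normalised), with gene row
#'   names.
#' @param genes Character vector of module genes. Genes absent from `expr`
#'   are dropped with a warning; an all-absent module is an error.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_control Control genes sampled per module gene (default 100).
#' @param seed Seed for the control draw; `NULL` uses current RNG state.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, genes, n_bins = 24, n_control = 100,
                         seed = NULL) {
  if (is.null(rownames(expr))) {
    abort("expression matrix must have gene row names",
          class = "tilmotif_format_error")
  }
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    abort("no module gene present in the expression matrix",
          class = "tilmotif_config_error")
  }
  if (length(present) < length(genes)) {
    warn(sprintf("%d module gene(s) absent and dropped: %s",
                 length(genes) - length(present),
                 paste(setdiff(genes, present), collapse = ", ")))
  }
  if (nrow(expr) < n_bins) {
    abort(sprintf("need at least n_bins = %d genes, have %d",
                  n_bins, nrow(expr)), class = "tilmotif_config_error")
  }
  avg <- rowMeans(expr)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- rownames(expr)
  draw <- function() {
    unlist(lapply(present, function(g) {
      pool <- setdiff(rownames(expr)[bins == bins[[g]]], present)
      if (length(pool) == 0) pool <- rownames(expr)[bins == bins[[g]]]
      sample(pool, n_control, replace = TRUE)
    }), use.names = FALSE)
  }
  ctrl <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  module_mean <- if (length(present) == 1) expr[present, ]
                 else colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  module_mean - ctrl_mean
}

#' Default signature gene panels
#'
#' The three module-gene panels scored on tumor-infiltrating T cells:
#' cytotoxicity (`GZMB, GZMA, GZMH, PRF1, GNLY, FGFBP2`), exhaustion
#' (`PDCD1, LAG3, CTLA4, TIGIT, TOX, HAVCR2`) and tissue residency
#' (`ITGA1, ITGAE, ZNF683, CD69, IFNG, CCR5`).
#' @return Named list of character vectors.
#' @export
signature_panels <- function() {
  list(
    cytotoxicity = c("GZMB", "GZMA", "GZMH", "PRF1", "GNLY", "FGFBP2"),
    exhaustion = c("PDCD1", "LAG3", "CTLA4", "TIGIT", "TOX", "HAVCR2"),
    tissue_resident = c("ITGA1", "ITGAE", "ZNF683", "CD69", "IFNG", "CCR5")
  )
}
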