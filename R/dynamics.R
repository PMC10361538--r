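#' Track top clonotypes across samples
#'
#' Takes the `n` most abundant clonotypes of a reference repertoire (ties
#' broken lexicographically by key) and reports their frequency in every
#' target repertoire (0 when absent), plus a cumulative-frequency row. This
#' is the operation behind tracking the top expansion-product clonotypes back
#' into the tumor and pre-expansion cultures.
#'
#' @param reference A `clonotype_table` supplying the top clones.
#' @param targets Named list of `clonotype_table`s to track into.
#' @param n Number of top reference clonotypes (default 20). If `n` exceeds
#'   the repertoire size, all clones are used with a warning.
#' @param mode Clonotype keying mode (default `"aa"`: amino-acid identity, the
#'   granularity used for cross-sample tracking).
#' @return A tibble: `key`, `reference` frequency, one column per target, and
#'   a final `TOTAL` row of column sums.
#' @export
track_top_clonotypes <- function(reference, targets, n = 20, mode = "aa") {
  if (n > nrow(reference)) {
    warn(sprintf("n = %d exceeds repertoire size %d; using all clonotypes",
                 n, nrow(reference)))
    n <- nrow(reference)
  }
  ref <- tibble(key = clonotype_keys(reference, mode),
                freq = clone_frequencies(reference)) |>
    group_by(.data$key) |> summarise(freq = sum(.data$freq), .groups = "drop") |>
    arrange(desc(.data$freq), .data$key) |>
    head(n)
  if (is.null(names(targets))) {
    names(targets) <- vapply(targets, function(t) attr(t, "sample_id"),
                             character(1))
  }
  out <- tibble(key = ref$key, reference = ref$freq)
  for (nm in names(targets)) {
    tg <- tibble(key = clonotype_keys(targets[[nm]], mode),
                 freq = clone_frequencies(targets[[nm]])) |>
      group_by(.data$key) |> summarise(freq = sum(.data$freq), .groups = "drop")
    out[[nm]] <- tg$freq[match(out$key, tg$key)]
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  totals <- out |> summarise(across(where(is.numeric), sum))
  bind_rows(out, bind_cols(tibble(key = "TOTAL"), totals))
}

#' Repertoire overlap and rank correlation
#'
#' Inner-joins two repertoires on the clonotype key and reports shared/unique
#' clone counts plus the Spearman correlation of log10 clone frequencies of
#' the shared clones (the log transform leaves ranks, hence rho, unchanged;
#' it matches how overlap plots are drawn). With fewer than 3 shared clones
#' the correlation is undefined (`NA`).
#'
#' @param a,b `clonotype_table`s.
#' @param mode Clonotype keying mode (default `"aa_vj"`).
#' @return A list: `shared` (tibble of key, freq_a, freq_b), `n_shared`,
#'   `n_only_a`, `n_only_b`, `spearman_rho`, `spearman_p`.
#' @export
repertoire_overlap <- function(a, b, mode = "aa_vj") {
  fa <- tibble(key = clonotype_keys(a, mode), freq_a = clone_frequencies(a)) |>
    group_by(.data$key) |> summarise(freq_a = sum(.data$freq_a), .groups = "drop")
  fb <- tibble(key = clonotype_keys(b, mode), freq_b = clone_frequencies(b)) |>
    group_by(.data$key) |> summarise(freq_b = sum(.data$freq_b), .groups = "drop")
  shared <- inner_join(fa, fb, by = "key")
  if (nrow(shared) >= 3) {
    ct <- suppressWarnings(
      cor.test(log10(shared$freq_a), log10(shared$freq_b),
               method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    pval <- ct$p.value
  } else {
    rho <- NA_real_
    pval <- NA_real_
  }
  list(shared = shared,
       n_shared = nrow(shared),
       n_only_a = nrow(fa) - nrow(shared),
       n_only_b = nrow(fb) - nrow(shared),
       spearman_rho = rho,
       spearman_p = pval)
}

#' Test clonal expansion between two repertoires
#'
#' For every clonotype present in either sample (the union universe), builds
#' the 2x2 table `[count_a, total_a - count_a; count_b, total_b - count_b]`
#' and applies the two-sided Fisher exact test, with Benjamini-Hochberg
#' correction across all tested clonotypes. A clonotype is called expanded
#' when its adjusted p-value is below `alpha` *and* its frequency reaches
#' `min_freq` (0.1% by default) in at least one of the two samples; the
#' direction is the sample with the higher frequency. Intended for full
#' (non-downsampled) repertoires.
#'
#' @param a,b `clonotype_table`s (e.g. pre-expansion and post-expansion TIL).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_freq Minimum frequency in either sample (default 0.001; the
#'   comparison is `>=`).
#' @param mode Clonotype keying mode (default `"aa_vj"`).
#' @return A tibble with one row per clonotype: counts, totals, frequencies,
#'   `odds_ratio`, `p_value`, `p_adjusted`, `expanded_in` (`"a"`, `"b"` or
#'   `"none"`).
#' @export
test_expansion <- function(a, b, alpha = 0.05, min_freq = 0.001,
                           mode = "aa_vj") {
  total_a <- total_reads(a)
  total_b <- total_reads(b)
  if (total_a == 0 || total_b == 0) {
    abort("both samples must contain reads", class = "tilmotif_empty_error")
  }
  ca <- tibble(key = clonotype_keys(a, mode), count_a = a$count) |>
    group_by(.data$key) |> summarise(count_a = sum(.data$count_a), .groups = "drop")
  cb <- tibble(key = clonotype_keys(b, mode), count_b = b$count) |>
    group_by(.data$key) |> summarise(count_b = sum(.data$count_b), .groups = "drop")
  res <- full_join(ca, cb, by = "key") |>
    mutate(count_a = ifelse(is.na(.data$count_a), 0L, .data$count_a),
           count_b = ifelse(is.na(.data$count_b), 0L, .data$count_b),
           total_a = total_a, total_b = total_b,
           freq_a = .data$count_a / total_a,
           freq_b = .data$count_b / total_b)
  res$p_value <- fisher_exact(res$count_a, res$total_a - res$count_a,
                              res$count_b, res$total_b - res$count_b)
  res$odds_ratio <- haldane_or(res$count_a, res$total_a - res$count_a,
                               res$count_b, res$total_b - res$count_b)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$expanded_in <- ifelse(
    res$p_adjusted < alpha & pmax(res$freq_a, res$freq_b) >= min_freq,
    ifelse(res$freq_a > res$freq_b, "a", "b"),
    "none")
  arrange(res, .data$p_adjusted, .data$key)
}

# odds ratio with Haldane-Anscombe +0.5 applied when any cell is zero
haldane_or <- function(a, b, c, d) {
  z <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  (a * d) / (b * c)
}

#' Annotate clonotypes against a reference TCR table
#'
#' Exact-match join of repertoire clonotypes to an epitope-annotated
#' reference (a VDJdb-style TSV with columns `cdr3`, `v.segm`,
#' `antigen.epitope`, `antigen.species`), used e.g. to mark virus-specific
#' clones. Matching defaults to CDR3aa + V gene with alleles stripped
#' (truncation at `*`).
#'
#' @param x A `clonotype_table`.
#' @param reference A data frame or TSV path with the reference TCRs.
#' @param fields Columns used for matching: subset of `c("cdr3", "v")`.
#' @return A list: `hits` (tibble of matched clonotypes with epitope labels)
#'   and `annotated_read_fraction` (fraction of sample reads carried by
#'   matched clonotypes).
#' @export
annotate_against_reference <- function(x, reference, fields = c("cdr3", "v")) {
  if (is.character(reference) && length(reference) == 1) {
    reference <- readr::read_tsv(reference, col_types = readr::cols(),
                                 progress = FALSE)
  }
  reference <- as_tibble(reference)
  bad <- setdiff(fields, c("cdr3", "v"))
  if (length(bad) > 0) {
    abort(paste0("unknown match field(s): ", paste(bad, collapse = ", ")),
          class = "tilmotif_config_error")
  }
  need <- c(cdr3 = "cdr3", v = "v.segm")[fields]
  missing <- setdiff(unname(need), names(reference))
  if (length(missing) > 0) {
    abort(paste0("reference lacks column(s): ", paste(missing, collapse = ", ")),
          class = "tilmotif_config_error")
  }
  strip_allele <- function(v) sub("\\*.*$", "", v)
  make_key <- function(cdr3, v) {
    parts <- list()
    if ("cdr3" %in% fields) parts <- c(parts, list(cdr3))
    if ("v" %in% fields) parts <- c(parts, list(strip_allele(v)))
    do.call(paste, c(parts, sep = "|"))
  }
  ref_key <- make_key(reference$cdr3,
                      if ("v.segm" %in% names(reference)) reference$v.segm
                      else "")
  sample_key <- make_key(x$cdr3_aa, x$v_gene)
  idx <- match(sample_key, ref_key)
  hit_rows <- which(!is.na(idx))
  hits <- tibble(
    key = clonotype_keys(x, "aa_vj")[hit_rows],
    cdr3_aa = x$cdr3_aa[hit_rows],
    v_gene = x$v_gene[hit_rows],
    count = x$count[hit_rows],
    reference_row = idx[hit_rows],
    epitope = if ("antigen.epitope" %in% names(reference))
      reference$antigen.epitope[idx[hit_rows]] else NA_character_,
    species = if ("antigen.species" %in% names(reference))
      reference$antigen.species[idx[hit_rows]] else NA_character_)
  list(hits = hits,
       annotated_read_fraction = if (total_reads(x) == 0) 0
       else sum(hits$count) / total_reads(x))
}
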