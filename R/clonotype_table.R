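#' Construct a clonotype table
#'
#' A clonotype table is the unit repertoire container: one row per unique
#' TCR-beta rearrangement of a single sample, carrying the CDR3 nucleotide and
#' amino-acid sequence, V/J gene calls, a template/read count and a productive
#' flag, plus sample-level metadata (sample id, tissue compartment, patient).
#'
#' Invariants enforced by [validate_clonotype_table()]: retained rows have
#' `count >= 1`; productive rows have a non-empty `cdr3_aa` free of `*`;
#' frequencies (`count / sum(count)`) sum to one.
#'
#' @param clonotypes A data frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `count`, `productive`. Missing `cdr3_nt` is allowed (filled with
#'   `NA`) unless nucleotide-strict keying is requested later.
#' @param sample_id Sample identifier string.
#' @param tissue One of `r paste(TISSUES, collapse = ", ")`.
#' @param patient_id Patient identifier string.
#' @return A tibble of class `clonotype_table` with metadata attributes.
#' @examples
#' tab <- clonotype_table(
#'   data.frame(cdr3_aa = c("CASSLAPGATNEKLFF", "CASSQDRGRYGYTF"),
#'              v_gene = "TRBV5-1", j_gene = "TRBJ1-4",
#'              count = c(10, 2), productive = TRUE),
#'   sample_id = "s1", tissue = "tumor", patient_id = "p1")
#' total_reads(tab)
#' @export
clonotype_table <- function(clonotypes, sample_id, tissue = "other",
                            patient_id = NA_character_) {
  tissue <- match.arg(tissue, TISSUES)
  df <- as_tibble(clonotypes)
  if (!"cdr3_nt" %in% names(df)) df$cdr3_nt <- NA_character_
  if (!"productive" %in% names(df)) df$productive <- TRUE
  required <- c("cdr3_aa", "v_gene", "j_gene", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("clonotype table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmotif_format_error")
  }
  df <- df[, c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "count", "productive")]
  df$count <- as.integer(df$count)
  out <- structure(df,
                   class = c("clonotype_table", class(tibble())),
                   sample_id = as.character(sample_id),
                   tissue = tissue,
                   patient_id = as.character(patient_id))
  validate_clonotype_table(out)
}

#' Validate clonotype-table invariants
#'
#' @param x A `clonotype_table`.
#' @return `x`, invisibly unchanged, or an error describing the violated
#'   invariant.
#' @export
validate_clonotype_table <- function(x) {
  stopifnot(inherits(x, "clonotype_table"))
  if (nrow(x) > 0) {
    if (any(is.na(x$count)) || any(x$count < 1)) {
      abort("retained clonotype rows must have count >= 1",
            class = "tilmotif_invariant_error")
    }
    bad <- x$productive & (grepl("*", x$cdr3_aa, fixed = TRUE) |
                             is.na(x$cdr3_aa) | nchar(x$cdr3_aa) == 0)
    if (any(bad)) {
      abort("productive rows must have a non-empty cdr3_aa without '*'",
            class = "tilmotif_invariant_error")
    }
  }
  x
}

# rebuild a clonotype_table from a plain tibble, keeping metadata of `template`
restore_table <- function(df, template) {
  structure(as_tibble(df),
            class = c("clonotype_table", class(tibble())),
            sample_id = attr(template, "sample_id"),
            tissue = attr(template, "tissue"),
            patient_id = attr(template, "patient_id"),
            filter_log = attr(template, "filter_log"))
}

#' Sample metadata of a clonotype table
#' @param x A `clonotype_table`.
#' @return A one-row tibble with `sample_id`, `tissue`, `patient_id`,
#'   `n_clonotypes` and `total_reads`.
#' @export
sample_meta <- function(x) {
  tibble(sample_id = attr(x, "sample_id"),
         tissue = attr(x, "tissue"),
         patient_id = attr(x, "patient_id"),
         n_clonotypes = nrow(x),
         total_reads = total_reads(x))
}

#' Total reads (templates) in a repertoire
#' @param x A `clonotype_table`.
#' @return Integer scalar; 0 for an empty table.
#' @export
total_reads <- function(x) {
  if (nrow(x) == 0) return(0L)
  sum(x$count)
}

#' Clone frequencies
#'
#' Read-weighted frequencies `count / sum(count)`; sums to one within 1e-9.
#' @param x A `clonotype_table`.
#' @return Numeric vector aligned with the rows of `x`.
#' @export
clone_frequencies <- function(x) {
  if (nrow(x) == 0) return(numeric(0))
  x$count / sum(x$count)
}

#' Clonotype keys under a keying mode
#'
#' Three granularities are used by different analyses: `"aa"` (CDR3
#' amino-acid sequence only; used for cross-sample clonotype tracking),
#' `"aa_vj"` (CDR3aa plus V and J gene; the default for bulk overlap and
#' expansion analyses) and `"nt_strict"` (exact CDR3 nucleotide sequence; the
#' strict clonotype definition used when joining bulk data to single-cell
#' clonotypes).
#'
#' @param x A `clonotype_table`.
#' @param mode One of `"aa"`, `"aa_vj"`, `"nt_strict"`.
#' @return Character vector of keys, one per row.
#' @export
clonotype_keys <- function(x, mode = c("aa_vj", "aa", "nt_strict")) {
  mode <- match.arg(mode)
  switch(mode,
    aa = x$cdr3_aa,
    aa_vj = paste(x$cdr3_aa, x$v_gene, x$j_gene, sep = "|"),
    nt_strict = {
      if (any(is.na(x$cdr3_nt))) {
        abort("nt_strict keying requires cdr3_nt for every row",
              class = "tilmotif_invariant_error")
      }
      x$cdr3_nt
    })
}

#' Collapse rows sharing a clonotype key
#'
#' Sums counts over rows identical under the keying mode; the first row's
#' sequence/gene fields are retained per key.
#' @inheritParams clonotype_keys
#' @return A `clonotype_table` with unique keys.
#' @export
collapse_by_key <- function(x, mode = c("aa_vj", "aa", "nt_strict")) {
  mode <- match.arg(mode)
  if (nrow(x) == 0) return(x)
  key <- clonotype_keys(x, mode)
  if (!anyDuplicated(key)) return(x)
  df <- as_tibble(x)
  df$.key <- key
  df <- df |>
    group_by(.data$.key) |>
    summarise(cdr3_nt = first(.data$cdr3_nt),
              cdr3_aa = first(.data$cdr3_aa),
              v_gene = first(.data$v_gene),
              j_gene = first(.data$j_gene),
              count = sum(.data$count),
              productive = first(.data$productive),
              .groups = "drop") |>
    select(-any_of(".key")) |>
    arrange(desc(.data$count), .data$cdr3_aa)
  restore_table(df, x)
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> sample %s (%s, patient %s): %d clonotypes, %d reads\n",
              attr(x, "sample_id"), attr(x, "tissue"), attr(x, "patient_id"),
              nrow(x), total_reads(x)))
  NextMethod()
}
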