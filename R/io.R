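# Dialect column maps. "simple_tsv" is the package's own documented format;
# "airr" follows the AIRR Rearrangement schema names; "immunoseq" follows the
# immunoSEQ v2 export names (sequenceStatus == "In" marks productive).
DIALECTS <- list(
  simple_tsv = c(cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3_aa", v_gene = "v_gene",
                 j_gene = "j_gene", count = "count", productive = "productive"),
  airr = c(cdr3_nt = "junction", cdr3_aa = "junction_aa", v_gene = "v_call",
           j_gene = "j_call", count = "duplicate_count",
           productive = "productive"),
  immunoseq = c(cdr3_nt = "nucleotide", cdr3_aa = "aminoAcid",
                v_gene = "vGeneName", j_gene = "jGeneName", count = "count",
                productive = "sequenceStatus")
)

#' Read a clonotype table from TSV
#'
#' Parses one repertoire sample from a tab-separated file in one of three
#' dialects and validates it. Malformed rows (missing CDR3aa, non-positive or
#' missing count) are dropped with a warning and recorded in the table's
#' `filter_log` attribute, since real repertoire exports routinely contain
#' such rows. `"reads"` and `"templates"` are treated as one count column.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"simple_tsv"`, `"airr"`, `"immunoseq"`.
#' @param sample_id,tissue,patient_id Sample metadata (not stored in the file
#'   body). `sample_id` defaults to the file name without extension.
#' @return A [clonotype_table()].
#' @export
read_clonotype_table <- function(path,
                                 dialect = c("simple_tsv", "airr", "immunoseq"),
                                 sample_id = NULL, tissue = "other",
                                 patient_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tilmotif_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("empty clonotype file: ", path),
          class = "tilmotif_empty_error")
  }
  map <- DIALECTS[[dialect]]
  missing <- setdiff(unname(map[c("cdr3_aa", "v_gene", "j_gene", "count")]),
                     names(raw))
  if (length(missing) > 0) {
    abort(paste0("dialect '", dialect, "' requires column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmotif_format_error")
  }
  df <- tibble(
    cdr3_nt = if (map[["cdr3_nt"]] %in% names(raw))
      raw[[map[["cdr3_nt"]]]] else NA_character_,
    cdr3_aa = raw[[map[["cdr3_aa"]]]],
    v_gene = raw[[map[["v_gene"]]]],
    j_gene = raw[[map[["j_gene"]]]],
    count = suppressWarnings(as.integer(raw[[map[["count"]]]])),
    productive = if (map[["productive"]] %in% names(raw)) {
      if (dialect == "immunoseq") raw[[map[["productive"]]]] == "In"
      else toupper(raw[[map[["productive"]]]]) %in% c("T", "TRUE", "1")
    } else TRUE
  )
  ok <- !is.na(df$cdr3_aa) & nchar(df$cdr3_aa) > 0 &
    !is.na(df$count) & df$count >= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("%d malformed row(s) dropped while reading %s",
                 n_dropped, basename(path)))
  }
  out <- clonotype_table(df[ok, ],
                         sample_id = sample_id %||%
                           sub("\\.[^.]*$", "", basename(path)),
                         tissue = tissue, patient_id = patient_id)
  attr(out, "filter_log") <- list(read = list(path = path, dialect = dialect,
                                              n_rows = nrow(raw),
                                              n_dropped = n_dropped))
  out
}

#' Write a clonotype table to TSV
#'
#' Inverse of [read_clonotype_table()]: `read(write(x))` reproduces `x` for
#' every dialect.
#'
#' @param x A `clonotype_table`.
#' @param path Output file path.
#' @param dialect One of `"simple_tsv"`, `"airr"`, `"immunoseq"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(x, path,
                                  dialect = c("simple_tsv", "airr",
                                              "immunoseq")) {
  dialect <- match.arg(dialect)
  map <- DIALECTS[[dialect]]
  out <- tibble(a = x$cdr3_nt, b = x$cdr3_aa, c = x$v_gene, d = x$j_gene,
                e = x$count,
                f = if (dialect == "immunoseq")
                  ifelse(x$productive, "In", "Out")
                else ifelse(x$productive, "T", "F"))
  names(out) <- unname(map[c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
                             "count", "productive")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep only productive clonotypes
#'
#' Removes non-functional (out-of-frame / stop-containing) rearrangements;
#' only productive, in-frame TCRs enter downstream analyses. Idempotent.
#'
#' @param x A `clonotype_table`.
#' @return A `clonotype_table` with only productive rows; warns if the result
#'   is empty.
#' @export
filter_productive <- function(x) {
  validate_clonotype_table(x)
  out <- restore_table(as_tibble(x)[x$productive, ], x)
  if (nrow(out) == 0 && nrow(x) > 0) {
    warn(sprintf("sample %s: no productive clonotypes remain",
                 attr(x, "sample_id")))
  }
  log_filter(out, "productive", nrow(x) - nrow(out))
}

#' Exclude shallow samples
#'
#' Drops repertoires sequenced below a minimum read depth; samples with fewer
#' than 10,000 reads are excluded by default.
#'
#' @param tables A list of `clonotype_table`s.
#' @param min_reads Minimum total reads to retain a sample (default 10000).
#' @return The retained sublist; exclusions are reported with their sample id.
#' @export
exclude_small_samples <- function(tables, min_reads = 10000) {
  stopifnot(min_reads >= 1)
  if (length(tables) == 0) return(tables)
  totals <- vapply(tables, total_reads, numeric(1))
  drop <- totals < min_reads
  if (any(drop)) {
    ids <- vapply(tables[drop], function(t) attr(t, "sample_id"), character(1))
    inform(sprintf("excluded %d sample(s) below %d reads: %s",
                   sum(drop), min_reads, paste(ids, collapse = ", ")))
  }
  tables[!drop]
}

#' Remove singleton clonotypes
#'
#' A singleton is a TCR supported by exactly one read; blood-sample motif
#' quantification uses only non-singleton TCRs. Idempotent.
#'
#' @param x A `clonotype_table`.
#' @return A `clonotype_table` without count-1 rows; warns if empty.
#' @export
remove_singletons <- function(x) {
  out <- restore_table(as_tibble(x)[x$count > 1, ], x)
  if (nrow(out) == 0 && nrow(x) > 0) {
    warn(sprintf("sample %s: all clonotypes are singletons",
                 attr(x, "sample_id")))
  }
  log_filter(out, "singletons", nrow(x) - nrow(out))
}

#' Downsample a repertoire to a fixed read depth
#'
#' Draws `target_reads` reads without replacement from the repertoire's read
#' pool (a multivariate hypergeometric subsample, realised by sequential
#' conditional [stats::rhyper()] draws). Clonotypes reduced to zero reads are
#' dropped. Deterministic given `seed`. Upsampling is refused.
#'
#' @param x A `clonotype_table`.
#' @param target_reads Number of reads to keep; must not exceed
#'   `total_reads(x)`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `clonotype_table` whose counts sum to exactly `target_reads`.
#' @export
downsample_repertoire <- function(x, target_reads, seed = NULL) {
  n_total <- total_reads(x)
  if (target_reads > n_total) {
    abort(sprintf("target_reads (%d) exceeds total reads (%d); no upsampling",
                  target_reads, n_total),
          class = "tilmotif_downsample_error")
  }
  if (target_reads == n_total) return(x)
  draw <- function() {
    counts <- x$count
    kept <- integer(length(counts))
    remaining <- n_total
    to_draw <- as.integer(target_reads)
    for (i in seq_along(counts)) {
      if (to_draw == 0) break
      remaining <- remaining - counts[i]
      kept[i] <- rhyper(1, counts[i], remaining, to_draw)
      to_draw <- to_draw - kept[i]
    }
    kept
  }
  kept <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  df <- as_tibble(x)
  df$count <- kept
  log_filter(restore_table(df[kept > 0, ], x), "downsample",
             sum(kept == 0))
}

# append an entry to the filter_log attribute
log_filter <- function(x, stage, n_dropped) {
  log <- attr(x, "filter_log") %||% list()
  log[[stage]] <- list(n_dropped = n_dropped, n_after = nrow(x))
  attr(x, "filter_log") <- log
  x
}

#' Write per-sample filter logs as JSON
#'
#' @param tables A list of `clonotype_table`s that have passed through the
#'   filter chain.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(tables, path) {
  logs <- lapply(tables, function(t) attr(t, "filter_log") %||% list())
  names(logs) <- vapply(tables, function(t) attr(t, "sample_id"), character(1))
  jsonlite::write_json(logs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
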