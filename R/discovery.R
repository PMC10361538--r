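# Unique TCRs of a pooled cohort: distinct (cdr3_aa, v_gene) pairs, the
# granularity at which "different TCRs" are counted for cluster sizes.
pool_unique_tcrs <- function(tables) {
  dt <- data.table::rbindlist(lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    data.table::data.table(cdr3_aa = t$cdr3_aa, v_gene = t$v_gene,
                           sample = i)
  }))
  dt
}

#' Build a motif reference index from a background repertoire
#'
#' Enumerates all local motifs of a (naive) background repertoire once, so
#' repeated discovery runs against the same background do not re-enumerate
#' it. The background is user-replaceable; [default_reference_repertoire()]
#' supplies a deterministic synthetic naive background.
#'
#' @param reference A `clonotype_table`, or a list of them, pooled to unique
#'   TCRs (distinct CDR3aa + V pairs).
#' @param params A [motif_params()] bundle; must match the discovery run.
#' @return A list of class `motif_reference`: `counts` (data.table of motif,
#'   n_tcr), `n_tcr` total unique TCRs, `params`.
#' @export
build_motif_reference <- function(reference, params = motif_params()) {
  if (inherits(reference, "clonotype_table")) reference <- list(reference)
  pool <- unique(pool_unique_tcrs(reference)[, c("cdr3_aa", "v_gene")])
  cores <- trim_cores(pool$cdr3_aa, params$head, params$tail)
  keep <- !is.na(cores)
  counts <- count_motif_carriers(cores[keep], params)
  structure(list(code = counts$code, n_tcr_by_code = counts$n,
                 n_tcr = sum(keep), params = params),
            class = "motif_reference")
}

# distinct-carrier counts per integer motif code
count_motif_carriers <- function(cores, params) {
  enum <- enumerate_motifs_codes(cores, params)
  if (length(enum$code) == 0) return(list(code = numeric(0), n = integer(0)))
  mult <- 2^ceiling(log2(length(cores) + 1))
  ucode <- floor(unique(enum$code * mult + enum$idx) / mult)
  s <- sort.int(ucode, method = "radix")
  r <- rle(s)
  list(code = r$values, n = r$lengths)
}

#' Synthetic naive background repertoire
#'
#' A deterministic, seed-fixed naive repertoire (no planted motifs, flat
#' Zipf clone sizes) used as the default enrichment background for motif
#' discovery. Generated in code rather than shipped as data; regenerating
#' with the same parameters is bit-reproducible.
#'
#' @param n_clones Number of clonotypes (default 2000).
#' @param seed Fixed seed (default 20230901).
#' @return A `clonotype_table` of tissue `"other"`.
#' @export
default_reference_repertoire <- function(n_clones = 2000, seed = 20230901) {
  cfg <- generator_config(clones_per_sample = n_clones,
                          reads_per_sample = 4 * n_clones)
  generate_repertoire(cfg, tissue = "other", patient_id = "reference",
                      seed = seed, motifs = NULL)
}

#' Discover cohort-shared CDR3 motifs
#'
#' Local-motif discovery in the spirit of GLIPH2: unique TCRs are pooled
#' across the cohort's samples, every candidate motif is counted as the
#' number of distinct TCRs (CDR3aa + V) carrying it, and enrichment over a
#' naive background repertoire is assessed with a one-sided Fisher exact
#' test, Benjamini-Hochberg corrected across candidates. Motifs are retained
#' when they are carried by at least `min_cluster` distinct TCRs, reach
#' `min_fold` enrichment over the background, and have adjusted p below
#' `alpha`. Offsets observed across carriers are aggregated per motif.
#'
#' Fold is `(c1 / n1) / ((c2 + 1) / (n2 + 1))` where `c1`/`n1` are carrier /
#' total TCR counts in the cohort and `c2`/`n2` in the background; the
#' pseudocount keeps motifs absent from the background finite.
#'
#' @param cohort List of `clonotype_table`s (one tissue compartment, pooled).
#' @param reference Background: a `clonotype_table`, list of them, or a
#'   prebuilt [build_motif_reference()] object.
#' @param min_cluster Minimum distinct carrier TCRs (default 3).
#' @param min_fold Minimum enrichment fold over background (default 10).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param params A [motif_params()] bundle.
#' @param tissue Discovery-tissue label recorded on the index.
#' @return A tibble of class `motif_index`: `motif`, `offsets` (list column
#'   of integer vectors), `cluster_size`, `n_samples`, `cohort_tcrs`,
#'   `reference_tcrs`, `fold`, `p_value`, `p_adjusted`; parameters are kept
#'   in attributes.
#' @export
discover_cohort_motifs <- function(cohort, reference, min_cluster = 3,
                                   min_fold = 10, alpha = 0.05,
                                   params = motif_params(),
                                   tissue = NULL) {
  if (inherits(cohort, "clonotype_table")) cohort <- list(cohort)
  if (length(cohort) == 0) {
    abort("cohort must contain at least one sample",
          class = "tilmotif_empty_error")
  }
  if (!inherits(reference, "motif_reference")) {
    reference <- build_motif_reference(reference, params)
  }
  pool <- unique(pool_unique_tcrs(cohort)[, c("cdr3_aa", "v_gene")])
  cores0 <- trim_cores(pool$cdr3_aa, params$head, params$tail)
  cores <- cores0[!is.na(cores0)]
  n1 <- length(cores)
  enum <- enumerate_motifs_codes(cores, params)
  if (length(enum$code) == 0) {
    return(empty_motif_index(params, tissue))
  }
  mult <- 2^ceiling(log2(n1 + 1))
  ucode <- floor(unique(enum$code * mult + enum$idx) / mult)
  s <- sort.int(ucode, method = "radix")
  r <- rle(s)
  sel <- r$lengths >= min_cluster
  if (!any(sel)) {
    return(empty_motif_index(params, tissue))
  }
  cand_code <- r$values[sel]
  c1 <- r$lengths[sel]
  m <- match(cand_code, reference$code)
  c2 <- ifelse(is.na(m), 0, reference$n_tcr_by_code[m])
  n2 <- reference$n_tcr
  fold <- (c1 / n1) / ((c2 + 1) / (n2 + 1))
  p <- phyper(c1 - 1, c1 + c2, (n1 - c1) + (n2 - c2), n1, lower.tail = FALSE)
  p_adj <- p.adjust(p, method = "BH")
  keep_motif <- fold >= min_fold & p_adj < alpha
  out <- tibble(motif = decode_motif(cand_code),
                cluster_size = c1,
                cohort_tcrs = n1,
                reference_tcrs = c2,
                fold = fold,
                p_value = p,
                p_adjusted = p_adj)[keep_motif, ]
  # offsets only needed for the retained motifs
  kept_code <- cand_code[keep_motif]
  offkey <- unique(enum$code * 64 + enum$offset)
  okc <- floor(offkey / 64)
  out$offsets <- lapply(kept_code, function(cc)
    sort(as.integer(offkey[okc == cc] - cc * 64)))
  out <- out[, c("motif", "offsets", "cluster_size", "cohort_tcrs",
                 "reference_tcrs", "fold", "p_value", "p_adjusted")]
  # distinct cohort samples contributing at least one carrier, per motif
  out$n_samples <- vapply(seq_len(nrow(out)), function(i) {
    sum(vapply(cohort, function(t) {
      any(motif_matches(t$cdr3_aa, out$motif[i], out$offsets[[i]],
                        head = params$head, tail = params$tail))
    }, logical(1)))
  }, integer(1))
  out <- arrange(out, desc(.data$cluster_size), .data$motif)
  structure(out,
            class = c("motif_index", class(out)),
            params = params,
            discovery_tissue = tissue %||%
              attr(cohort[[1]], "tissue") %||% "other",
            min_cluster = min_cluster, min_fold = min_fold, alpha = alpha)
}

empty_motif_index <- function(params, tissue) {
  structure(tibble(motif = character(0), offsets = list(),
                   cluster_size = integer(0), cohort_tcrs = integer(0),
                   reference_tcrs = numeric(0), fold = numeric(0),
                   p_value = numeric(0), p_adjusted = numeric(0),
                   n_samples = integer(0)),
            class = c("motif_index", class(tibble())),
            params = params, discovery_tissue = tissue %||% "other")
}

#' Serialise a motif index to TSV
#'
#' Offsets are written as comma-joined integers; [read_motif_index()] is the
#' inverse.
#' @param index A `motif_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_index <- function(index, path) {
  out <- as_tibble(index)
  out$offsets <- vapply(out$offsets, paste, character(1), collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_motif_index
#' @export
read_motif_index <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(offsets = "c"),
                        progress = FALSE)
  df$offsets <- lapply(strsplit(as.character(df$offsets), ","), as.integer)
  structure(as_tibble(df), class = c("motif_index", class(tibble())))
}
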