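#' Motif enumeration parameters
#'
#' Bundles the conventions under which CDR3-beta local motifs are enumerated
#' and matched: how many residues to trim from the conserved head and tail of
#' the CDR3 before enumeration, which k-mer lengths to enumerate, and whether
#' single-wildcard patterns are included.
#'
#' @param head Residues trimmed from the CDR3 start (default 3; the conserved
#'   "CAS" head does not inform specificity).
#' @param tail Residues trimmed from the CDR3 end (default 2).
#' @param k_set Contiguous k-mer lengths enumerated (default `c(3, 4)`;
#'   motifs shorter than 3 are never considered).
#' @param allow_wildcard If `TRUE` (default), also enumerate patterns of
#'   length `k + 1` for each `k` with exactly one internal position replaced
#'   by the wildcard `*`, which matches any residue. The wildcard is never
#'   terminal.
#' @return A list of class `motif_params`.
#' @export
motif_params <- function(head = 3, tail = 2, k_set = c(3, 4),
                         allow_wildcard = TRUE) {
  stopifnot(head >= 0, tail >= 0, all(k_set >= 3))
  structure(list(head = head, tail = tail, k_set = sort(unique(k_set)),
                 allow_wildcard = allow_wildcard),
            class = "motif_params")
}

#' Trim a CDR3 to its central region
#'
#' Returns the central portion of a CDR3 amino-acid sequence used for motif
#' enumeration, together with the 1-based start position of that core in the
#' full CDR3 (so core coordinates can be mapped back). Sequences too short to
#' leave a non-empty core return the skip sentinel `NULL` core.
#'
#' @param cdr3_aa CDR3 amino-acid string (scalar).
#' @param head,tail Residues to trim from each end.
#' @return A list with `core` (string, or `NA` when the sequence is too
#'   short) and `offset` (1-based position of the first core residue).
#' @examples
#' trim_cdr3("CASSLAPGATNEKLFF")  # core "SLAPGATNEKL", offset 4
#' @export
trim_cdr3 <- function(cdr3_aa, head = 3, tail = 2) {
  n <- nchar(cdr3_aa)
  if (n <= head + tail) {
    return(list(core = NA_character_, offset = head + 1L))
  }
  list(core = substr(cdr3_aa, head + 1L, n - tail), offset = head + 1L)
}

#' Enumerate local motifs of a CDR3 core
#'
#' All contiguous k-mers of the core for each `k` in `k_set`, and (when
#' wildcarding is on) all patterns of length `k + 1` with exactly one
#' internal residue replaced by `*`. Offsets are reported as 1-based start
#' positions in the full CDR3 (core position plus head offset).
#'
#' @param core Core string from [trim_cdr3()].
#' @param params A [motif_params()] bundle.
#' @param core_offset 1-based position of the core's first residue in the
#'   full CDR3.
#' @return A tibble with columns `motif` and `offset`.
#' @examples
#' enumerate_motifs("SLAP", motif_params(k_set = 3, allow_wildcard = FALSE))
#' @export
enumerate_motifs <- function(core, params = motif_params(),
                             core_offset = params$head + 1L) {
  if (is.na(core) || nchar(core) == 0) {
    return(tibble(motif = character(0), offset = integer(0)))
  }
  dt <- enumerate_motifs_bulk(core, params, core_offset)
  as_tibble(dt[, c("motif", "offset")])
}

# Vectorised enumeration over many cores. Returns a data.table with columns
# idx (index into `cores`), motif, offset (1-based, full-CDR3 coordinates).
enumerate_motifs_bulk <- function(cores, params = motif_params(),
                                  core_offset = params$head + 1L) {
  widths <- params$k_set
  if (params$allow_wildcard) widths <- sort(unique(c(widths, params$k_set + 1L)))
  lens <- nchar(cores)
  pieces <- vector("list", 64)
  np <- 0L
  for (w in widths) {
    base_w <- w %in% params$k_set           # emit as contiguous motif
    wild_w <- params$allow_wildcard && (w - 1L) %in% params$k_set
    max_start <- max(lens) - w + 1L
    if (is.infinite(max_start) || max_start < 1L) next
    for (s in seq_len(max_start)) {
      sel <- which(lens >= s + w - 1L)
      if (length(sel) == 0) next
      mers <- substr(cores[sel], s, s + w - 1L)
      off <- core_offset + s - 1L
      if (base_w) {
        np <- np + 1L
        pieces[[np]] <- data.table::data.table(idx = sel, motif = mers,
                                               offset = off)
      }
      if (wild_w) {
        for (j in 2:(w - 1L)) {
          np <- np + 1L
          pieces[[np]] <- data.table::data.table(
            idx = sel,
            motif = paste0(substr(mers, 1L, j - 1L), "*",
                           substr(mers, j + 1L, w)),
            offset = off)
        }
      }
    }
  }
  if (np == 0L) {
    return(data.table::data.table(idx = integer(0), motif = character(0),
                                  offset = integer(0)))
  }
  out <- data.table::rbindlist(pieces[seq_len(np)])
  unique(out)
}

# --- integer motif codes -------------------------------------------------
# Motifs (<= 6 residues over the 20-letter alphabet plus '*') are packed as
# base-27 integers for fast radix grouping in discovery; codes of different
# widths cannot collide because every digit is >= 1.
MOTIF_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                    "R","S","T","V","W","Y","*")

# n x max-length matrix of residue codes (NA beyond each core's end)
core_code_matrix <- function(cores) {
  maxlen <- max(nchar(cores), 0L)
  m <- matrix(NA_real_, nrow = length(cores), ncol = maxlen)
  for (p in seq_len(maxlen)) {
    m[, p] <- match(substr(cores, p, p), MOTIF_ALPHABET)
  }
  m
}

decode_motif <- function(code) {
  vapply(code, function(x) {
    out <- character(0)
    while (x > 0) {
      d <- x %% 27
      out <- c(out, MOTIF_ALPHABET[d])
      x <- (x - d) / 27
    }
    paste(out, collapse = "")
  }, character(1))
}

encode_motif <- function(motif) {
  vapply(strsplit(motif, ""), function(ch)
    sum(match(ch, MOTIF_ALPHABET) * 27^(seq_along(ch) - 1)), numeric(1))
}

# Vectorised integer enumeration: list(code, offset, idx) over all local
# motifs of `cores` (contiguous k-mers plus single-wildcard patterns).
enumerate_motifs_codes <- function(cores, params = motif_params(),
                                   core_offset = params$head + 1L) {
  M <- core_code_matrix(cores)
  lens <- nchar(cores)
  wild <- match("*", MOTIF_ALPHABET)
  pw27 <- 27^(0:6)
  code_l <- list(); off_l <- list(); idx_l <- list()
  np <- 0L
  widths <- params$k_set
  if (params$allow_wildcard) widths <- sort(unique(c(widths, params$k_set + 1L)))
  for (w in widths) {
    base_w <- w %in% params$k_set
    wild_w <- params$allow_wildcard && (w - 1L) %in% params$k_set
    if (ncol(M) < w) next
    for (s in seq_len(ncol(M) - w + 1L)) {
      sel <- which(lens >= s + w - 1L)
      if (length(sel) == 0) next
      win <- M[sel, s:(s + w - 1L), drop = FALSE]
      if (base_w) {
        np <- np + 1L
        code_l[[np]] <- drop(win %*% pw27[seq_len(w)])
        off_l[[np]] <- rep(core_offset + s - 1L, length(sel))
        idx_l[[np]] <- sel
      }
      if (wild_w) {
        base_code <- drop(win %*% pw27[seq_len(w)])
        for (j in 2:(w - 1L)) {
          np <- np + 1L
          code_l[[np]] <- base_code + (wild - win[, j]) * pw27[j]
          off_l[[np]] <- rep(core_offset + s - 1L, length(sel))
          idx_l[[np]] <- sel
        }
      }
    }
  }
  list(code = unlist(code_l), offset = unlist(off_l), idx = unlist(idx_l))
}

# vectorised trim: central cores of many CDR3s (NA when too short)
trim_cores <- function(cdr3_aa, head = 3, tail = 2) {
  n <- nchar(cdr3_aa)
  out <- substr(cdr3_aa, head + 1L, n - tail)
  out[n <= head + tail] <- NA_character_
  out
}

#' Test whether CDR3 sequences carry a motif at allowed offsets
#'
#' A sequence carries the motif when the substring starting at one of the
#' allowed 1-based offsets equals the motif, with `*` matching any residue,
#' and the occupied span lies inside the trimmed central region of that
#' sequence (same convention as discovery). This is the "same location"
#' matching rule used for motif quantification in new repertoires.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param motif Motif string (may contain one `*`).
#' @param offsets Integer vector of allowed 1-based start positions.
#' @param head,tail Trim convention under which the motif was discovered.
#' @return Logical vector, one element per sequence.
#' @examples
#' motif_matches("CSAGLAGEYEQYF", "SAGLAGE*E", offsets = 2, head = 1)
#' @export
motif_matches <- function(cdr3_aa, motif, offsets, head = 3, tail = 2) {
  w <- nchar(motif)
  n <- nchar(cdr3_aa)
  pat <- paste0("^", gsub("*", ".", motif, fixed = TRUE), "$")
  hit <- logical(length(cdr3_aa))
  for (o in offsets) {
    in_core <- o >= head + 1L & (o + w - 1L) <= (n - tail)
    if (!any(in_core)) next
    sub <- substr(cdr3_aa, o, o + w - 1L)
    hit <- hit | (in_core & grepl(pat, sub))
  }
  hit
}
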