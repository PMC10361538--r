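# in-code fixtures and independent oracles shared across test files

# distinct plausible CDR3s: CASS + 3 varying residues + NEQFF
fixture_cdr3s <- function(n) {
  stopifnot(n <= 26^2)
  mid <- expand.grid(LETTERS[c(1, 4, 5, 7)], LETTERS[seq_len(26)],
                     stringsAsFactors = FALSE)
  paste0("CASS", mid[seq_len(n), 1], "LG", mid[seq_len(n), 2], "NEQFF")
}

make_table <- function(counts, cdr3_aa = NULL, v_gene = "TRBV5-1",
                       j_gene = "TRBJ1-1", productive = TRUE,
                       sample_id = "s1", tissue = "other",
                       patient_id = "p1", cdr3_nt = NULL) {
  n <- length(counts)
  if (is.null(cdr3_aa)) cdr3_aa <- fixture_cdr3s(n)
  df <- tibble::tibble(
    cdr3_nt = cdr3_nt %||% strrep("ACG", nchar(cdr3_aa)),
    cdr3_aa = cdr3_aa,
    v_gene = rep_len(v_gene, n), j_gene = rep_len(j_gene, n),
    count = counts, productive = rep_len(productive, n))
  clonotype_table(df, sample_id = sample_id, tissue = tissue,
                  patient_id = patient_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) Gini oracle: mean absolute difference over twice the mean
oracle_gini <- function(x) {
  n <- length(x)
  sum(outer(x, x, function(a, b) abs(a - b))) / (2 * n^2 * mean(x))
}

# full-enumeration two-sided Fisher oracle (lchoose-based pmf)
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; nn <- c + d; k <- a + c
  support <- max(0, k - nn):min(k, m)
  logp <- lchoose(m, support) + lchoose(nn, k - support) - lchoose(m + nn, k)
  pmf <- exp(logp)
  d_obs <- pmf[support == a]
  min(1, sum(pmf[pmf <= d_obs * (1 + 1e-7)]))
}

# brute-force Benjamini-Hochberg step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (k in seq_len(n)) {
    adj_sorted[k] <- min(1, min((n / (k:n)) * p[o][k:n]))
  }
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# rank correlation oracle: pairwise-comparison ranks + explicit Pearson
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided rank-sum test by enumeration of all group assignments
oracle_wilcoxon_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n)])
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n * (length(all_v) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force local-motif enumeration oracle (strings + offsets)
oracle_enumerate <- function(core, k_set = c(3, 4), wildcard = TRUE,
                             core_offset = 4L) {
  out <- list()
  L <- nchar(core)
  for (k in k_set) {
    if (L < k) next
    for (s in seq_len(L - k + 1)) {
      out[[length(out) + 1]] <- data.frame(
        motif = substr(core, s, s + k - 1), offset = core_offset + s - 1)
    }
  }
  if (wildcard) {
    for (k in k_set) {
      w <- k + 1
      if (L < w) next
      for (s in seq_len(L - w + 1)) {
        mer <- substr(core, s, s + w - 1)
        for (j in 2:(w - 1)) {
          m <- mer
          substr(m, j, j) <- "*"
          out[[length(out) + 1]] <- data.frame(
            motif = m, offset = core_offset + s - 1)
        }
      }
    }
  }
  unique(do.call(rbind, out))
}

# shared small generator config to keep test runtime low
small_config <- function(...) {
  defaults <- list(n_tumor = 4, n_healthy = 3, n_pb = 3, n_til_pairs = 2,
                   clones_per_sample = 120, til_clones = 300,
                   reads_per_sample = 12000, n_cells = 400,
                   cells_per_motif = c(10, 25), n_genes = 60)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}
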