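# build a minimal motif_index for a given motif set
fake_index <- function(motifs, offsets = 5L) {
  structure(tibble::tibble(
    motif = motifs,
    offsets = replicate(length(motifs), as.integer(offsets),
                        simplify = FALSE),
    cluster_size = 5L, cohort_tcrs = 100L, reference_tcrs = 0,
    fold = 50, p_value = 1e-6, p_adjusted = 1e-5),
    class = c("motif_index", class(tibble::tibble())))
}

# one sample whose pooled frequency for a motif planted at offset 5 is f
freq_sample <- function(f, id, total = 1000L) {
  k <- as.integer(round(f * total))
  carrier <- "CASSQWERAANEQFF"  # QWER at offset 5
  if (k == 0) {
    make_table(total, cdr3_aa = "CASSAAAAAANEQFF", sample_id = id)
  } else {
    make_table(c(k, total - k),
               cdr3_aa = c(carrier, "CASSAAAAAANEQFF"), sample_id = id)
  }
}

test_that("pooled motif frequency sums carrier clones, zeros included", {
  tab <- make_table(c(10L, 20L, 970L),
                    cdr3_aa = c("CASSQWERAANEQFF", "CASSQWERBBNEQFF",
                                "CASSAAAAAANEQFF"))
  expect_equal(pooled_motif_frequency(tab, "QWER", 5L), 0.03)
  expect_equal(pooled_motif_frequency(tab, "QWER", 5L, "unique"), 2 / 3)
  # motif present only at a disallowed offset counts as zero
  expect_equal(pooled_motif_frequency(tab, "QWER", 6L), 0)
  # sample lacking the motif is noted as zero
  expect_equal(pooled_motif_frequency(freq_sample(0, "s0"), "QWER", 5L), 0)
  expect_error(pooled_motif_frequency(tab, "QWER", integer(0)),
               class = "tilmotif_config_error")
})

test_that("motifs absent from every comparator index are exclusive", {
  tum <- lapply(1:3, function(i) freq_sample(0.05, paste0("t", i)))
  cmp <- lapply(1:3, function(i) freq_sample(0.01, paste0("h", i)))
  res <- classify_motifs(fake_index("QWER"), list(healthy = fake_index("RRRR")),
                         tum, list(healthy = cmp))
  expect_equal(res$status, "exclusive")
})

test_that("shared motifs are tested by Wilcoxon with an exact-oracle p", {
  f_t <- c(0.051, 0.047, 0.062, 0.055, 0.043, 0.058, 0.049, 0.066)
  f_c <- c(0.012, 0.003, 0.017, 0.009, 0.021, 0.006, 0.014, 0.011)
  tum <- lapply(seq_along(f_t), function(i)
    freq_sample(f_t[i], paste0("t", i)))
  cmp <- lapply(seq_along(f_c), function(i)
    freq_sample(f_c[i], paste0("h", i)))
  res <- classify_motifs(fake_index("QWER"), list(healthy = fake_index("QWER")),
                         tum, list(healthy = cmp))
  expect_equal(res$status, "enriched")
  expect_equal(res$wilcoxon_p, oracle_wilcoxon_exact(f_t, f_c),
               tolerance = 1e-9)
  expect_gt(res$log2fc, 1)
  # identical pooled frequencies: shared motif rejected
  res2 <- classify_motifs(fake_index("QWER"), list(healthy = fake_index("QWER")),
                          tum, list(healthy = tum))
  expect_equal(res2$status, "rejected")
})

test_that("a motif absent everywhere is rejected with undefined log2fc", {
  tum <- lapply(1:3, function(i) freq_sample(0, paste0("t", i)))
  cmp <- lapply(1:3, function(i) freq_sample(0, paste0("h", i)))
  res <- classify_motifs(fake_index("QWER"), list(healthy = fake_index("QWER")),
                         tum, list(healthy = cmp))
  expect_equal(res$status, "rejected")
  expect_true(is.na(res$log2fc))
})

test_that("adding zero-frequency comparator samples never hurts enrichment", {
  f_t <- c(0.05, 0.04, 0.06, 0.055, 0.045, 0.052)
  f_c <- c(0.02, 0.01, 0.015, 0.025, 0.012, 0.018)
  p_of <- function(extra_zeros) {
    tum <- lapply(seq_along(f_t), function(i)
      freq_sample(f_t[i], paste0("t", i)))
    cmp <- lapply(seq_along(c(f_c, rep(0, extra_zeros))), function(i)
      freq_sample(c(f_c, rep(0, extra_zeros))[i], paste0("h", i)))
    classify_motifs(fake_index("QWER"), list(healthy = fake_index("QWER")),
                    tum, list(healthy = cmp))$wilcoxon_p
  }
  p0 <- p_of(0)
  # a small bump is tolerated exactly at the exact-to-approximate switch of
  # the rank-sum test; past it, added zeros strictly help
  expect_lte(p_of(2), p0 * 1.15)
  expect_lt(p_of(5), p0)
  expect_lt(p_of(8), p_of(5))
})

test_that("pruning marks control-set motifs and partitions statuses", {
  tum <- lapply(1:3, function(i) freq_sample(0.05, paste0("t", i)))
  cmp <- lapply(1:3, function(i) freq_sample(0.01, paste0("h", i)))
  idx <- fake_index(c("QWER", "RRRR"))
  res <- classify_motifs(idx, list(healthy = fake_index("SSSS")),
                         tum, list(healthy = cmp))
  pruned <- prune_against_controls(res, list(viral = c("RRRR", "TTTT")))
  expect_equal(pruned$status[pruned$motif == "RRRR"], "pruned")
  expect_equal(pruned$pruned_by[[which(pruned$motif == "RRRR")]], "viral")
  expect_equal(pruned$status[pruned$motif == "QWER"], "exclusive")
  # empty control sets are the identity
  same <- prune_against_controls(res, list())
  expect_equal(same$status, res$status)
  # idempotent and order-independent
  sets <- list(a = "RRRR", b = c("RRRR", "QWER"))
  p1 <- prune_against_controls(prune_against_controls(res, sets), sets)
  p2 <- prune_against_controls(res, rev(sets))
  expect_equal(p1$status, p2$status)
  expect_equal(lapply(p1$pruned_by, sort), lapply(p2$pruned_by, sort))
  # every motif lands in exactly one status class
  expect_true(all(p1$status %in% c("exclusive", "enriched", "rejected",
                                   "pruned")))
  expect_equal(nrow(p1), nrow(idx))
  # the surviving associated set excludes pruned motifs
  expect_equal(associated_motifs(p1)$motif, character(0))
})
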