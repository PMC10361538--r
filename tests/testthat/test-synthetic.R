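test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config()
  a <- generate_repertoire(cfg, "tumor", seed = 5)
  b <- generate_repertoire(cfg, "tumor", seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  pa <- generate_paired_til(cfg, seed = 6)
  pb <- generate_paired_til(cfg, seed = 6)
  expect_identical(tibble::as_tibble(pa$rep), tibble::as_tibble(pb$rep))
  expect_identical(pa$truth, pb$truth)
  ca <- generate_cell_table(cfg, seed = 7)
  cb <- generate_cell_table(cfg, seed = 7)
  expect_identical(ca$cells, cb$cells)
  expect_identical(ca$expression, cb$expression)
})

test_that("clone sizes follow the configured Zipf law", {
  cfg <- generator_config(clones_per_sample = 1000, zipf_exponent = 1.1,
                          reads_per_sample = 30000, n_viral_spikes = 0)
  tab <- generate_repertoire(cfg, "healthy_kidney", seed = 8)
  counts <- sort(tab$count, decreasing = TRUE)
  counts <- counts[counts >= 10]  # above sampling noise floor
  fit <- stats::lm(log(counts) ~ log(seq_along(counts)))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1.1), 0.15)
})

test_that("zero comparator incidence leaves healthy samples motif-free", {
  cfg <- small_config(incidence_ratio = Inf)
  motifs <- withr::with_seed(1, tilmotif:::draw_planted_motifs(cfg))
  tab <- generate_repertoire(cfg, "healthy_kidney", seed = 9,
                             motifs = motifs)
  expect_equal(nrow(attr(tab, "planted")), 0)
  hits <- vapply(seq_len(nrow(motifs)), function(i)
    sum(motif_matches(tab$cdr3_aa, motifs$motif[i], motifs$offset[i])),
    numeric(1))
  expect_lte(sum(hits), 1)  # chance background only
})

test_that("planted expansions obey the configured construction", {
  cfg <- small_config()
  pair <- generate_paired_til(cfg, seed = 10)
  expect_equal(nrow(pair$truth), cfg$n_expansions)
  expect_true(all(pair$truth$fold >= cfg$expansion_fold_range[1] - 1e-9))
  expect_true(all(pair$truth$rep_freq >= 0.001))
  expect_true(all(pair$truth$key %in% clonotype_keys(pair$rep, "aa_vj")))
  # degenerate fold distribution: no true expansions
  flat <- small_config(expansion_fold_range = c(1, 1))
  expect_equal(nrow(generate_paired_til(flat, seed = 11)$truth), 0)
})

test_that("non-designated clones keep identical underlying frequencies", {
  # with no designated expansions and no carrier decay the pair is pure null
  cfg <- small_config(expansion_fold_range = c(1, 1))
  pair <- generate_paired_til(cfg, seed = 12)
  res <- test_expansion(pair$pre_rep, pair$rep)
  expect_true(all(res$expanded_in == "none"))
})

test_that("the cohort manifest audit passes", {
  cfg <- small_config()
  cohort <- simulate_cohort(cfg, seed = 13)
  audit <- audit_cohort(cohort)
  expect_true(all(audit$pass))
  man <- cohort$manifest
  expect_equal(nrow(man$planted_motifs), cfg$n_motifs)
  expect_length(man$contamination, cfg$n_contaminated)
  expect_true(all(man$contamination %in% man$control_sets$validation_cohort))
})

test_that("generated AIRR files re-read with zero dropped rows", {
  cfg <- small_config()
  cohort <- simulate_cohort(cfg, seed = 14, with_cells = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  f <- file.path(dir, paste0(attr(cohort$tumor[[1]], "sample_id"),
                             ".airr.tsv"))
  expect_true(file.exists(f))
  got <- read_clonotype_table(f, "airr", tissue = "tumor")
  expect_equal(attr(got, "filter_log")$read$n_dropped, 0)
  expect_equal(total_reads(got), total_reads(cohort$tumor[[1]]))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("phenotype-biased carriage propagates to dominant calls", {
  cfg <- small_config(phenotype_bias = 0.95)
  ct <- generate_cell_table(cfg, seed = 15)
  motifs <- tibble::tibble(motif = ct$truth$motif,
                           offsets = as.list(ct$truth$offset))
  calls <- assign_motif_phenotypes(ct$cells, motifs)
  m <- merge(as.data.frame(calls[, c("motif", "dominant_phenotype")]),
             as.data.frame(ct$truth), by = "motif")
  expect_gte(mean(m$dominant_phenotype == m$target_phenotype), 0.8)
})

test_that("a zero module effect leaves module scores phenotype-neutral", {
  withr::with_seed(67, {
    cfg <- small_config(module_effect = 1, n_cells = 250)
    pvals <- vapply(1:40, function(i) {
      ct <- generate_cell_table(cfg, seed = 700 + i)
      sc <- module_score(ct$expression, signature_panels()$exhaustion,
                         seed = i)
      ph <- ct$cells$phenotype == "CD8_Texh"
      if (sum(ph) < 3) return(NA_real_)
      suppressWarnings(stats::wilcox.test(sc[ph], sc[!ph])$p.value)
    }, numeric(1))
    pvals <- pvals[!is.na(pvals)]
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.001)
  })
})
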