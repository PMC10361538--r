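cells_fixture <- function(carrier_ph, bg_n = 200, bg_levels = c("P", "Q", "R", "S")) {
  n <- length(carrier_ph)
  tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n + bg_n)),
    cdr3_aa = c(rep("CASSQWERAANEQFF", n), rep("CASSAAAAAANEQFF", bg_n)),
    phenotype = c(carrier_ph, rep(bg_levels, length.out = bg_n)))
}

one_motif <- function() {
  tibble::tibble(motif = "QWER", offsets = list(5L))
}

test_that("dominant phenotype follows the largest odds ratio", {
  cells <- cells_fixture(c(rep("P", 9), "Q"))
  calls <- assign_motif_phenotypes(cells, one_motif())
  expect_equal(calls$n_supporting_cells, 10L)
  expect_equal(calls$dominant_phenotype, "P")
  expect_gt(calls$dominant_or, 1)
  per <- calls$per_phenotype[[1]]
  expect_equal(sum(per$n11), 10 * nrow(per) - sum(per$n10))
})

test_that("motifs below five supporting cells are never called", {
  cells <- cells_fixture(rep("P", 4))
  calls <- assign_motif_phenotypes(cells, one_motif())
  expect_equal(nrow(calls), 0)
  expect_equal(attr(calls, "skipped"), "QWER")
  # exactly five cells is callable
  calls5 <- assign_motif_phenotypes(cells_fixture(rep("P", 5)), one_motif())
  expect_equal(nrow(calls5), 1)
})

test_that("cell-table validation catches structural errors", {
  cells <- cells_fixture(rep("P", 6))
  dup <- cells; dup$cell_id[2] <- dup$cell_id[1]
  expect_error(assign_motif_phenotypes(dup, one_motif()),
               class = "tilmotif_invariant_error")
  nap <- cells; nap$phenotype[1] <- NA
  expect_error(assign_motif_phenotypes(nap, one_motif()),
               class = "tilmotif_invariant_error")
  expect_error(assign_motif_phenotypes(cells[, 1:2], one_motif()),
               class = "tilmotif_format_error")
})

test_that("relabelling phenotypes permutes the per-phenotype odds ratios", {
  cells <- cells_fixture(c(rep("P", 6), rep("Q", 3), "R"))
  a <- assign_motif_phenotypes(cells, one_motif())$per_phenotype[[1]]
  swap <- c(P = "Q", Q = "P", R = "R", S = "S")
  cells2 <- cells
  cells2$phenotype <- unname(swap[cells$phenotype])
  b <- assign_motif_phenotypes(cells2, one_motif())$per_phenotype[[1]]
  expect_equal(a$odds_ratio[a$phenotype == "P"],
               b$odds_ratio[b$phenotype == "Q"])
  expect_equal(a$odds_ratio[a$phenotype == "Q"],
               b$odds_ratio[b$phenotype == "P"])
})

test_that("random phenotype assignment yields uniform dominant calls", {
  withr::with_seed(53, {
    labels <- c("P", "Q", "R", "S")
    doms <- vapply(1:200, function(i) {
      cells <- cells_fixture(sample(labels, 12, replace = TRUE), bg_n = 120)
      assign_motif_phenotypes(cells, one_motif())$dominant_phenotype
    }, character(1))
    gof <- suppressWarnings(
      stats::chisq.test(table(factor(doms, levels = labels))))
    expect_gt(gof$p.value, 0.001)
  })
})

test_that("module scores recover a planted expression shift", {
  withr::with_seed(59, {
    n_genes <- 500; n_cells <- 2000; delta <- 2
    expr <- matrix(rnorm(n_genes * n_cells, mean = 5),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%03d", 1:n_genes),
                                   sprintf("c%04d", 1:n_cells)))
    module <- rownames(expr)[1:6]
    expr[module, ] <- expr[module, ] + delta
    sc <- module_score(expr, module, seed = 1)
    expect_lt(abs(mean(sc) - delta), 0.05 * delta)
    # constant-zero matrix scores zero
    zero <- matrix(0, 30, 10,
                   dimnames = list(sprintf("Z%02d", 1:30), NULL))
    expect_equal(unname(module_score(zero, "Z01", n_bins = 5, seed = 1)),
                 rep(0, 10))
    # deterministic under a fixed seed
    expect_identical(module_score(expr, module, seed = 9),
                     module_score(expr, module, seed = 9))
    # a random gene set scores near zero
    rand <- sample(rownames(expr)[7:n_genes], 6)
    sr <- module_score(expr, rand, seed = 2)
    expect_lt(abs(mean(sr)), 3 * stats::sd(sr) / sqrt(length(sr)))
  })
})

test_that("missing module genes warn, an empty module errors", {
  expr <- matrix(rnorm(300), 30, 10,
                 dimnames = list(sprintf("G%02d", 1:30), NULL))
  expect_warning(s <- module_score(expr, c("G01", "NOPE"), n_bins = 5,
                                   seed = 1), "absent")
  expect_length(s, 10)
  expect_error(module_score(expr, "NOPE", n_bins = 5),
               class = "tilmotif_config_error")
  expect_error(module_score(expr, "G01", n_bins = 50),
               class = "tilmotif_config_error")
})

test_that("biased motif carriage in generated cells recovers the truth", {
  cfg <- small_config()
  ct <- generate_cell_table(cfg, seed = 61)
  motifs <- tibble::tibble(motif = ct$truth$motif,
                           offsets = as.list(ct$truth$offset))
  calls <- assign_motif_phenotypes(ct$cells, motifs)
  m <- merge(as.data.frame(calls[, c("motif", "dominant_phenotype",
                                     "n_supporting_cells")]),
             as.data.frame(ct$truth), by = "motif")
  big <- m[m$n_supporting_cells >= 10, ]
  expect_gt(nrow(big), 0)
  expect_gte(mean(big$dominant_phenotype == big$target_phenotype), 0.95)
})
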