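test_that("fisher_exact matches the worked hypergeometric example", {
  p <- fisher_exact(5, 5, 0, 10)
  expect_equal(p, oracle_fisher2x2(5, 5, 0, 10), tolerance = 1e-12)
  expect_equal(p, 0.03250774, tolerance = 1e-6)
  expect_equal(p, stats::fisher.test(matrix(c(5, 0, 5, 10), 2))$p.value,
               tolerance = 1e-9)
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  withr::with_seed(5, {
    for (i in 1:40) {
      cells <- rmultinom(1, sample(20:120, 1), rep(0.25, 4))[, 1]
      mine <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
      ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  })
})

test_that("top-clonotype tracking reports target frequencies with totals", {
  ref <- make_table(c(50L, 30L, 20L))
  tr <- track_top_clonotypes(ref, list(self = ref), n = 3)
  expect_equal(tr$self[1:3], tr$reference[1:3])
  expect_equal(tr$reference[tr$key == "TOTAL"], 1)
  # absent clones read zero
  other <- make_table(c(10L, 10L), cdr3_aa = c(ref$cdr3_aa[1], "CASSXXYNEQFF"))
  tr2 <- track_top_clonotypes(ref, list(o = other), n = 3)
  expect_equal(tr2$o[tr2$key == ref$cdr3_aa[2]], 0)
  expect_warning(track_top_clonotypes(ref, list(o = other), n = 10),
                 "exceeds")
})

test_that("tracked cumulative frequency recovers a planted tumor share", {
  # top REP clones planted to sum to 5% of the tumor repertoire
  rep_tab <- make_table(rep(10L, 20), sample_id = "rep")
  tumor_counts <- c(rep(25L, 20), 9500L)
  tumor <- make_table(tumor_counts,
                      cdr3_aa = c(rep_tab$cdr3_aa, "CASSZZZZNEQFF"),
                      sample_id = "tumor")
  tr <- track_top_clonotypes(rep_tab, list(tumor = tumor), n = 20)
  expect_equal(tr$tumor[tr$key == "TOTAL"], 0.05, tolerance = 1e-9)
})

test_that("overlap reports shared clones and an exact Spearman rho", {
  a <- make_table(c(5L, 4L, 3L, 2L))
  expect_equal(repertoire_overlap(a, a)$spearman_rho, 1)
  b <- make_table(c(5L, 4L), cdr3_aa = c("CASSQQAQNEQFF", "CASSQQBQNEQFF"))
  ov <- repertoire_overlap(a, b)
  expect_equal(ov$n_shared, 0)
  expect_true(is.na(ov$spearman_rho))
  withr::with_seed(9, {
    n <- 50
    cdr3 <- fixture_cdr3s(n)
    x <- sample(10:2000, n)
    y <- sample(10:2000, n)
    ov <- repertoire_overlap(make_table(x, cdr3_aa = cdr3),
                             make_table(y, cdr3_aa = cdr3))
    expect_equal(ov$spearman_rho,
                 oracle_spearman(x / sum(x), y / sum(y)), tolerance = 1e-12)
  })
})

test_that("expansion testing applies the adjusted-p and min-frequency rule", {
  a <- make_table(c(5000L, 30L, rep(200L, 24)))
  b <- make_table(c(5000L, 500L, rep(180L, 24)), cdr3_aa = a$cdr3_aa)
  res <- test_expansion(a, b)
  expect_true(all(res$p_adjusted >= res$p_value))
  hit <- res[res$expanded_in != "none", ]
  expect_equal(hit$key, clonotype_keys(a, "aa_vj")[2])
  expect_equal(hit$expanded_in, "b")
  # identical tables: nothing expands
  expect_true(all(test_expansion(a, a)$expanded_in == "none"))
  # below min_freq in both samples: significant but not called
  res2 <- test_expansion(a, b, min_freq = 0.2)
  expect_true(all(res2$expanded_in == "none"))
})

test_that("expansion testing is symmetric under sample swap", {
  withr::with_seed(13, {
    a <- make_table(sample(1:400, 30))
    b <- make_table(sample(1:400, 30), cdr3_aa = a$cdr3_aa)
    ab <- test_expansion(a, b)
    ba <- test_expansion(b, a)
    m <- match(ab$key, ba$key)
    expect_equal(ab$p_value, ba$p_value[m], tolerance = 1e-12)
    swapped <- c(a = "b", b = "a", none = "none")
    expect_identical(unname(swapped[ab$expanded_in]), ba$expanded_in[m])
  })
})

test_that("BH adjustment matches p.adjust exactly", {
  withr::with_seed(17, {
    for (i in 1:10) {
      p <- runif(sample(5:500, 1))
      expect_identical(p.adjust(p, "BH"), oracle_bh(p))
    }
  })
})

test_that("reference annotation joins exactly on CDR3 + allele-stripped V", {
  ref <- viral_reference()
  tab <- make_table(c(90L, 10L),
                    cdr3_aa = c("CASSAAAANEQFF", ref$cdr3[1]),
                    v_gene = c("TRBV5-1", sub("\\*.*", "", ref$v.segm[1])))
  ann <- annotate_against_reference(tab, ref)
  expect_equal(nrow(ann$hits), 1)
  expect_equal(ann$hits$epitope, ref$antigen.epitope[1])
  expect_equal(ann$annotated_read_fraction, 0.1)
  # empty reference: no hits
  empty <- annotate_against_reference(tab, ref[0, ])
  expect_equal(nrow(empty$hits), 0)
  expect_error(annotate_against_reference(tab, ref, fields = "nope"),
               class = "tilmotif_config_error")
})

test_that("spike-in read fractions are recovered exactly by annotation", {
  cfg <- small_config()
  tab <- generate_repertoire(cfg, "tumor", seed = 31)
  sp <- attr(tab, "spikes")
  man_frac <- sum(tab$count[paste(tab$cdr3_aa, tab$v_gene) %in%
                              paste(sp$cdr3_aa, sp$v_gene)]) / total_reads(tab)
  ann <- annotate_against_reference(tab, viral_reference())
  expect_equal(ann$annotated_read_fraction, man_frac)
  expect_gt(man_frac, 0)
})
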