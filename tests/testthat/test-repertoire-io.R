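test_that("simple TSV clonotype tables read with correct totals", {
  tab <- make_table(c(10L, 5L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(tab, path, "simple_tsv")
  got <- read_clonotype_table(path, "simple_tsv", sample_id = "s1")
  expect_equal(total_reads(got), 16)
  expect_equal(nrow(got), 3)
})

test_that("all dialects round-trip the same logical table", {
  tab <- make_table(c(12L, 7L, 3L, 2L), productive = c(TRUE, TRUE, FALSE, TRUE))
  for (d in c("simple_tsv", "airr", "immunoseq")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_clonotype_table(tab, path, d)
    got <- read_clonotype_table(path, d, sample_id = "s1")
    expect_equal(tibble::as_tibble(got), tibble::as_tibble(tab),
                 ignore_attr = TRUE, label = d)
  }
})

test_that("malformed rows are dropped with a warning, not fatally", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3_nt\tcdr3_aa\tv_gene\tj_gene\tcount\tproductive",
               "ACG\tCASSLGANEQFF\tTRBV5-1\tTRBJ1-1\t10\tT",
               "ACG\tCASSLGBNEQFF\tTRBV5-1\tTRBJ1-1\t0\tT",
               "ACG\t\tTRBV5-1\tTRBJ1-1\t5\tT"), path)
  expect_warning(got <- read_clonotype_table(path, "simple_tsv"),
                 "2 malformed")
  expect_equal(nrow(got), 1)
  expect_equal(attr(got, "filter_log")$read$n_dropped, 2)
})

test_that("missing required columns raise a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3_aa\tv_gene\tcount", "CASSLGANEQFF\tTRBV5-1\t3"), path)
  expect_error(read_clonotype_table(path, "simple_tsv"),
               class = "tilmotif_format_error", regexp = "j_gene")
  writeLines("x", paste0(path, ".empty"))
  expect_error(read_clonotype_table(paste0(path, ".empty"), "simple_tsv"),
               class = "tilmotif_empty_error")
})

test_that("productive filter removes non-functional rows and is idempotent", {
  tab <- make_table(c(5L, 4L, 3L, 2L),
                    productive = c(TRUE, TRUE, FALSE, TRUE))
  filt <- filter_productive(tab)
  expect_equal(nrow(filt), 3)
  expect_true(all(filt$productive))
  expect_equal(tibble::as_tibble(filter_productive(filt)),
               tibble::as_tibble(filt), ignore_attr = TRUE)
  # all-productive table passes through unchanged
  ok <- make_table(c(2L, 1L))
  expect_equal(tibble::as_tibble(filter_productive(ok)),
               tibble::as_tibble(ok), ignore_attr = TRUE)
})

test_that("a productive row with a stop codon violates the invariant", {
  df <- tibble::tibble(cdr3_aa = "CASS*GANEQFF", v_gene = "TRBV5-1",
                       j_gene = "TRBJ1-1", count = 3L, productive = TRUE)
  expect_error(clonotype_table(df, "s1"),
               class = "tilmotif_invariant_error")
})

test_that("shallow samples are excluded at the 10,000-read threshold", {
  tabs <- list(make_table(9999L), make_table(10000L), make_table(40000L))
  expect_message(kept <- exclude_small_samples(tabs), "excluded 1")
  expect_length(kept, 2)
  expect_length(exclude_small_samples(tabs, min_reads = 1), 3)
  expect_length(exclude_small_samples(list()), 0)
})

test_that("singleton removal keeps only multi-read clonotypes", {
  tab <- make_table(c(1L, 1L, 2L, 5L))
  out <- remove_singletons(tab)
  expect_equal(sort(out$count), c(2L, 5L))
  expect_equal(tibble::as_tibble(remove_singletons(out)),
               tibble::as_tibble(out), ignore_attr = TRUE)
  expect_warning(empty <- remove_singletons(make_table(c(1L, 1L))),
                 "singleton")
  expect_equal(nrow(empty), 0)
})

test_that("downsampling is an exact without-replacement subsample", {
  tab <- make_table(c(20L, 10L, 5L))
  same <- downsample_repertoire(tab, 35, seed = 1)
  expect_equal(total_reads(same), 35)
  expect_equal(sort(same$count), sort(tab$count))
  # single clonotype: forced outcome
  one <- downsample_repertoire(make_table(20L), 7, seed = 1)
  expect_equal(one$count, 7L)
  # support conservation and exact total
  ds <- downsample_repertoire(tab, 12, seed = 42)
  expect_equal(total_reads(ds), 12)
  expect_true(all(ds$cdr3_aa %in% tab$cdr3_aa))
  expect_true(all(ds$count <= tab$count[match(ds$cdr3_aa, tab$cdr3_aa)]))
  expect_error(downsample_repertoire(tab, 100),
               class = "tilmotif_downsample_error")
  # reproducible given seed
  expect_identical(downsample_repertoire(tab, 12, seed = 7),
                   downsample_repertoire(tab, 12, seed = 7))
})

test_that("downsampled counts follow the hypergeometric law", {
  tab <- make_table(c(50L, 50L))
  draws <- vapply(seq_len(3000), function(s) {
    ds <- downsample_repertoire(tab, 40, seed = s)
    ds$count[match(tab$cdr3_aa[1], ds$cdr3_aa)]
  }, numeric(1))
  mu <- 40 * 50 / 100
  v <- 40 * 0.5 * 0.5 * (100 - 40) / (100 - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / length(draws)))
})
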