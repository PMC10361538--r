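test_that("CDR3 trimming returns the central core with its 1-based offset", {
  tr <- trim_cdr3("CASSLAPGATNEKLFF")
  expect_equal(tr$core, "SLAPGATNEKL")
  expect_equal(tr$offset, 4L)
  # too short to leave a core: skip sentinel
  expect_true(is.na(trim_cdr3("CASSF", head = 3, tail = 2)$core))
  # no trimming is the identity
  expect_equal(trim_cdr3("SLAP", head = 0, tail = 0)$core, "SLAP")
})

test_that("motif enumeration produces all k-mers and wildcard variants", {
  plain <- enumerate_motifs("SLAP", motif_params(k_set = 3,
                                                 allow_wildcard = FALSE))
  expect_setequal(paste(plain$motif, plain$offset),
                  c("SLA 4", "LAP 5"))
  wild <- enumerate_motifs("SLAP", motif_params(k_set = 3))
  expect_setequal(paste(wild$motif, wild$offset),
                  c("SLA 4", "LAP 5", "S*AP 4", "SL*P 4"))
})

test_that("enumeration matches a brute-force oracle on random cores", {
  withr::with_seed(23, {
    for (i in 1:10) {
      core <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                           sample(5:12, 1), replace = TRUE), collapse = "")
      mine <- enumerate_motifs(core)
      oracle <- oracle_enumerate(core)
      expect_setequal(paste(mine$motif, mine$offset),
                      paste(oracle$motif, oracle$offset))
    }
  })
})

test_that("integer-coded enumeration agrees with the string enumeration", {
  withr::with_seed(29, {
    cores <- replicate(30, paste(sample(tilmotif:::aa_core_alphabet(),
                                        sample(4:12, 1), replace = TRUE),
                                 collapse = ""))
    p <- motif_params()
    str_enum <- tilmotif:::enumerate_motifs_bulk(cores, p)
    int_enum <- tilmotif:::enumerate_motifs_codes(cores, p)
    got <- unique(paste(tilmotif:::decode_motif(int_enum$code),
                        int_enum$offset, int_enum$idx))
    want <- unique(paste(str_enum$motif, str_enum$offset, str_enum$idx))
    expect_setequal(got, want)
    # encode/decode are inverse
    ms <- c("SLA", "S*AP", "QWERT")
    expect_identical(tilmotif:::decode_motif(tilmotif:::encode_motif(ms)), ms)
  })
})

test_that("wildcard motifs match carriers at their reported location", {
  # a published-style wildcard motif is carried by a matching CDR3
  expect_true(motif_matches("CSAGLAGEYEQYF", "SAGLAGE*E", offsets = 2,
                            head = 1))
  expect_false(motif_matches("CSAGLAGEYEQYF", "SAGLAGE*E", offsets = 3,
                             head = 1))
  # matching respects the trimmed region
  expect_false(motif_matches("CASSLAPF", "CAS", offsets = 1))
})

test_that("planted cohort motifs are discovered with correct cluster sizes", {
  withr::with_seed(37, {
    carriers <- paste0("CASS", replicate(10, paste(
      sample(tilmotif:::aa_core_alphabet(), 3, replace = TRUE),
      collapse = "")), "QWER", "NEQFF")
    bg <- fixture_cdr3s(50)
    cohort <- make_table(rep(5L, 60), cdr3_aa = c(carriers, bg),
                         v_gene = rep(c("TRBV5-1", "TRBV6-2"), 30))
    ref <- make_table(rep(3L, 80),
                      cdr3_aa = paste0("CASS", replicate(80, paste(
                        sample(setdiff(tilmotif:::aa_core_alphabet(), "Q"),
                               7, replace = TRUE), collapse = "")), "FF"))
    idx <- discover_cohort_motifs(list(cohort), ref)
    hit <- idx[idx$motif == "QWER", ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$cluster_size, 10L)
    expect_true(8L %in% hit$offsets[[1]])
    expect_equal(hit$reference_tcrs, 0)
    # two carriers only: filtered by the cluster-size rule
    two <- make_table(rep(5L, 52), cdr3_aa = c(carriers[1:2], bg))
    idx2 <- discover_cohort_motifs(list(two), ref)
    expect_false("QWER" %in% idx2$motif)
  })
})

test_that("discovery against itself finds nothing (fold is ~1)", {
  withr::with_seed(41, {
    tab <- generate_repertoire(small_config(), "tumor", seed = 41)
    idx <- discover_cohort_motifs(list(tab), tab)
    expect_equal(nrow(idx), 0)
  })
})

test_that("discovery is deterministic and round-trips through TSV", {
  cfg <- small_config()
  motifs <- withr::with_seed(1, tilmotif:::draw_planted_motifs(cfg))
  cohort <- lapply(1:3, function(i)
    generate_repertoire(cfg, "tumor", seed = 50 + i, motifs = motifs))
  ref <- build_motif_reference(default_reference_repertoire(500))
  i1 <- discover_cohort_motifs(cohort, ref, tissue = "tumor")
  i2 <- discover_cohort_motifs(cohort, ref, tissue = "tumor")
  expect_identical(tibble::as_tibble(i1), tibble::as_tibble(i2))
  expect_gt(nrow(i1), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_index(i1, path)
  back <- read_motif_index(path)
  expect_equal(back$motif, i1$motif)
  expect_equal(back$offsets, i1$offsets)
})
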