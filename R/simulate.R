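#' Synthetic-cohort generator configuration
#'
#' Parameters of the synthetic TCR-beta cohort generator. The defaults
#' describe a desk-scale cohort with the statistical structure the analysis
#' assumes: Zipf-distributed clone sizes, tissue-shared planted motifs
#' enriched in tumor samples (ten-fold over healthy kidney and blood),
#' dominant top clones in pre-expansion TIL cultures, designated clonal
#' expansions into the expansion product, viral-specific spike-in clones,
#' and phenotype-labelled single cells whose clonotypes carry planted
#' motifs.
#'
#' @param n_tumor,n_healthy,n_pb Samples per discovery compartment.
#' @param n_til_pairs Matched pre-expansion / expansion-product TIL pairs.
#' @param clones_per_sample Clonotypes per bulk sample.
#' @param til_clones Clonotypes per TIL sample (deeper backbone).
#' @param reads_per_sample Sequencing depth (templates) per sample.
#' @param zipf_exponent Clone-size power-law exponent (rank-frequency
#'   slope); 1.2 reproduces the dominance structure of clonal repertoires
#'   without claiming a measured value.
#' @param pre_rep_top_boost,pre_rep_top_n Pre-expansion TIL cultures are
#'   dominated by their top clones: the `pre_rep_top_n` largest clones are
#'   boosted by this factor before renormalisation.
#' @param cdr3_lengths CDR3 amino-acid lengths (uniform draw).
#' @param v_scaffolds,j_scaffolds Gene-segment scaffolds: tibbles with
#'   `v_gene`/`head` and `j_gene`/`tail` columns; CDR3s are built as
#'   conserved head + stochastic core + conserved tail. The core alphabet
#'   excludes cysteine.
#' @param n_motifs Number of planted motifs.
#' @param motif_widths,motif_wildcard Width (including any wildcard) and
#'   whether each motif carries one internal `*` wildcard.
#' @param motif_offsets Allowed planting start positions (1-based, full-CDR3
#'   coordinates); one is drawn per motif.
#' @param tumor_incidence Per-motif fraction of tumor-sample clones carrying
#'   the motif.
#' @param incidence_ratio Tumor-to-comparator incidence ratio (default 10).
#' @param til_incidence Per-motif carrier fraction in TIL backbones.
#' @param til_carrier_top If `TRUE`, TIL motif carriers sit among the
#'   high-rank clones, so carrier mass is highest in the pre-expansion
#'   culture.
#' @param til_carrier_ranks Rank window (excluding rank 1) in which TIL
#'   carriers are placed.
#' @param n_expansions Designated true expansions per TIL pair.
#' @param expansion_fold_range Frequency-ratio range for true expansions
#'   (all ratios at least 10).
#' @param expansion_pre_freq Pre-expansion frequency window of designated
#'   expansion clones (their product frequency then exceeds 0.1%).
#' @param rep_carrier_decay Multiplier on motif-carrier probabilities in the
#'   expansion product. 1 (default) leaves non-designated clones at
#'   identical underlying frequencies in both members of a pair (a clean
#'   null for expansion testing); values below 1 model rapid expansion
#'   favouring non-carrier clones and dilute motif burden in the product.
#' @param n_viral_spikes,viral_spike_freq,spike_tissues Spike-in clones
#'   drawn from the packaged synthetic viral reference, their per-clone
#'   frequency range, and the compartments receiving them.
#' @param n_contaminated Planted motifs also written into the control motif
#'   set (ground truth for pruning).
#' @param n_control_decoys Random non-planted motif strings padded into
#'   each control set.
#' @param n_cells Cells in the synthetic single-cell table.
#' @param phenotypes Phenotype labels.
#' @param phenotype_bias Probability that a motif-carrier cell receives its
#'   motif's designated phenotype (the rest spread uniformly).
#' @param cells_per_motif Range of supporting-cell counts per motif.
#' @param n_genes Background genes in the expression matrix (module-panel
#'   genes are added on top).
#' @param nb_mu,nb_size Negative-binomial background expression parameters.
#' @param module_effect Mean fold elevation of a panel's genes in its
#'   designated phenotype (log-normal spread); 1 disables the effect.
#' @param module_phenotypes Named list mapping signature panels to the
#'   phenotypes in which they are elevated.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_tumor = 20, n_healthy = 20, n_pb = 20, n_til_pairs = 7,
    clones_per_sample = 200, til_clones = 400, reads_per_sample = 30000,
    zipf_exponent = 1.2, pre_rep_top_boost = 3, pre_rep_top_n = 10,
    cdr3_lengths = 11:19,
    v_scaffolds = NULL, j_scaffolds = NULL,
    n_motifs = 6,
    motif_widths = c(4, 4, 4, 5, 4, 5),
    motif_wildcard = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    motif_offsets = 5:6,
    tumor_incidence = rep(c(0.06, 0.03), length.out = n_motifs),
    incidence_ratio = 10,
    til_incidence = 0.02, til_carrier_top = TRUE, til_carrier_ranks = 2:60,
    n_expansions = 3, expansion_fold_range = c(10, 20),
    expansion_pre_freq = c(2e-4, 5e-4),
    rep_carrier_decay = 1,
    n_viral_spikes = 3, viral_spike_freq = c(5e-4, 2e-3),
    spike_tissues = c("tumor", "pre_rep_til", "rep_til"),
    n_contaminated = 2, n_control_decoys = 10,
    n_cells = 2000,
    phenotypes = c("CD4_Tcytotoxic", "CD8_Texh", "CD8_Tpre_exh", "CD8_Teff",
                   "CD4_Treg", "CD8_Ttrm", "CD8_Teff2", "CD4_Tfh"),
    phenotype_bias = 0.9, cells_per_motif = c(20, 60),
    n_genes = 200, nb_mu = 0.5, nb_size = 2, module_effect = 3,
    module_phenotypes = list(
      cytotoxicity = c("CD4_Tcytotoxic", "CD8_Teff"),
      exhaustion = "CD8_Texh",
      tissue_resident = "CD8_Ttrm")) {
  if (is.null(v_scaffolds)) {
    v_scaffolds <- tibble(
      v_gene = c("TRBV5-1", "TRBV6-2", "TRBV7-9", "TRBV19", "TRBV27",
                 "TRBV28"),
      head = c("CASS", "CASR", "CASG", "CAST", "CASN", "CAWS"))
  }
  if (is.null(j_scaffolds)) {
    j_scaffolds <- tibble(
      j_gene = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3", "TRBJ2-7"),
      tail = c("TEAFF", "YGYTF", "NEQFF", "DTQYF", "YEQYF"))
  }
  cfg <- list(n_tumor = n_tumor, n_healthy = n_healthy, n_pb = n_pb,
              n_til_pairs = n_til_pairs,
              clones_per_sample = clones_per_sample, til_clones = til_clones,
              reads_per_sample = reads_per_sample,
              zipf_exponent = zipf_exponent,
              pre_rep_top_boost = pre_rep_top_boost,
              pre_rep_top_n = pre_rep_top_n,
              cdr3_lengths = cdr3_lengths,
              v_scaffolds = v_scaffolds, j_scaffolds = j_scaffolds,
              n_motifs = n_motifs,
              motif_widths = rep(motif_widths, length.out = n_motifs),
              motif_wildcard = rep(motif_wildcard, length.out = n_motifs),
              motif_offsets = motif_offsets,
              tumor_incidence = rep(tumor_incidence, length.out = n_motifs),
              incidence_ratio = incidence_ratio,
              til_incidence = til_incidence,
              til_carrier_top = til_carrier_top,
              til_carrier_ranks = til_carrier_ranks,
              n_expansions = n_expansions,
              expansion_fold_range = expansion_fold_range,
              expansion_pre_freq = expansion_pre_freq,
              rep_carrier_decay = rep_carrier_decay,
              n_viral_spikes = n_viral_spikes,
              viral_spike_freq = viral_spike_freq,
              spike_tissues = spike_tissues,
              n_contaminated = n_contaminated,
              n_control_decoys = n_control_decoys,
              n_cells = n_cells, phenotypes = phenotypes,
              phenotype_bias = phenotype_bias,
              cells_per_motif = cells_per_motif,
              n_genes = n_genes, nb_mu = nb_mu, nb_size = nb_size,
              module_effect = module_effect,
              module_phenotypes = module_phenotypes)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$tumor_incidence, cfg$til_incidence, cfg$phenotype_bias)
  if (any(probs < 0 | probs > 1)) {
    abort("all incidence/bias probabilities must lie in [0, 1]",
          class = "tilmotif_config_error")
  }
  if (cfg$zipf_exponent <= 0) {
    abort("Zipf exponent must be positive", class = "tilmotif_config_error")
  }
  tail_len <- max(nchar(cfg$j_scaffolds$tail))
  need <- max(cfg$motif_offsets) + max(cfg$motif_widths) - 1 + tail_len
  if (need > max(cfg$cdr3_lengths)) {
    abort(sprintf(paste0("planted motifs do not fit the CDR3 core: need ",
                         "length %d, max configured length %d"),
                  need, max(cfg$cdr3_lengths)),
          class = "tilmotif_config_error")
  }
  invisible(cfg)
}

zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

aa_core_alphabet <- function() setdiff(AA20, "C")

random_strings <- function(lengths, alphabet) {
  vapply(lengths, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# stochastic clone scaffolds: head + core + tail, cysteine only at position 1
random_clones <- function(n, cfg, min_length = NULL) {
  vi <- sample(nrow(cfg$v_scaffolds), n, replace = TRUE)
  ji <- sample(nrow(cfg$j_scaffolds), n, replace = TRUE)
  lens <- sample(cfg$cdr3_lengths, n, replace = TRUE)
  if (!is.null(min_length)) lens <- pmax(lens, min_length)
  heads <- cfg$v_scaffolds$head[vi]
  tails <- cfg$j_scaffolds$tail[ji]
  core_len <- lens - nchar(heads) - nchar(tails)
  if (any(core_len < 1)) {
    abort("configured CDR3 lengths leave no stochastic core",
          class = "tilmotif_config_error")
  }
  tibble(cdr3_aa = paste0(heads, random_strings(core_len, aa_core_alphabet()),
                          tails),
         v_gene = cfg$v_scaffolds$v_gene[vi],
         j_gene = cfg$j_scaffolds$j_gene[ji],
         length = nchar(heads) + core_len + nchar(tails))
}

random_nt <- function(aa_lengths) {
  random_strings(3 * aa_lengths, c("A", "C", "G", "T"))
}

# Draw the planted motif panel: strings over the non-cysteine alphabet with
# at most one internal wildcard, a fixed planting offset each, and the
# per-compartment incidences. Motif strings are pairwise distinct.
draw_planted_motifs <- function(cfg) {
  alphabet <- aa_core_alphabet()
  motifs <- character(cfg$n_motifs)
  wild_pos <- rep(NA_integer_, cfg$n_motifs)
  for (i in seq_len(cfg$n_motifs)) {
    repeat {
      w <- cfg$motif_widths[i]
      m <- paste(sample(alphabet, w, replace = TRUE), collapse = "")
      if (cfg$motif_wildcard[i]) {
        wild_pos[i] <- sample(2:(w - 1), 1)
        substr(m, wild_pos[i], wild_pos[i]) <- "*"
      }
      if (!m %in% motifs[seq_len(i - 1)]) break
    }
    motifs[i] <- m
  }
  tibble(motif = motifs,
         offset = sample(cfg$motif_offsets, cfg$n_motifs, replace = TRUE),
         width = cfg$motif_widths,
         wildcard_pos = wild_pos,
         incidence_tumor = cfg$tumor_incidence,
         incidence_comparator = cfg$tumor_incidence / cfg$incidence_ratio,
         incidence_til = rep(cfg$til_incidence, cfg$n_motifs),
         target_phenotype = rep(cfg$phenotypes,
                                length.out = cfg$n_motifs))
}

motif_incidence_for <- function(motifs, tissue) {
  switch(tissue,
         tumor = motifs$incidence_tumor,
         healthy_kidney = motifs$incidence_comparator,
         pb = motifs$incidence_comparator,
         pre_rep_til = motifs$incidence_til,
         rep_til = motifs$incidence_til,
         other = rep(0, nrow(motifs)))
}

# overwrite clone CDR3s so they carry `motif` at `offset`; lengthens clones
# whose tail would clash. Returns the modified clone tibble.
plant_into <- function(clones, idx, motif, offset, cfg) {
  w <- nchar(motif)
  tail_len <- nchar(cfg$j_scaffolds$tail[match(clones$j_gene[idx],
                                               cfg$j_scaffolds$j_gene)])
  need <- offset + w - 1 + tail_len
  short <- idx[clones$length[idx] < need]
  if (length(short) > 0) {
    # regrow short carriers with a feasible length
    vi <- match(clones$v_gene[short], cfg$v_scaffolds$v_gene)
    ji <- match(clones$j_gene[short], cfg$j_scaffolds$j_gene)
    heads <- cfg$v_scaffolds$head[vi]
    tails <- cfg$j_scaffolds$tail[ji]
    lo <- offset + w - 1 + nchar(tails)
    lens <- vapply(lo, function(l) {
      ok <- cfg$cdr3_lengths[cfg$cdr3_lengths >= l]
      if (length(ok) == 0) abort("motif longer than configured core region",
                                 class = "tilmotif_config_error")
      if (length(ok) == 1) ok else sample(ok, 1)
    }, numeric(1))
    core_len <- lens - nchar(heads) - nchar(tails)
    clones$cdr3_aa[short] <- paste0(
      heads, random_strings(core_len, aa_core_alphabet()), tails)
    clones$length[short] <- lens
  }
  # write the motif, filling any wildcard position per carrier
  for (i in idx) {
    filled <- motif
    if (grepl("*", filled, fixed = TRUE)) {
      p <- regexpr("*", filled, fixed = TRUE)[1]
      substr(filled, p, p) <- sample(aa_core_alphabet(), 1)
    }
    substr(clones$cdr3_aa[i], offset, offset + w - 1) <- filled
  }
  clones
}

strip_allele <- function(x) sub("\\*.*$", "", x)

#' Packaged synthetic viral reference TCRs
#'
#' A small, clearly synthetic VDJdb-style table of epitope-labelled CDR3s
#' (columns `cdr3`, `v.segm`, `antigen.epitope`, `antigen.species`) used for
#' spike-in generation and anti-viral annotation.
#' @return A tibble.
#' @export
viral_reference <- function() {
  if (is.null(.tilmotif_cache$viral_reference)) {
    path <- system.file("extdata", "synthetic_viral_reference.tsv",
                        package = "tilmotif", mustWork = TRUE)
    .tilmotif_cache$viral_reference <-
      readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  }
  .tilmotif_cache$viral_reference
}

.tilmotif_cache <- new.env(parent = emptyenv())

#' Generate one synthetic repertoire sample
#'
#' Clone sizes follow a Zipf law; CDR3s are conserved-head + stochastic
#' core + conserved-tail scaffolds; planted motifs are embedded at their
#' manifest offsets in a tissue-dependent fraction of clones (tumor-biased);
#' viral spike-in clones are added in the configured compartments; counts
#' are a multinomial draw of the configured depth. Deterministic given
#' `seed`.
#'
#' @param config A [generator_config()].
#' @param tissue Target compartment.
#' @param patient_id Patient label.
#' @param seed Integer seed (`NULL`: current RNG state).
#' @param motifs Planted-motif panel from the cohort manifest; `NULL` draws
#'   a fresh panel (standalone mode).
#' @param sample_id Sample label; defaults to `<patient>_<tissue>`.
#' @return A `clonotype_table` with `planted` and `spikes` truth attributes.
#' @export
generate_repertoire <- function(config, tissue, patient_id = "p1",
                                seed = NULL, motifs = NULL,
                                sample_id = NULL) {
  tissue <- match.arg(tissue, TISSUES)
  gen <- function() {
    if (is.null(motifs)) motifs <- draw_planted_motifs(config)
    n <- config$clones_per_sample
    probs <- zipf_probs(n, config$zipf_exponent)
    clones <- random_clones(n, config)
    inc <- motif_incidence_for(motifs, tissue)
    carrier_of <- rep(NA_integer_, n)
    for (i in seq_len(nrow(motifs))) {
      if (inc[i] <= 0) next
      n_carr <- rbinom(1, n, inc[i])
      if (tissue == "tumor" && round(inc[i] * n) >= 3) {
        n_carr <- max(n_carr, 3)  # discoverability floor
      }
      free <- which(is.na(carrier_of))
      n_carr <- min(n_carr, length(free))
      if (n_carr == 0) next
      idx <- sample(free, n_carr)
      clones <- plant_into(clones, idx, motifs$motif[i], motifs$offset[i],
                           config)
      carrier_of[idx] <- i
    }
    spikes <- NULL
    if (tissue %in% config$spike_tissues && config$n_viral_spikes > 0) {
      ref <- viral_reference()
      pick <- sample(nrow(ref), config$n_viral_spikes)
      sf <- runif(config$n_viral_spikes, config$viral_spike_freq[1],
                  config$viral_spike_freq[2])
      spikes <- tibble(cdr3_aa = ref$cdr3[pick],
                       v_gene = strip_allele(ref$v.segm[pick]),
                       j_gene = strip_allele(ref$j.segm[pick]),
                       length = nchar(ref$cdr3[pick]),
                       epitope = ref$antigen.epitope[pick],
                       species = ref$antigen.species[pick],
                       freq = sf)
      probs <- c(probs * (1 - sum(sf)), sf)
      clones <- bind_rows(clones,
                          spikes[, c("cdr3_aa", "v_gene", "j_gene", "length")])
      carrier_of <- c(carrier_of, rep(NA_integer_, nrow(spikes)))
    }
    counts <- rmultinom(1, config$reads_per_sample, probs)[, 1]
    keep <- counts > 0
    tab <- clonotype_table(
      tibble(cdr3_nt = random_nt(clones$length[keep]),
             cdr3_aa = clones$cdr3_aa[keep],
             v_gene = clones$v_gene[keep],
             j_gene = clones$j_gene[keep],
             count = counts[keep], productive = TRUE),
      sample_id = sample_id %||% paste(patient_id, tissue, sep = "_"),
      tissue = tissue, patient_id = patient_id)
    attr(tab, "planted") <- tibble(
      motif = motifs$motif[carrier_of[keep][!is.na(carrier_of[keep])]],
      offset = motifs$offset[carrier_of[keep][!is.na(carrier_of[keep])]],
      cdr3_aa = clones$cdr3_aa[keep][!is.na(carrier_of[keep])],
      v_gene = clones$v_gene[keep][!is.na(carrier_of[keep])])
    if (!is.null(spikes)) {
      spike_keep <- keep[n + seq_len(nrow(spikes))]
      attr(tab, "spikes") <- spikes[spike_keep, ]
    }
    tab
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a matched pre-expansion / expansion-product TIL pair
#'
#' Both samples share one clone backbone. The pre-expansion culture is
#' dominated by its top clones (top-`pre_rep_top_n` boost); motif carriers
#' sit in the high-rank window when `til_carrier_top` is on. The expansion
#' product keeps every non-designated clone at an identical underlying
#' frequency (the clean null for expansion testing): designated expansion
#' clones are multiplied by a fold drawn from `expansion_fold_range`, and
#' the added mass is balanced by zeroing a set of sub-threshold sink clones
#' (all below 0.05% in frequency, so they can never satisfy the 0.1%
#' expansion rule) — no global renormalisation touches the null clones.
#' With `rep_carrier_decay < 1` the product instead models expansion
#' favouring non-carrier clones; carrier mass is decayed and the whole
#' vector renormalised (used for structural cohorts, not for expansion-test
#' calibration).
#'
#' @inheritParams generate_repertoire
#' @return A list: `pre_rep` and `rep` (`clonotype_table`s) and `truth`, a
#'   tibble of designated expansions (`key`, underlying `pre_freq`,
#'   `rep_freq`, `fold`, `direction = "rep"`).
#' @export
generate_paired_til <- function(config, patient_id = "p1", seed = NULL,
                                motifs = NULL) {
  gen <- function() {
    if (is.null(motifs)) motifs <- draw_planted_motifs(config)
    n <- config$til_clones
    base <- zipf_probs(n, config$zipf_exponent)
    boost <- rep(1, n)
    boost[seq_len(min(config$pre_rep_top_n, n))] <- config$pre_rep_top_boost
    pre <- base * boost
    pre <- pre / sum(pre)
    clones <- random_clones(n, config)
    carrier_of <- rep(NA_integer_, n)
    rank_pool <- if (config$til_carrier_top) {
      intersect(config$til_carrier_ranks, seq_len(n))
    } else seq_len(n)
    for (i in seq_len(nrow(motifs))) {
      inc <- motifs$incidence_til[i]
      if (inc <= 0) next
      n_carr <- max(3, rbinom(1, n, inc))
      free <- setdiff(rank_pool, which(!is.na(carrier_of)))
      n_carr <- min(n_carr, length(free))
      if (n_carr == 0) next
      idx <- sample(free, n_carr)
      clones <- plant_into(clones, idx, motifs$motif[i], motifs$offset[i],
                           config)
      carrier_of[idx] <- i
    }
    # spike-ins shared by both members at identical frequency (null clones)
    spikes <- NULL
    if (all(c("pre_rep_til", "rep_til") %in% config$spike_tissues) &&
        config$n_viral_spikes > 0) {
      ref <- viral_reference()
      pick <- sample(nrow(ref), config$n_viral_spikes)
      sf <- runif(config$n_viral_spikes, config$viral_spike_freq[1],
                  config$viral_spike_freq[2])
      spikes <- tibble(cdr3_aa = ref$cdr3[pick],
                       v_gene = strip_allele(ref$v.segm[pick]),
                       j_gene = strip_allele(ref$j.segm[pick]),
                       length = nchar(ref$cdr3[pick]),
                       epitope = ref$antigen.epitope[pick],
                       species = ref$antigen.species[pick],
                       freq = sf)
      pre <- c(pre * (1 - sum(sf)), sf)
      clones <- bind_rows(clones,
                          spikes[, c("cdr3_aa", "v_gene", "j_gene", "length")])
      carrier_of <- c(carrier_of, rep(NA_integer_, nrow(spikes)))
    }
    n_all <- length(pre)
    is_carrier <- !is.na(carrier_of)
    is_spike <- seq_len(n_all) > n
    # designated expansions: small non-carrier, non-spike clones
    small <- which(pre <= 5e-4 & !is_carrier & !is_spike)
    eligible <- small[pre[small] >= config$expansion_pre_freq[1] &
                        pre[small] <= config$expansion_pre_freq[2]]
    if (length(eligible) < config$n_expansions) {
      abort("not enough clones in the expansion frequency window",
            class = "tilmotif_config_error")
    }
    targets <- sample(eligible, config$n_expansions)
    folds <- runif(config$n_expansions, config$expansion_fold_range[1],
                   config$expansion_fold_range[2])
    rep_p <- pre
    if (config$rep_carrier_decay < 1) {
      rep_p[is_carrier] <- rep_p[is_carrier] * config$rep_carrier_decay
    }
    rep_p[targets] <- rep_p[targets] * folds
    excess <- sum(rep_p) - 1
    if (excess > 0) {
      sinks <- sample(setdiff(small, targets))
      cum <- cumsum(rep_p[sinks])
      if (cum[length(cum)] < excess) {
        abort("sink clones cannot absorb the planted expansion mass",
              class = "tilmotif_config_error")
      }
      k <- which(cum >= excess)[1]
      if (k > 1) rep_p[sinks[seq_len(k - 1)]] <- 0
      rep_p[sinks[k]] <- cum[k] - excess
    } else if (excess < 0) {
      rep_p <- rep_p / sum(rep_p)
    }
    truth <- tibble(
      key = paste(clones$cdr3_aa[targets], clones$v_gene[targets],
                  clones$j_gene[targets], sep = "|"),
      pre_freq = pre[targets],
      rep_freq = rep_p[targets],
      fold = rep_p[targets] / pre[targets],
      direction = "rep")
    # a degenerate fold distribution plants no real expansions
    truth <- truth[truth$fold > 1 + 1e-9, ]
    nts <- random_nt(clones$length)
    build <- function(p, tissue) {
      counts <- rmultinom(1, config$reads_per_sample, p)[, 1]
      keep <- counts > 0
      tab <- clonotype_table(
        tibble(cdr3_nt = nts[keep], cdr3_aa = clones$cdr3_aa[keep],
               v_gene = clones$v_gene[keep], j_gene = clones$j_gene[keep],
               count = counts[keep], productive = TRUE),
        sample_id = paste(patient_id, tissue, sep = "_"),
        tissue = tissue, patient_id = patient_id)
      attr(tab, "planted") <- tibble(
        motif = motifs$motif[carrier_of[keep][!is.na(carrier_of[keep])]],
        offset = motifs$offset[carrier_of[keep][!is.na(carrier_of[keep])]],
        cdr3_aa = clones$cdr3_aa[keep][!is.na(carrier_of[keep])],
        v_gene = clones$v_gene[keep][!is.na(carrier_of[keep])])
      if (!is.null(spikes)) {
        attr(tab, "spikes") <- spikes[counts[n + seq_len(nrow(spikes))] > 0, ]
      }
      tab
    }
    list(pre_rep = build(pre, "pre_rep_til"),
         rep = build(rep_p, "rep_til"),
         truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic single-cell clonotype-phenotype table
#'
#' Cells carry clonotypes; clonotypes of planted-motif carriers are assigned
#' their motif's designated phenotype with probability `phenotype_bias`
#' (remainder uniform over the other labels); background cells draw
#' phenotypes uniformly. The expression matrix is a negative-binomial
#' background (per-gene log-normal baselines) with the signature-panel genes
#' elevated by a log-normal factor of mean `module_effect` in their
#' designated phenotypes, returned log1p-transformed.
#'
#' @inheritParams generate_repertoire
#' @return A list: `cells` (tibble of `cell_id`, `clonotype_key` (nucleotide
#'   key), `cdr3_nt`, `cdr3_aa`, `v_gene`, `phenotype`), `expression`
#'   (genes x cells matrix, log1p scale) and `truth` (per-motif designated
#'   phenotype and supporting-cell count).
#' @export
generate_cell_table <- function(config, seed = NULL, motifs = NULL) {
  gen <- function() {
    if (is.null(motifs)) motifs <- draw_planted_motifs(config)
    phenos <- config$phenotypes
    cells <- list()
    truth <- list()
    for (i in seq_len(nrow(motifs))) {
      n_m <- sample(config$cells_per_motif[1]:config$cells_per_motif[2], 1)
      k <- max(2, ceiling(n_m / 10))
      carr <- random_clones(k, config)
      carr <- plant_into(carr, seq_len(k), motifs$motif[i],
                         motifs$offset[i], config)
      carr$cdr3_nt <- random_nt(carr$length)
      assign <- sample(k, n_m, replace = TRUE, prob = zipf_probs(k, 1))
      is_target <- runif(n_m) < config$phenotype_bias
      ph <- ifelse(is_target, motifs$target_phenotype[i],
                   sample(setdiff(phenos, motifs$target_phenotype[i]),
                          n_m, replace = TRUE))
      cells[[i]] <- tibble(cdr3_nt = carr$cdr3_nt[assign],
                           cdr3_aa = carr$cdr3_aa[assign],
                           v_gene = carr$v_gene[assign],
                           phenotype = ph)
      truth[[i]] <- tibble(motif = motifs$motif[i],
                           offset = motifs$offset[i],
                           target_phenotype = motifs$target_phenotype[i],
                           n_cells = n_m)
    }
    n_bg <- config$n_cells - sum(vapply(cells, nrow, integer(1)))
    if (n_bg < 0) {
      abort("n_cells too small for the configured motif carriage",
            class = "tilmotif_config_error")
    }
    if (n_bg > 0) {
      k_bg <- max(2, ceiling(n_bg / 3))
      bg <- random_clones(k_bg, config)
      # keep background clear of the planted patterns at their offsets
      for (i in seq_len(nrow(motifs))) {
        repeat {
          hit <- motif_matches(bg$cdr3_aa, motifs$motif[i],
                               motifs$offset[i])
          if (!any(hit)) break
          redo <- random_clones(sum(hit), config)
          bg$cdr3_aa[hit] <- redo$cdr3_aa
          bg$v_gene[hit] <- redo$v_gene
          bg$j_gene[hit] <- redo$j_gene
          bg$length[hit] <- redo$length
        }
      }
      bg$cdr3_nt <- random_nt(bg$length)
      assign <- sample(k_bg, n_bg, replace = TRUE,
                       prob = zipf_probs(k_bg, 0.8))
      cells[[length(cells) + 1]] <- tibble(
        cdr3_nt = bg$cdr3_nt[assign], cdr3_aa = bg$cdr3_aa[assign],
        v_gene = bg$v_gene[assign],
        phenotype = sample(phenos, n_bg, replace = TRUE))
    }
    cells <- bind_rows(cells)
    cells <- cells[sample(nrow(cells)), ]
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
    cells$clonotype_key <- cells$cdr3_nt
    cells <- cells[, c("cell_id", "clonotype_key", "cdr3_nt", "cdr3_aa",
                       "v_gene", "phenotype")]
    # expression matrix
    panels <- signature_panels()
    genes <- c(unique(unlist(panels)), sprintf("G%03d", seq_len(config$n_genes)))
    mu <- rlnorm(length(genes), log(config$nb_mu), 0.7)
    names(mu) <- genes
    n_cells <- nrow(cells)
    counts <- matrix(rnbinom(length(genes) * n_cells,
                             mu = rep(mu, times = n_cells),
                             size = config$nb_size),
                     nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, cells$cell_id))
    if (config$module_effect != 1) {
      for (panel in names(config$module_phenotypes)) {
        target_ph <- config$module_phenotypes[[panel]]
        cols <- which(cells$phenotype %in% target_ph)
        if (length(cols) == 0) next
        for (g in panels[[panel]]) {
          eff <- rlnorm(length(cols), log(config$module_effect), 0.2)
          counts[g, cols] <- rnbinom(length(cols), mu = mu[g] * eff,
                                     size = config$nb_size)
        }
      }
    }
    list(cells = cells, expression = log1p(counts),
         truth = bind_rows(truth))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a full synthetic cohort with ground-truth manifest
#'
#' Generates the tumor / healthy-kidney / peripheral-blood discovery
#' compartments, matched TIL pairs, the single-cell table, and control motif
#' sets (a contaminated subset of the planted motifs plus decoys), together
#' with a manifest sufficient to recompute every truth label.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param with_til,with_cells Generate the TIL pairs / the cell table
#'   (switch off for cohorts used only for motif discovery).
#' @return A list of class `til_cohort`: `tumor`, `healthy`, `pb` (lists of
#'   `clonotype_table`s), `til` (list of [generate_paired_til()] results),
#'   `cells` (or `NULL`), and `manifest` (class `cohort_manifest`).
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1,
                            with_til = TRUE, with_cells = TRUE) {
  motifs <- withr::with_seed(seed, draw_planted_motifs(config))
  pat <- function(i) sprintf("pt%03d", i)
  tumor <- lapply(seq_len(config$n_tumor), function(i)
    generate_repertoire(config, "tumor", pat(i), seed = seed + 1000 + i,
                        motifs = motifs))
  healthy <- lapply(seq_len(config$n_healthy), function(i)
    generate_repertoire(config, "healthy_kidney", pat(i),
                        seed = seed + 2000 + i, motifs = motifs))
  pb <- lapply(seq_len(config$n_pb), function(i)
    generate_repertoire(config, "pb", pat(i), seed = seed + 3000 + i,
                        motifs = motifs))
  til <- if (with_til) {
    lapply(seq_len(config$n_til_pairs), function(i)
      generate_paired_til(config, pat(i), seed = seed + 4000 + i,
                          motifs = motifs))
  } else list()
  cells <- if (with_cells) {
    generate_cell_table(config, seed = seed + 5000, motifs = motifs)
  } else NULL
  controls <- withr::with_seed(seed + 6000, {
    contaminated <- if (config$n_contaminated > 0) {
      sample(motifs$motif, min(config$n_contaminated, nrow(motifs)))
    } else character(0)
    decoy <- function(n) {
      out <- character(0)
      while (length(out) < n) {
        cand <- random_strings(rep(4, n), aa_core_alphabet())
        out <- unique(c(out, setdiff(cand, motifs$motif)))
      }
      out[seq_len(n)]
    }
    list(validation_cohort = c(contaminated, decoy(config$n_control_decoys)),
         viral_motifs = decoy(config$n_control_decoys))
  })
  contaminated <- intersect(controls$validation_cohort, motifs$motif)
  manifest <- structure(list(
    planted_motifs = motifs,
    true_expansions = lapply(til, function(p) p$truth),
    viral_spikes = c(
      lapply(tumor, function(t) attr(t, "spikes")),
      unlist(lapply(til, function(p)
        list(attr(p$pre_rep, "spikes"), attr(p$rep, "spikes"))),
        recursive = FALSE)),
    contamination = contaminated,
    control_sets = controls,
    cell_truth = if (with_cells) cells$truth else NULL,
    seed = seed,
    config = config), class = "cohort_manifest")
  structure(list(tumor = tumor, healthy = healthy, pb = pb, til = til,
                 cells = cells, manifest = manifest),
            class = "til_cohort")
}

#' Audit a synthetic cohort against its manifest
#'
#' Self-consistency checks that every manifest quantity is recoverable from
#' the generated tables: each planted motif is carried by at least three
#' distinct TCRs in at least one tumor sample (so it is discoverable under
#' the cluster-size filter); spike-in read fractions recomputed from the
#' tables match exact annotation against the packaged viral reference; and
#' every designated expansion clone is present in its pair.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
audit_cohort <- function(cohort) {
  man <- cohort$manifest
  checks <- list()
  # planted motifs discoverable
  max_carriers <- vapply(seq_len(nrow(man$planted_motifs)), function(i) {
    max(vapply(cohort$tumor, function(t) {
      hit <- motif_matches(t$cdr3_aa, man$planted_motifs$motif[i],
                           man$planted_motifs$offset[i])
      length(unique(paste(t$cdr3_aa[hit], t$v_gene[hit])))
    }, numeric(1)))
  }, numeric(1))
  checks$planted_carriers <- tibble(
    check = "planted motifs have >=3 distinct carriers in some tumor sample",
    pass = all(max_carriers >= 3),
    detail = paste(max_carriers, collapse = ","))
  # spikes recomputable by exact annotation
  ref <- viral_reference()
  spike_ok <- vapply(cohort$tumor, function(t) {
    sp <- attr(t, "spikes")
    ann <- annotate_against_reference(t, ref)
    man_frac <- if (is.null(sp) || nrow(sp) == 0) 0 else {
      key <- paste(t$cdr3_aa, t$v_gene)
      sum(t$count[key %in% paste(sp$cdr3_aa, sp$v_gene)]) / total_reads(t)
    }
    isTRUE(all.equal(ann$annotated_read_fraction, man_frac))
  }, logical(1))
  checks$spikes <- tibble(
    check = "spike read fractions equal exact-annotation fractions",
    pass = all(spike_ok), detail = sprintf("%d/%d", sum(spike_ok),
                                           length(spike_ok)))
  # designated expansions present in their pairs
  if (length(cohort$til) > 0) {
    exp_ok <- vapply(cohort$til, function(p) {
      keys <- clonotype_keys(p$rep, "aa_vj")
      all(p$truth$key %in% keys)
    }, logical(1))
    checks$expansions <- tibble(
      check = "designated expansion clones present in expansion product",
      pass = all(exp_ok), detail = sprintf("%d/%d", sum(exp_ok),
                                           length(exp_ok)))
  }
  bind_rows(checks)
}

#' Score motif discovery against the manifest
#'
#' Sensitivity: the fraction of planted motifs (excluding those planted into
#' control sets, whose fate is pruning) recovered with status `exclusive` or
#' `enriched` at an offset set containing the planted offset.
#' False-discovery proportion: the fraction of the final associated set
#' (exclusive or enriched after pruning) whose support does not come from
#' planted carriers — a discovered motif is *planted-derived* when the
#' majority of its carrier TCRs in the pooled tumor cohort are manifest
#' carrier clones (sub-patterns and scaffold-overhang variants of a planted
#' motif ride on exactly the planted carriers, so they are recovered signal,
#' not false discoveries; chance background motifs draw carriers from the
#' whole repertoire and fail the majority rule). Pruning correctness: the
#' pruned motifs are exactly the discovered motifs contaminating the control
#' sets.
#'
#' @param associations A pruned `motif_association` tibble.
#' @param manifest The cohort manifest.
#' @param tumor_samples The cohort's tumor `clonotype_table`s (carrying the
#'   generator's per-sample carrier truth attributes).
#' @return A list: `sensitivity`, `fdp`, `n_recovered`, `n_plantable`,
#'   `n_false`, `n_associated`, `pruning_exact` (logical).
#' @export
score_motif_recovery <- function(associations, manifest, tumor_samples) {
  planted <- manifest$planted_motifs
  contaminated <- manifest$contamination
  scoreable <- planted[!planted$motif %in% contaminated, ]
  recovered <- vapply(seq_len(nrow(scoreable)), function(i) {
    j <- which(associations$motif == scoreable$motif[i])
    length(j) == 1 &&
      associations$status[j] %in% c("exclusive", "enriched") &&
      scoreable$offset[i] %in% associations$offsets[[j]]
  }, logical(1))
  carriers_truth <- unique(unlist(lapply(tumor_samples, function(t) {
    pl <- attr(t, "planted")
    if (is.null(pl) || nrow(pl) == 0) character(0)
    else paste(pl$cdr3_aa, pl$v_gene, sep = "|")
  })))
  assoc <- associations[associations$status %in% c("exclusive", "enriched"), ]
  derived <- vapply(seq_len(nrow(assoc)), function(i) {
    keys <- unlist(lapply(tumor_samples, function(t) {
      hit <- motif_matches(t$cdr3_aa, assoc$motif[i], assoc$offsets[[i]])
      paste(t$cdr3_aa[hit], t$v_gene[hit], sep = "|")
    }))
    keys <- unique(keys)
    length(keys) > 0 && mean(keys %in% carriers_truth) >= 0.5
  }, logical(1))
  pruned <- associations$motif[associations$status == "pruned"]
  discovered_contam <- intersect(contaminated, associations$motif)
  list(sensitivity = mean(recovered),
       fdp = if (nrow(assoc) == 0) 0 else mean(!derived),
       n_recovered = sum(recovered),
       n_plantable = nrow(scoreable),
       n_false = sum(!derived),
       n_associated = nrow(assoc),
       pruning_exact = setequal(pruned, discovered_contam))
}

#' Score expansion calls against a pair's truth list
#'
#' @param results A [test_expansion()] tibble from
#'   `test_expansion(pre_rep, rep)`.
#' @param truth The pair's manifest truth tibble.
#' @return A list: `n_true`, `n_flagged`, `n_hit` (true expansions flagged
#'   in the correct direction), `n_false` (flagged clones not in truth).
#' @export
score_expansion <- function(results, truth) {
  flagged <- results[results$expanded_in != "none", ]
  hit <- truth$key %in% flagged$key[flagged$expanded_in == "b"]
  list(n_true = nrow(truth),
       n_flagged = nrow(flagged),
       n_hit = sum(hit),
       n_false = sum(!flagged$key %in% truth$key))
}

#' Write a synthetic cohort to disk
#'
#' One AIRR TSV per sample plus a JSON manifest (planted motifs, true
#' expansions, spike identities, seeds and generator parameters).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(tab) {
    write_clonotype_table(tab, file.path(dir, paste0(attr(tab, "sample_id"),
                                                     ".airr.tsv")), "airr")
  }
  for (t in cohort$tumor) dump(t)
  for (t in cohort$healthy) dump(t)
  for (t in cohort$pb) dump(t)
  for (p in cohort$til) { dump(p$pre_rep); dump(p$rep) }
  if (!is.null(cohort$cells)) {
    readr::write_tsv(cohort$cells$cells, file.path(dir, "cells.tsv"),
                     progress = FALSE)
  }
  man <- cohort$manifest
  jsonlite::write_json(
    list(planted_motifs = man$planted_motifs,
         true_expansions = man$true_expansions,
         contamination = man$contamination,
         control_sets = man$control_sets,
         seed = man$seed,
         generator_params = man$config[!vapply(man$config, is.data.frame,
                                               logical(1))]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
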