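#' Default pipeline thresholds
#'
#' The filter and test thresholds used across the pipeline: minimum sample
#' depth 10,000 reads; expansion rule adjusted p < 0.05 with frequency >=
#' 0.1% in either sample; motif cluster size >= 3 and length >= 3 with
#' ten-fold enrichment; tumor-enrichment log2 fold change > 1; burden
#' filters (non-singleton blood, >= 100 reads, 40,000-read downsampling for
#' deep external cohorts); >= 5 supporting cells per phenotype call.
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(min_reads = 10000, alpha = 0.05, min_freq = 0.001,
       min_cluster = 3, min_fold = 10, min_log2fc = 1.0,
       burden_min_reads = 100, burden_downsample = 40000,
       min_cells = 5)
}

#' Run the end-to-end motif pipeline
#'
#' Orchestrates filtering, diversity, expansion testing, motif discovery,
#' tumor-association classification, control pruning, burden quantification
#' and phenotype assignment over a cohort, writing one TSV per stage plus a
#' JSON provenance record into `out_dir`. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A named list (or path to a YAML/JSON file) with elements:
#'   `out_dir` (required); `seed` (default 1); `generator` (list of
#'   [generator_config()] overrides used to simulate the cohort when no
#'   `cohort` is supplied); `cohort` (a [simulate_cohort()] result, only
#'   when calling programmatically); `stages` (subset of `filter`,
#'   `diversity`, `expansion`, `discovery`, `association`, `burden`,
#'   `phenotype`; default all); `thresholds` (overrides of
#'   [pipeline_thresholds()]); `control_sets` (named list of motif-string
#'   vectors; defaults to the cohort manifest's control sets).
#' @return Invisibly, a list with the per-stage results, the written file
#'   paths and a `report` tibble of completed stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$out_dir)) {
    abort("config$out_dir is required", class = "tilmotif_config_error")
  }
  all_stages <- c("filter", "diversity", "expansion", "discovery",
                  "association", "burden", "phenotype")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "tilmotif_config_error")
  }
  th <- modifyList(pipeline_thresholds(), config$thresholds %||% list())
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- config$cohort
  if (is.null(cohort)) {
    gen_cfg <- do.call(generator_config, config$generator %||% list())
    cohort <- simulate_cohort(gen_cfg, seed = seed,
                              with_til = TRUE, with_cells = TRUE)
  }
  res <- list()
  paths <- character(0)
  done <- character(0)
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "tilmotif_stage_error")
    })
    done <<- c(done, name)
  }

  bulk <- function() c(cohort$tumor, cohort$healthy, cohort$pb,
                       unlist(lapply(cohort$til, function(p)
                         list(p$pre_rep, p$rep)), recursive = FALSE))

  run_stage("filter", function() {
    filt <- lapply(bulk(), filter_productive)
    filt <- exclude_small_samples(filt, th$min_reads)
    write_filter_log(filt, file.path(out_dir, "filter_log.json"))
    paths <<- c(paths, file.path(out_dir, "filter_log.json"))
    res$filtered <<- filt
  })
  samples <- res$filtered %||% bulk()

  run_stage("diversity", function() {
    div_full <- cohort_diversity(samples)
    div_ds <- cohort_diversity(samples, downsample_within_group = TRUE,
                               seed = seed + 100)
    readr::write_tsv(div_full, file.path(out_dir, "diversity_full.tsv"),
                     progress = FALSE)
    readr::write_tsv(div_ds, file.path(out_dir, "diversity_downsampled.tsv"),
                     progress = FALSE)
    paths <<- c(paths, file.path(out_dir, c("diversity_full.tsv",
                                            "diversity_downsampled.tsv")))
    res$diversity <<- div_full
    res$diversity_downsampled <<- div_ds
  })

  run_stage("expansion", function() {
    if (length(cohort$til) == 0) {
      abort("expansion stage requested but the cohort has no TIL pairs",
            class = "tilmotif_config_error")
    }
    res$expansion <<- lapply(cohort$til, function(p) {
      ex <- test_expansion(p$pre_rep, p$rep, alpha = th$alpha,
                           min_freq = th$min_freq)
      f <- file.path(out_dir, sprintf(
        "expansion_%s.tsv", attr(p$pre_rep, "patient_id")))
      readr::write_tsv(ex, f, progress = FALSE)
      paths <<- c(paths, f)
      ex
    })
  })

  run_stage("discovery", function() {
    if (length(cohort$tumor) == 0) {
      abort("discovery stage requires a tumor cohort",
            class = "tilmotif_config_error")
    }
    ref <- build_motif_reference(default_reference_repertoire())
    idx <- list(
      tumor = discover_cohort_motifs(cohort$tumor, ref,
                                     min_cluster = th$min_cluster,
                                     min_fold = th$min_fold,
                                     alpha = th$alpha, tissue = "tumor"),
      healthy_kidney = discover_cohort_motifs(cohort$healthy, ref,
                                              min_cluster = th$min_cluster,
                                              min_fold = th$min_fold,
                                              alpha = th$alpha,
                                              tissue = "healthy_kidney"),
      pb = discover_cohort_motifs(cohort$pb, ref,
                                  min_cluster = th$min_cluster,
                                  min_fold = th$min_fold,
                                  alpha = th$alpha, tissue = "pb"))
    for (nm in names(idx)) {
      f <- file.path(out_dir, sprintf("motif_index_%s.tsv", nm))
      write_motif_index(idx[[nm]], f)
      paths <<- c(paths, f)
    }
    res$indexes <<- idx
  })

  run_stage("association", function() {
    if (is.null(res$indexes)) {
      abort("association stage requires discovery (tumor cohort missing?)",
            class = "tilmotif_config_error")
    }
    assoc <- classify_motifs(
      res$indexes$tumor,
      res$indexes[c("healthy_kidney", "pb")],
      cohort$tumor,
      list(healthy_kidney = cohort$healthy, pb = cohort$pb),
      alpha = th$alpha, min_log2fc = th$min_log2fc)
    controls <- config$control_sets %||%
      cohort$manifest$control_sets %||% list()
    assoc <- prune_against_controls(assoc, controls)
    out <- as_tibble(assoc)
    out$offsets <- vapply(out$offsets, paste, character(1), collapse = ",")
    out$pruned_by <- vapply(out$pruned_by, paste, character(1),
                            collapse = ",")
    out$freqs <- NULL
    f <- file.path(out_dir, "associations.tsv")
    readr::write_tsv(out, f, progress = FALSE)
    paths <<- c(paths, f)
    res$associations <<- assoc
  })

  run_stage("burden", function() {
    if (is.null(res$associations)) {
      abort("burden stage requires association results",
            class = "tilmotif_config_error")
    }
    motifs <- associated_motifs(res$associations)
    if (nrow(motifs) == 0) {
      warn("no associated motifs; burden stage skipped")
      return(invisible(NULL))
    }
    ref <- viral_reference()
    rows <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      s <- apply_tissue_filters(
        s, drop_singletons = attr(s, "tissue") == "pb",
        min_reads = th$burden_min_reads,
        downsample_to = th$burden_downsample, seed = seed + 200 + i)
      if (is.null(s)) return(NULL)
      b <- motif_burden(s, motifs)
      b$antiviral_fraction <-
        annotate_against_reference(s, ref)$annotated_read_fraction
      b$viral_ratio <- if (b$antiviral_fraction > 0) {
        b$fraction_reads / b$antiviral_fraction
      } else NA_real_
      b$per_motif <- NULL
      b
    })
    burden <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
    f <- file.path(out_dir, "burden.tsv")
    readr::write_tsv(burden, f, progress = FALSE)
    paths <<- c(paths, f)
    res$burden <<- burden
  })

  run_stage("phenotype", function() {
    if (is.null(cohort$cells)) {
      abort("phenotype stage requested but the cohort has no cell table",
            class = "tilmotif_config_error")
    }
    if (is.null(res$associations)) {
      abort("phenotype stage requires association results",
            class = "tilmotif_config_error")
    }
    motifs <- associated_motifs(res$associations)
    calls <- assign_motif_phenotypes(cohort$cells$cells, motifs,
                                     min_cells = th$min_cells)
    flat <- as_tibble(calls)
    flat$per_phenotype <- NULL
    f <- file.path(out_dir, "phenotype.tsv")
    readr::write_tsv(flat, f, progress = FALSE)
    paths <<- c(paths, f)
    scores <- lapply(names(signature_panels()), function(nm) {
      module_score(cohort$cells$expression, signature_panels()[[nm]],
                   seed = seed + 300)
    })
    sc <- tibble(cell_id = colnames(cohort$cells$expression))
    for (i in seq_along(scores)) {
      sc[[names(signature_panels())[i]]] <- scores[[i]]
    }
    f2 <- file.path(out_dir, "module_scores.tsv")
    readr::write_tsv(sc, f2, progress = FALSE)
    paths <<- c(paths, f2)
    res$phenotype <<- calls
    res$module_scores <<- sc
  })

  prov <- list(seed = seed, thresholds = th, stages = done,
               package_version = as.character(utils::packageVersion("tilmotif")),
               sample_totals = lapply(samples, function(s)
                 list(sample_id = attr(s, "sample_id"),
                      tissue = attr(s, "tissue"),
                      total_reads = total_reads(s),
                      n_clonotypes = nrow(s))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, file.path(out_dir, "provenance.json"))
  res$report <- tibble(stage = done, completed = TRUE)
  res$paths <- paths
  invisible(res)
}
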