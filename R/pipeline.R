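default_params <- function() {
  list(
    bin_size = 10000, promoter_flank = 2000, min_peak_rpkm = 2,
    state_threshold = 1, up_fold = 2, down_fold = 2, change_min_rpkm = 2,
    change_pseudocount = 0.5, de_fold = 1.5, de_min_fpkm = 0.5,
    de_pseudocount = 0.1, min_coverage = 1, profile_window = 2000,
    profile_step = 100
  )
}

# Internal: closest-match suggestion for an unknown key.
suggest_key <- function(key, known) {
  d <- utils::adist(key, known, ignore.case = TRUE)
  if (min(d) <= 3) sprintf(" (did you mean '%s'?)", known[which.min(d)]) else ""
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills in the
#' documented defaults for every analysis parameter, and reports all
#' problems at once: unknown keys (with a closest-match suggestion),
#' out-of-range values and missing input paths.
#'
#' Top-level keys: `seed`, `output_dir`, `simulation` (arguments for
#' [sim_config()]), `analysis` (keys `input_dir`, `annotation_dir`,
#' `chip_samples`, `methylation_samples`, `expression`, `truth_dir`) and
#' `params` (see [default_params] in the source for names and defaults).
#'
#' @param config Path to a YAML file, or a list.
#' @return A resolved list of class `epi_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file or a list")
  problems <- character()
  top_known <- c("seed", "output_dir", "simulation", "analysis", "params")
  for (k in setdiff(names(config), top_known)) {
    problems <- c(problems, sprintf("unknown key '%s'%s", k, suggest_key(k, top_known)))
  }
  params <- default_params()
  for (k in names(config$params %||% list())) {
    if (!k %in% names(params)) {
      problems <- c(problems, sprintf("unknown params key '%s'%s",
                                      k, suggest_key(k, names(params))))
    } else {
      params[[k]] <- config$params[[k]]
    }
  }
  positive <- c("bin_size", "promoter_flank", "min_peak_rpkm", "up_fold",
                "down_fold", "change_min_rpkm", "min_coverage",
                "profile_window", "profile_step", "de_fold")
  for (k in positive) {
    if (!is.numeric(params[[k]]) || params[[k]] <= 0) {
      problems <- c(problems, sprintf("params$%s must be a positive number", k))
    }
  }
  if (is.numeric(params$de_fold) && params$de_fold <= 1) {
    problems <- c(problems, "params$de_fold must be > 1")
  }
  if (!is.null(config$simulation)) {
    bad_sim <- setdiff(names(config$simulation),
                       setdiff(names(formals(sim_config)), "seed"))
    for (k in bad_sim) {
      problems <- c(problems, sprintf(
        "unknown simulation key '%s'%s", k,
        suggest_key(k, names(formals(sim_config)))))
    }
  }
  analysis <- config$analysis
  if (!is.null(analysis)) {
    a_known <- c("input_dir", "annotation_dir", "chip_samples",
                 "methylation_samples", "expression", "truth_dir")
    for (k in setdiff(names(analysis), a_known)) {
      problems <- c(problems, sprintf("unknown analysis key '%s'%s",
                                      k, suggest_key(k, a_known)))
    }
    base <- analysis$input_dir %||% "."
    resolve <- function(p) {
      if (is.null(p)) return(NULL)
      if (file.exists(p)) p else file.path(base, p)
    }
    for (k in c("annotation_dir", "chip_samples", "methylation_samples",
                "expression", "truth_dir")) {
      analysis[[k]] <- resolve(analysis[[k]])
      if (!is.null(analysis[[k]]) && !file.exists(analysis[[k]])) {
        problems <- c(problems, sprintf("analysis$%s: path does not exist: %s",
                                        k, analysis[[k]]))
      }
    }
    if (is.null(analysis$annotation_dir)) {
      problems <- c(problems, "analysis block needs 'annotation_dir'")
    }
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid configuration:", paste0("  - ", problems)),
                collapse = "\n"))
  }
  structure(
    list(seed = config$seed %||% 1L, output_dir = config$output_dir %||% ".",
         simulation = config$simulation, analysis = analysis, params = params),
    class = "epi_config"
  )
}

# Internal: structured one-line-per-stage logger.
stage_logger <- function(log_path) {
  t_run <- Sys.time()
  function(stage, status, detail = "") {
    line <- sprintf("stage=%s\tstatus=%s\telapsed_s=%.2f\t%s",
                    stage, status, as.numeric(Sys.time() - t_run, units = "secs"),
                    detail)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    invisible(line)
  }
}

#' Simulate a fixture bundle from a configuration
#'
#' Runs the synthetic-data generator end-to-end and writes the fixture
#' bundle plus a run report.  Deterministic under the configured seed.
#'
#' @param config An `epi_config` (or path/list accepted by
#'   [validate_config()]) with a `simulation` block.
#' @param outdir Output directory; defaults to the configured `output_dir`.
#' @return List with `manifest`, `report`, `outdir`, invisibly.
#' @export
run_simulate <- function(config, outdir = NULL) {
  if (!inherits(config, "epi_config")) config <- validate_config(config)
  if (is.null(config$simulation)) {
    abort("config has no 'simulation' block; nothing to simulate")
  }
  outdir <- outdir %||% config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$simulation))
  sim <- simulate_dataset(sim_cfg)
  manifest <- write_fixture_bundle(sim, outdir)
  report <- tibble(
    item = c("genes", "bins_planted_changed", "chip_samples", "wgbs_samples",
             "files_written"),
    value = c(nrow(sim$annotation$genes),
              sum(sim$truth$bin_class$class != "unchanged"),
              length(sim$reads), length(sim$methylomes), nrow(manifest))
  )
  readr::write_tsv(report, file.path(outdir, "simulate_report.tsv"), progress = FALSE)
  invisible(list(manifest = manifest, report = report, outdir = outdir))
}

#' Build an analysis configuration for a fixture bundle
#'
#' Convenience constructor pointing every analysis input at the layout
#' written by [run_simulate()] / [write_fixture_bundle()].
#'
#' @param bundle_dir The fixture directory.
#' @param output_dir Where the analysis should write its results.
#' @param seed Seed echoed in the configuration.
#' @param params Optional list of parameter overrides.
#' @return An `epi_config`.
#' @export
fixture_analysis_config <- function(bundle_dir, output_dir, seed = 1, params = list()) {
  validate_config(list(
    seed = seed, output_dir = output_dir,
    analysis = list(
      input_dir = bundle_dir,
      annotation_dir = "annotation",
      chip_samples = "samples_chip.tsv",
      methylation_samples = "samples_meth.tsv",
      expression = "fpkm.tsv",
      truth_dir = if (dir.exists(file.path(bundle_dir, "truth"))) "truth" else NULL
    ),
    params = params
  ))
}

# Internal: read the ChIP sample sheet and load read sets.
load_chip_samples <- function(sheet_path, base_dir) {
  meta <- readr::read_tsv(sheet_path, col_types = readr::cols(
    sample_id = readr::col_character(), mark = readr::col_character(),
    genotype = readr::col_character(), total_mapped = readr::col_double(),
    reads = readr::col_character(), peaks = readr::col_character()
  ), progress = FALSE)
  readsets <- purrr::pmap(meta, function(sample_id, mark, genotype,
                                         total_mapped, reads, peaks) {
    epi_reads(read_bed(file.path(base_dir, reads)), sample_id = sample_id,
              mark = mark, genotype = genotype, total_mapped = total_mapped)
  })
  names(readsets) <- meta$sample_id
  list(meta = meta, readsets = readsets)
}

#' Mean CpG methylation per bin
#'
#' @param sites Site table from [site_levels()].
#' @param bins Bin tibble from [make_bins()].
#' @return Tibble `bin_id`, `n_sites`, `mean_level` (`NA` for uncovered bins).
#' @export
bin_cpg_means <- function(sites, bins) {
  cpg <- sites %>% filter(.data$context == "CpG")
  hits <- GenomicRanges::findOverlaps(as_gr(bins), points_gr(cpg$chrom, cpg$position),
                                      ignore.strand = TRUE)
  agg <- tibble(bin = S4Vectors::queryHits(hits),
                level = cpg$level[S4Vectors::subjectHits(hits)]) %>%
    group_by(.data$bin) %>%
    summarise(n_sites = n(), mean_level = mean(.data$level), .groups = "drop")
  out <- tibble(bin_id = bins$bin_id, n_sites = 0L, mean_level = NA_real_)
  out$n_sites[agg$bin] <- agg$n_sites
  out$mean_level[agg$bin] <- agg$mean_level
  out
}

# Internal: pick the sample id for a mark/genotype pair, or NULL.
sample_for <- function(meta, mark_, genotype_) {
  hit <- meta %>% filter(.data$mark == mark_, .data$genotype == genotype_)
  if (nrow(hit) == 0) NULL else hit$sample_id[1]
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — signal quantification over bins and
#' promoters, peak filtering and genomic distribution, promoter chromatin
#' states and their expression, differential expression, methylome
#' summaries (contexts, elements, ICRs, conversion efficiency, sample
#' clustering), the six-class bin-change taxonomy with covariates and
#' tests, single-mark (H3K36me3) change classes, and TSS-anchored profiles
#' — writing one tab-separated table per result into the output directory.
#' Stages whose inputs are absent (e.g. a missing genotype) are skipped
#' with a logged reason.  When a ground-truth directory is configured, a
#' truth-recovery comparison is emitted.
#'
#' @param config An `epi_config` (or path/list accepted by
#'   [validate_config()]) with an `analysis` block.
#' @param outdir Output directory; defaults to the configured `output_dir`.
#' @return A run report (list with `counts`, `outputs`, `log`), invisibly.
#' @export
run_analysis <- function(config, outdir = NULL) {
  if (!inherits(config, "epi_config")) config <- validate_config(config)
  if (is.null(config$analysis)) abort("config has no 'analysis' block")
  outdir <- outdir %||% config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "analysis_log.txt")
  if (file.exists(log_path)) file.remove(log_path)
  logf <- stage_logger(log_path)
  pr <- config$params
  an <- config$analysis
  base <- an$input_dir %||% "."
  counts <- list()
  out <- function(name) file.path(outdir, name)
  wt <- function(df, name) {
    readr::write_tsv(df, out(name), progress = FALSE)
    name
  }

  annotation <- read_annotation_dir(an$annotation_dir)
  logf("load_annotation", "ok", sprintf("genes=%d", nrow(annotation$genes)))

  bins <- make_bins(annotation, pr$bin_size)
  promoters <- promoters_from_genes(annotation$genes, pr$promoter_flank,
                                    annotation$chrom_sizes)

  # --- ChIP quantification ---------------------------------------------
  meta <- NULL; readsets <- list()
  bin_rpkm_tbl <- NULL; prom_rpkm_tbl <- NULL
  if (!is.null(an$chip_samples)) {
    chip <- load_chip_samples(an$chip_samples, base)
    meta <- chip$meta; readsets <- chip$readsets
    bin_rpkm_tbl <- quantify_samples(readsets, bins)
    wt(bin_rpkm_tbl, "bin_rpkm.tsv")
    for (nm in names(readsets)) {
      bg <- bin_rpkm_tbl %>%
        select("chrom", "start", "end", value = all_of(nm))
      write_bedgraph(bg, out(sprintf("bin_rpkm_%s.bedgraph", nm)), track_name = nm)
    }
    prom_rpkm_tbl <- quantify_samples(readsets, promoters)
    wt(prom_rpkm_tbl, "promoter_rpkm.tsv")
    wt(zscore_standardize(bin_rpkm_tbl, axis = "feature", value_cols = names(readsets)),
       "bin_rpkm_zscore.tsv")
    counts$chip_samples <- length(readsets)
    logf("quantify", "ok", sprintf("bins=%d promoters=%d samples=%d",
                                   nrow(bins), nrow(promoters), length(readsets)))

    # peak filtering + genomic distribution
    peak_rows <- list(); dist_rows <- list()
    for (i in seq_len(nrow(meta))) {
      pk_path <- file.path(base, meta$peaks[i])
      if (is.na(meta$peaks[i]) || !file.exists(pk_path)) next
      pk <- read_bed(pk_path)
      if (nrow(pk) == 0) next
      pk <- rpkm(readsets[[meta$sample_id[i]]], pk)
      flt <- filter_low_quality_peaks(pk, pr$min_peak_rpkm)
      peak_rows[[meta$sample_id[i]]] <- flt$report %>%
        mutate(sample_id = meta$sample_id[i], .before = 1)
      dist_rows[[meta$sample_id[i]]] <-
        peak_genomic_distribution(flt$retained, annotation,
                                  pr$promoter_flank, pr$promoter_flank) %>%
        mutate(sample_id = meta$sample_id[i], .before = 1)
      wt(flt$retained, sprintf("peaks_filtered_%s.tsv", meta$sample_id[i]))
    }
    if (length(peak_rows) > 0) {
      wt(bind_rows(peak_rows), "peak_filter_report.tsv")
      wt(bind_rows(dist_rows), "peak_genomic_distribution.tsv")
      counts$peak_reports <- length(peak_rows)
      logf("peak_filter", "ok", sprintf("samples=%d", length(peak_rows)))
    } else {
      logf("peak_filter", "skipped", "reason=no_peak_files")
    }
  } else {
    logf("quantify", "skipped", "reason=no_chip_samples")
  }

  # --- promoter states ---------------------------------------------------
  states <- list()
  if (!is.null(prom_rpkm_tbl)) {
    for (g in c("WT", "KO")) {
      ids <- list(K4 = sample_for(meta, "H3K4me3", g),
                  K27 = sample_for(meta, "H3K27me3", g),
                  ub = sample_for(meta, "H2AK119ub1", g))
      if (any(vapply(ids, is.null, TRUE))) {
        logf("promoter_states", "skipped",
             sprintf("genotype=%s reason=missing_marks", g))
        next
      }
      st <- classify_promoter_states(
        tibble(gene_id = prom_rpkm_tbl$gene_id,
               K4 = prom_rpkm_tbl[[ids$K4]],
               K27 = prom_rpkm_tbl[[ids$K27]],
               ub = prom_rpkm_tbl[[ids$ub]]),
        threshold = pr$state_threshold)
      states[[g]] <- st
      wt(st, sprintf("promoter_states_%s.tsv", g))
      counts[[paste0("genes_classified_", g)]] <- nrow(st)
      logf("promoter_states", "ok", sprintf("genotype=%s genes=%d", g, nrow(st)))
    }
  }

  # --- expression --------------------------------------------------------
  expression <- NULL; de <- NULL
  if (!is.null(an$expression)) {
    expression <- read_fpkm_table(an$expression)
    if (!is.null(states$WT) && "WT" %in% names(expression)) {
      wt(expression_by_state(states$WT, expression, sample = "WT"),
         "expression_by_state_WT.tsv")
      logf("expression_by_state", "ok", "genotype=WT")
    }
    if (all(c("WT", "KO") %in% names(expression))) {
      de <- call_de_genes(expression, fold = pr$de_fold,
                          min_fpkm = pr$de_min_fpkm, pseudocount = pr$de_pseudocount)
      wt(de, "de_calls.tsv")
      counts$de_down <- sum(de$status == "down")
      counts$de_up <- sum(de$status == "up")
      logf("de_calls", "ok", sprintf("down=%d up=%d", counts$de_down, counts$de_up))
    } else {
      logf("de_calls", "skipped", "reason=need_both_genotypes")
    }
  } else {
    logf("expression", "skipped", "reason=no_expression_table")
  }

  # --- methylome ---------------------------------------------------------
  meth_sites <- list(); meth_meta <- NULL
  if (!is.null(an$methylation_samples)) {
    meth_meta <- readr::read_tsv(an$methylation_samples, col_types = readr::cols(
      sample_id = readr::col_character(), genotype = readr::col_character(),
      path = readr::col_character()), progress = FALSE)
    ctx_rows <- list(); elem_rows <- list(); icr_rows <- list(); conv_rows <- list()
    for (i in seq_len(nrow(meth_meta))) {
      calls <- read_methylation_coverage(file.path(base, meth_meta$path[i]),
                                         sample_id = meth_meta$sample_id[i],
                                         genotype = meth_meta$genotype[i])
      sites <- site_levels(calls, min_coverage = pr$min_coverage)
      meth_sites[[meth_meta$sample_id[i]]] <- sites
      ctx_rows[[i]] <- global_levels_by_context(sites) %>%
        mutate(sample_id = meth_meta$sample_id[i], .before = 1)
      elem_rows[[i]] <- aggregate_by_element(sites, annotation, pr$promoter_flank) %>%
        mutate(sample_id = meth_meta$sample_id[i], .before = 1)
      if (nrow(annotation$icrs) > 0) {
        icr_rows[[i]] <- icr_levels(sites, annotation)$per_icr %>%
          mutate(sample_id = meth_meta$sample_id[i], .before = 1)
      }
      if (!is.null(annotation$lambda_chrom) &&
          any(calls$chrom == annotation$lambda_chrom)) {
        conv_rows[[i]] <- tibble(sample_id = meth_meta$sample_id[i],
                                 conversion_efficiency =
                                   conversion_efficiency(calls, annotation$lambda_chrom))
      }
    }
    wt(bind_rows(ctx_rows), "methylation_by_context.tsv")
    wt(bind_rows(elem_rows), "methylation_by_element.tsv")
    if (length(icr_rows) > 0) wt(bind_rows(icr_rows), "methylation_icr.tsv")
    if (length(conv_rows) > 0) wt(bind_rows(conv_rows), "conversion_efficiency.tsv")
    counts$meth_samples <- nrow(meth_meta)
    logf("methylome", "ok", sprintf("samples=%d", nrow(meth_meta)))
    if (length(meth_sites) >= 2) {
      cl <- cluster_samples_by_cpg(meth_sites, min_coverage = pr$min_coverage)
      wt(tidy(cl), "methylome_clusters.tsv")
      write_newick(cl, out("methylome_dendrogram.nwk"))
      logf("methylome_clustering", "ok",
           sprintf("shared_sites=%d", cl$n_shared_sites))
    } else {
      logf("methylome_clustering", "skipped", "reason=fewer_than_2_samples")
    }
  } else {
    logf("methylome", "skipped", "reason=no_methylation_samples")
  }

  # --- bin change classes ------------------------------------------------
  bin_changes <- NULL
  if (!is.null(bin_rpkm_tbl)) {
    ids <- list(k27_wt = sample_for(meta, "H3K27me3", "WT"),
                k27_ko = sample_for(meta, "H3K27me3", "KO"),
                ub_wt = sample_for(meta, "H2AK119ub1", "WT"),
                ub_ko = sample_for(meta, "H2AK119ub1", "KO"))
    if (!any(vapply(ids, is.null, TRUE))) {
      bin_changes <- classify_bin_changes(
        tibble(bin_id = bin_rpkm_tbl$bin_id,
               chrom = bin_rpkm_tbl$chrom, start = bin_rpkm_tbl$start,
               end = bin_rpkm_tbl$end,
               k27_wt = bin_rpkm_tbl[[ids$k27_wt]],
               k27_ko = bin_rpkm_tbl[[ids$k27_ko]],
               ub_wt = bin_rpkm_tbl[[ids$ub_wt]],
               ub_ko = bin_rpkm_tbl[[ids$ub_ko]]),
        up_fold = pr$up_fold, down_fold = pr$down_fold,
        min_rpkm = pr$change_min_rpkm, pseudocount = pr$change_pseudocount)
      wt(bin_changes, "bin_changes.tsv")
      counts$bins_changed <- sum(!bin_changes$class %in% "unchanged")
      logf("bin_changes", "ok", sprintf("changed=%d of %d",
                                        counts$bins_changed, nrow(bin_changes)))

      covs <- list()
      wt_meth_id <- if (!is.null(meth_meta)) {
        m <- meth_meta %>% filter(.data$genotype == "WT"); if (nrow(m)) m$sample_id[1] else NULL
      } else NULL
      ko_meth_id <- if (!is.null(meth_meta)) {
        m <- meth_meta %>% filter(.data$genotype == "KO"); if (nrow(m)) m$sample_id[1] else NULL
      } else NULL
      if (!is.null(wt_meth_id) && !is.null(ko_meth_id)) {
        covs$methylation <- tibble(
          bin_id = bins$bin_id,
          wt = bin_cpg_means(meth_sites[[wt_meth_id]], bins)$mean_level,
          ko = bin_cpg_means(meth_sites[[ko_meth_id]], bins)$mean_level)
      }
      k36_wt <- sample_for(meta, "H3K36me3", "WT")
      k36_ko <- sample_for(meta, "H3K36me3", "KO")
      if (!is.null(k36_wt) && !is.null(k36_ko)) {
        covs$H3K36me3 <- tibble(bin_id = bin_rpkm_tbl$bin_id,
                                wt = bin_rpkm_tbl[[k36_wt]],
                                ko = bin_rpkm_tbl[[k36_ko]])
      }
      expr_cov <- if (!is.null(expression) && all(c("WT", "KO") %in% names(expression))) {
        expression %>% select("gene_id", wt = "WT", ko = "KO")
      } else NULL
      cc <- bin_class_covariates(
        bin_changes %>% select("bin_id", "chrom", "start", "end", "class"),
        covariates = covs, expression = expr_cov, genes = annotation$genes)
      if (nrow(cc$summaries) > 0) {
        wt(cc$summaries, "bin_class_covariates.tsv")
        wt(cc$tests, "bin_class_tests.tsv")
        logf("bin_covariates", "ok", sprintf("tests=%d", nrow(cc$tests)))
      }

      if (!is.null(k36_wt) && !is.null(k36_ko)) {
        k36_changes <- bin_mark_change_classes(
          tibble(bin_id = bin_rpkm_tbl$bin_id,
                 wt = bin_rpkm_tbl[[k36_wt]], ko = bin_rpkm_tbl[[k36_ko]]),
          up_fold = pr$up_fold, down_fold = pr$down_fold,
          min_rpkm = pr$change_min_rpkm, pseudocount = pr$change_pseudocount)
        wt(k36_changes, "k36_changes.tsv")
        k36_cc <- bin_class_covariates(
          bins %>% inner_join(k36_changes %>% select("bin_id", class = "change"),
                              by = "bin_id"),
          covariates = if ("methylation" %in% names(covs)) covs["methylation"] else list(),
          expression = expr_cov, genes = annotation$genes)
        if (nrow(k36_cc$summaries) > 0) {
          wt(k36_cc$summaries, "k36_class_covariates.tsv")
          wt(k36_cc$tests, "k36_class_tests.tsv")
        }
        logf("k36_changes", "ok",
             sprintf("changed=%d", sum(k36_changes$change != "unchanged")))
      }
    } else {
      logf("bin_changes", "skipped", "reason=need_K27_and_ub_in_both_genotypes")
    }
  }

  # --- profiles ----------------------------------------------------------
  if (length(readsets) > 0) {
    anchors_all <- annotation$genes %>%
      select("gene_id", "chrom", pos = "tss", "strand")
    prof_rows <- purrr::imap_dfr(readsets, function(rs, nm) {
      tidy(average_profile(rs, anchors_all, pr$profile_window, pr$profile_step))
    })
    wt(prof_rows, "tss_profiles.tsv")
    if (!is.null(de)) {
      de_rows <- purrr::map_dfr(c("down", "up"), function(dir) {
        g <- de$gene_id[de$status == dir]
        anc <- anchors_all %>% filter(.data$gene_id %in% g)
        if (nrow(anc) == 0) return(NULL)
        purrr::imap_dfr(readsets, function(rs, nm) {
          tidy(average_profile(rs, anc, pr$profile_window, pr$profile_step)) %>%
            mutate(de_group = dir)
        })
      })
      if (nrow(de_rows) > 0) wt(de_rows, "tss_profiles_by_de_group.tsv")
    }
    logf("profiles", "ok", sprintf("anchors=%d", nrow(anchors_all)))
  }
  if (!is.null(states$WT) && length(meth_sites) > 0 && !is.null(meth_meta)) {
    m <- meth_meta %>% filter(.data$genotype == "WT")
    if (nrow(m) > 0) {
      wt(methylation_profile_by_tss_state(meth_sites[[m$sample_id[1]]], states$WT,
                                          annotation$genes, pr$profile_window,
                                          pr$profile_step),
         "methylation_tss_profile_by_state.tsv")
      logf("methylation_profile", "ok", "genotype=WT")
    }
  }

  # --- truth recovery ----------------------------------------------------
  if (!is.null(an$truth_dir)) {
    rec <- recover_truth(an$truth_dir, outdir)
    logf("recover", "ok", paste(sprintf("%s=%.3f", rec$metric, rec$value),
                                collapse = " "))
  }

  # --- report ------------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir),
                          c("run_report.tsv", "analysis_log.txt")))
  report_tbl <- tibble(
    item = c(names(counts), "outputs"),
    value = c(unlist(counts, use.names = FALSE), length(outputs))
  )
  readr::write_tsv(report_tbl, out("run_report.tsv"), progress = FALSE)
  manifest <- tibble(path = outputs,
                     md5 = unname(tools::md5sum(file.path(outdir, outputs))))
  readr::write_tsv(manifest, out("output_manifest.tsv"), progress = FALSE)
  logf("done", "ok", sprintf("outputs=%d", length(outputs)))
  invisible(list(counts = counts, outputs = outputs, log = log_path,
                 outdir = outdir))
}

#' Compare analysis results with the planted ground truth
#'
#' Reads the generator's truth tables and the corresponding analysis outputs
#' and reports recovery metrics: the fraction of genes whose recovered WT
#' promoter state equals the planted state, and the fraction of planted
#' class I-VI bins recovered exactly.
#'
#' @param truth_dir Directory with `promoter_states.tsv`/`bin_classes.tsv`
#'   (as written by [write_fixture_bundle()]).
#' @param results_dir Directory with `promoter_states_WT.tsv` and
#'   `bin_changes.tsv` (as written by [run_analysis()]); the comparison
#'   table `recovery.tsv` is written there.
#' @return Tibble `metric`, `value`, `n`.
#' @export
recover_truth <- function(truth_dir, results_dir) {
  rows <- list()
  ps_t <- file.path(truth_dir, "promoter_states.tsv")
  ps_r <- file.path(results_dir, "promoter_states_WT.tsv")
  if (file.exists(ps_t) && file.exists(ps_r)) {
    truth <- readr::read_tsv(ps_t, col_types = readr::cols(), progress = FALSE)
    rec <- readr::read_tsv(ps_r, col_types = readr::cols(), progress = FALSE)
    joined <- inner_join(truth %>% select("gene_id", planted = "state"),
                         rec %>% select("gene_id", recovered = "state"),
                         by = "gene_id")
    rows$promoter <- tibble(metric = "promoter_state_recovery",
                            value = mean(joined$planted == joined$recovered),
                            n = nrow(joined))
  }
  bc_t <- file.path(truth_dir, "bin_classes.tsv")
  bc_r <- file.path(results_dir, "bin_changes.tsv")
  if (file.exists(bc_t) && file.exists(bc_r)) {
    truth <- readr::read_tsv(bc_t, col_types = readr::cols(), progress = FALSE)
    rec <- readr::read_tsv(bc_r, col_types = readr::cols(), progress = FALSE)
    joined <- inner_join(truth %>% select("bin_id", planted = "class"),
                         rec %>% select("bin_id", recovered = "class"),
                         by = "bin_id") %>%
      filter(.data$planted %in% bin_class_names())
    rows$bins <- tibble(metric = "bin_class_recovery",
                        value = mean(joined$planted == joined$recovered),
                        n = nrow(joined))
  }
  if (length(rows) == 0) abort("no matching truth/result tables found")
  out <- bind_rows(rows)
  readr::write_tsv(out, file.path(results_dir, "recovery.tsv"), progress = FALSE)
  out
}
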