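#' Configuration for the synthetic two-genotype dataset
#'
#' Builds the parameter set for the toy multi-omic generator: a small
#' two-chromosome genome with tiled genes, alternating hyper-/hypomethylated
#' domains, planted promoter chromatin states, planted directional
#' Polycomb-mark changes in 10-kb bins, an unmethylated spike-in chromosome,
#' and expression coupled to promoter state.  Defaults are chosen for
#' comfortable statistical separation at desk scale; every coupling between
#' data layers is an explicit switch so tests can verify that the pipeline
#' does not manufacture correlations (see the methods vignette).
#'
#' @param seed Integer seed; the generator is fully deterministic under
#'   `(config, seed)`.
#' @param n_chroms,chrom_length,n_genes,gene_length Genome geometry.
#' @param bin_size,promoter_flank Analysis resolution (10 kb bins, +/- 2 kb
#'   promoters).
#' @param reads_per_sample,read_length ChIP library depth and read width.
#' @param state_frequencies Named probabilities over the 8 promoter states
#'   (`none`, `K4`, `K27`, `ub` and their combinations, `+`-joined).
#' @param bin_class_frequencies Named probabilities over
#'   `unchanged`, `I`..`VI`.
#' @param enrichment_fold Read-density ratio of a planted region over the
#'   uniform genomic background.  Very high by default: at desk scale
#'   (10 Mb genome, 200k reads) the background must be nearly empty for a
#'   fixed RPKM threshold to behave as it does on a full-size genome.
#' @param k4_ko_attenuation Multiplier on H3K4me3 enrichment in the KO,
#'   emulating the global loss of the mark.
#' @param domain_size Width of the alternating methylation domains.
#' @param methylation_high,methylation_low Mean CpG levels of hyper-/
#'   hypomethylated domains in WT.
#' @param meth_global_ko_drop KO reduction of hypermethylated domains.
#' @param meth_ko_delta Extra KO methylation loss inside bins planted as
#'   Polycomb-gain classes (I-III).
#' @param meth_ko_hypo_gain Slight KO gain in hypomethylated domains.
#' @param couple_methylation,couple_expression,couple_k36 Coupling switches:
#'   Polycomb-gain classes sit in WT-hypermethylated domains and lose
#'   methylation in KO; expression follows promoter state and bin class with
#'   H3K27me3 dominant-repressive; H3K36me3 follows expression over gene
#'   bodies.
#' @param cytosine_spacing,context_probs,coverage_mean,chh_level WGBS site
#'   density, context mix, mean coverage and non-CpG baseline level.
#' @param conversion_efficiency_true,lambda_chrom,lambda_sites Spike-in
#'   chromosome parameters.
#' @param cgi_fraction,cgi_halfwidth Fraction of promoters carrying a CpG
#'   island and CGI half-width.
#' @param n_icrs,icr_length Number and width of imprinting control regions.
#' @param icr_meth_wt_maternal,icr_meth_ko_maternal,icr_meth_paternal
#'   Planted ICR methylation (maternal ICRs are methylated in the oocyte,
#'   paternal ones are not; the KO loses part of the maternal methylation).
#' @param fpkm_means Named mean WT FPKM per promoter state.
#' @param dispersion Log-normal sd (log scale) of FPKM around its mean.
#' @param de_fraction,de_effect Fraction of K4-only genes planted as
#'   downregulated in KO and their WT/KO fold.
#' @param bin_effect_down,bin_effect_up KO expression multipliers for genes
#'   inside Polycomb-gain (I/II) and Polycomb-loss (IV/V) bins.
#' @param expressed_fpkm_min FPKM floor defining "expressed" gene bodies for
#'   H3K36me3 placement.
#' @param n_meth_reps WGBS replicates per genotype.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 5e6,
                       n_genes = 500, gene_length = 10000,
                       bin_size = 10000, promoter_flank = 2000,
                       reads_per_sample = 200000, read_length = 150,
                       state_frequencies = c(
                         none = 0.35, K4 = 0.30, K27 = 0.05, ub = 0.05,
                         `K4+K27` = 0.10, `K4+ub` = 0.08, `K27+ub` = 0.04,
                         `K4+K27+ub` = 0.03),
                       bin_class_frequencies = c(
                         unchanged = 0.82, I = 0.03, II = 0.03, III = 0.03,
                         IV = 0.03, V = 0.03, VI = 0.03),
                       enrichment_fold = 1e5,
                       k4_ko_attenuation = 0.4,
                       domain_size = 1e5,
                       methylation_high = 0.8, methylation_low = 0.1,
                       meth_global_ko_drop = 0.2,
                       meth_ko_delta = 0.6,
                       meth_ko_hypo_gain = 0.05,
                       couple_methylation = TRUE,
                       couple_expression = TRUE,
                       couple_k36 = TRUE,
                       cytosine_spacing = 100,
                       context_probs = c(CpG = 0.8, CHG = 0.1, CHH = 0.1),
                       coverage_mean = 30, chh_level = 0.01,
                       conversion_efficiency_true = 0.995,
                       lambda_chrom = "chrL", lambda_sites = 2000,
                       cgi_fraction = 0.5, cgi_halfwidth = 500,
                       n_icrs = 8, icr_length = 3000,
                       icr_meth_wt_maternal = 0.85,
                       icr_meth_ko_maternal = 0.55,
                       icr_meth_paternal = 0.05,
                       fpkm_means = c(
                         none = 0.15, K4 = 25, K27 = 0.3, ub = 6,
                         `K4+K27` = 0.5, `K4+ub` = 12, `K27+ub` = 0.25,
                         `K4+K27+ub` = 0.4),
                       dispersion = 0.3,
                       de_fraction = 0.3, de_effect = 4,
                       bin_effect_down = 0.4, bin_effect_up = 2,
                       expressed_fpkm_min = 2,
                       n_meth_reps = 2) {
  cfg <- as.list(environment())
  states <- promoter_state_names()
  if (!setequal(names(cfg$state_frequencies), states)) {
    abort("state_frequencies must name exactly the 8 promoter states")
  }
  if (!setequal(names(cfg$bin_class_frequencies), c("unchanged", bin_class_names()))) {
    abort("bin_class_frequencies must name 'unchanged' and classes I-VI")
  }
  if (abs(sum(cfg$state_frequencies) - 1) > 1e-9) {
    abort("state_frequencies must sum to 1")
  }
  if (abs(sum(cfg$bin_class_frequencies) - 1) > 1e-9) {
    abort("bin_class_frequencies must sum to 1")
  }
  if (abs(sum(cfg$context_probs) - 1) > 1e-9) abort("context_probs must sum to 1")
  if (cfg$enrichment_fold <= 1) abort("enrichment_fold must be > 1")
  if (!(cfg$methylation_low >= 0 && cfg$methylation_low < cfg$methylation_high &&
        cfg$methylation_high <= 1)) {
    abort("need 0 <= methylation_low < methylation_high <= 1")
  }
  if (!setequal(names(cfg$fpkm_means), states)) {
    abort("fpkm_means must name exactly the 8 promoter states")
  }
  structure(cfg, class = "sim_config")
}

# Canonical orderings used throughout.
promoter_state_names <- function() {
  c("none", "K4", "K27", "ub", "K4+K27", "K4+ub", "K27+ub", "K4+K27+ub")
}
bin_class_names <- function() c("I", "II", "III", "IV", "V", "VI")
chip_marks <- function() c("H3K4me3", "H3K27me3", "H2AK119ub1", "H3K36me3")

# Internal: does a state string contain a mark token?
state_has <- function(state, token) {
  vapply(strsplit(state, "+", fixed = TRUE), function(p) token %in% p, TRUE)
}

#' Build the toy genome annotation
#'
#' Tiles non-overlapping genes with alternating strands across the autosome
#' surrogates, lays down alternating hyper-/hypomethylated domains, places
#' CpG islands at a configurable fraction of promoters, puts imprinting
#' control regions inside hypermethylated domains, spaces repeat elements
#' evenly, and appends the unmethylated spike-in chromosome.
#'
#' @param config A [sim_config()].
#' @return An `epi_annotation` with a `domains` table and `lambda_chrom` set.
#' @export
build_toy_genome <- function(config) {
  if (config$chrom_length < 50 * config$bin_size) {
    abort("chrom_length must be at least 50 * bin_size")
  }
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  slot_need <- config$gene_length + 2 * config$promoter_flank
  if (any(per_chrom > 0 & floor(config$chrom_length / pmax(per_chrom, 1)) < slot_need)) {
    abort(sprintf(
      "genes cannot fit: need chrom_length >= %d for %d genes per chromosome",
      max(per_chrom) * slot_need, max(per_chrom)))
  }
  id_width <- max(4, nchar(config$n_genes))
  gene_idx <- 0L
  genes <- purrr::map2_dfr(chroms, per_chrom, function(ch, ng) {
    if (ng == 0) return(NULL)
    slot <- floor(config$chrom_length / ng)
    slot_start <- (seq_len(ng) - 1L) * slot
    body_start <- as.integer(slot_start + floor((slot - config$gene_length) / 2))
    idx <- gene_idx + seq_len(ng)
    gene_idx <<- gene_idx + ng
    tibble(
      gene_id = sprintf(paste0("g%0", id_width, "d"), idx),
      chrom = ch, start = body_start,
      end = body_start + as.integer(config$gene_length),
      strand = ifelse(idx %% 2 == 1, "+", "-")
    )
  })
  genes <- add_tss_tes(genes)
  # alternating methylation domains, hyper first
  domains <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0L, config$chrom_length - 1L, by = config$domain_size)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + config$domain_size, config$chrom_length)),
           type = ifelse(seq_along(starts) %% 2 == 1, "hyper", "hypo"))
  })
  cgis <- withr::with_seed(config$seed + 11L, {
    n_cgi <- round(config$cgi_fraction * nrow(genes))
    pick <- sort(sample.int(nrow(genes), n_cgi))
    tibble(chrom = genes$chrom[pick],
           start = pmax(0L, as.integer(genes$tss[pick] - config$cgi_halfwidth)),
           end = as.integer(genes$tss[pick] + config$cgi_halfwidth))
  })
  hyper <- domains %>% filter(.data$type == "hyper")
  if (config$n_icrs > nrow(hyper)) abort("not enough hypermethylated domains for ICRs")
  pick <- round(seq(1, nrow(hyper), length.out = config$n_icrs))
  icr_mid <- floor((hyper$start[pick] + hyper$end[pick]) / 2)
  icrs <- tibble(
    icr_id = sprintf("ICR%02d", seq_len(config$n_icrs)),
    chrom = hyper$chrom[pick],
    start = as.integer(icr_mid - floor(config$icr_length / 2)),
    end = as.integer(icr_mid + ceiling(config$icr_length / 2)),
    parent = ifelse(seq_len(config$n_icrs) %% 2 == 1, "maternal", "paternal")
  )
  repeats <- purrr::map_dfr(chroms, function(ch) {
    n_rep <- 50
    pos <- as.integer(floor((seq_len(n_rep) - 0.7) * config$chrom_length / n_rep))
    tibble(chrom = ch, start = pos, end = pos + 1000L)
  })
  chrom_sizes <- bind_rows(
    tibble(chrom = chroms, length = config$chrom_length),
    tibble(chrom = config$lambda_chrom, length = 48502)
  )
  epi_annotation(chrom_sizes, genes, cgis = cgis, repeats = repeats,
                 icrs = icrs, domains = domains, lambda_chrom = config$lambda_chrom)
}

#' Plant the ground truth
#'
#' Draws a promoter chromatin state for every gene and a change class for
#' every 10-kb bin, places the classes subject to the methylation coupling
#' (Polycomb-gain classes I-III only inside WT-hypermethylated domains,
#' loss classes IV-VI only inside hypomethylated ones, unless
#' `couple_methylation` is off), assigns planted methylation means to
#' domains, bins and ICRs, and derives expected WT/KO FPKM per gene.
#'
#' @param config A [sim_config()].
#' @param annotation The matching [build_toy_genome()] output.
#' @return An object of class `epi_truth`: list of tibbles
#'   `promoter_state`, `bin_class`, `domains`, `expression`, `k36`, plus the
#'   config.
#' @export
plant_truth <- function(config, annotation) {
  withr::with_seed(config$seed + 101L, {
    genes <- annotation$genes
    states <- sample(names(config$state_frequencies), nrow(genes),
                     replace = TRUE, prob = config$state_frequencies)
    promoter_state <- tibble(
      gene_id = genes$gene_id, state = states,
      group = four_group_label(state_has(states, "K4"), state_has(states, "K27"))
    )

    bins <- make_bins(annotation, config$bin_size)
    promoters <- promoters_from_genes(genes, config$promoter_flank,
                                      annotation$chrom_sizes)
    overlaps_promoter <- GenomicRanges::countOverlaps(
      as_gr(bins), as_gr(promoters), ignore.strand = TRUE) > 0
    dom_of_bin <- overlap_assign(
      bins, annotation$domains %>% mutate(label = .data$type), mode = "midpoint")$label
    whole_domain <- !is.na(dom_of_bin)
    eligible <- !overlaps_promoter & whole_domain
    n_bins <- nrow(bins)
    k <- round(config$bin_class_frequencies[bin_class_names()] * n_bins)
    class_vec <- rep("unchanged", n_bins)
    gain_classes <- c("I", "II", "III")
    loss_classes <- c("IV", "V", "VI")
    if (config$couple_methylation) {
      pool_gain <- which(eligible & dom_of_bin == "hyper")
      pool_loss <- which(eligible & dom_of_bin == "hypo")
    } else {
      pool_gain <- pool_loss <- which(eligible)
    }
    n_gain <- sum(k[gain_classes]); n_loss <- sum(k[loss_classes])
    if (length(pool_gain) < n_gain || length(setdiff(pool_loss, pool_gain)) <
        ifelse(config$couple_methylation, n_loss, 0)) {
      abort("infeasible coupling: not enough eligible bins in the required domains")
    }
    gain_bins <- sample(pool_gain, n_gain)
    pool_loss <- setdiff(pool_loss, gain_bins)
    if (length(pool_loss) < n_loss) {
      abort("infeasible coupling: not enough eligible bins in the required domains")
    }
    loss_bins <- sample(pool_loss, n_loss)
    class_vec[gain_bins] <- rep(gain_classes, times = k[gain_classes])
    class_vec[loss_bins] <- rep(loss_classes, times = k[loss_classes])
    bin_class <- bins %>% mutate(class = class_vec)

    domains <- annotation$domains %>%
      mutate(
        wt_level = if_else(.data$type == "hyper",
                           config$methylation_high, config$methylation_low),
        ko_level = if_else(.data$type == "hyper",
                           pmax(0, config$methylation_high - config$meth_global_ko_drop),
                           pmin(1, config$methylation_low + config$meth_ko_hypo_gain))
      )

    # expression effects: promoter state sets the WT mean, bin coupling and
    # planted DE modify the KO mean
    wt_mean <- unname(config$fpkm_means[states])
    ko_mean <- wt_mean
    body_mid <- interval_midpoint(genes$start, genes$end)
    gene_bin <- overlap_assign(
      tibble(chrom = genes$chrom, start = body_mid, end = body_mid + 1L),
      bin_class %>% mutate(label = .data$class), mode = "any")$label
    if (config$couple_expression) {
      ko_mean[gene_bin %in% c("I", "II")] <-
        wt_mean[gene_bin %in% c("I", "II")] * config$bin_effect_down
      ko_mean[gene_bin %in% c("IV", "V")] <-
        wt_mean[gene_bin %in% c("IV", "V")] * config$bin_effect_up
    }
    k4_only <- which(states == "K4" & ko_mean == wt_mean)
    n_de <- round(config$de_fraction * length(k4_only))
    de_pick <- sample(k4_only, n_de)
    ko_mean[de_pick] <- wt_mean[de_pick] / config$de_effect
    expression <- tibble(
      gene_id = genes$gene_id, state = states, bin_class = gene_bin,
      wt_mean = wt_mean, ko_mean = ko_mean,
      expected_de = dplyr::case_when(
        wt_mean / ko_mean >= 1.5 ~ "down",
        ko_mean / wt_mean >= 1.5 ~ "up",
        TRUE ~ "unchanged"
      )
    )

    k36 <- tibble(
      gene_id = genes$gene_id,
      k36_wt = wt_mean >= config$expressed_fpkm_min,
      k36_ko = if (config$couple_k36) ko_mean >= config$expressed_fpkm_min
               else wt_mean >= config$expressed_fpkm_min
    )

    structure(
      list(promoter_state = promoter_state, bin_class = bin_class,
           domains = domains, expression = expression, k36 = k36,
           config = config),
      class = "epi_truth"
    )
  })
}

#' @export
print.epi_truth <- function(x, ...) {
  cat("<epi_truth>\n")
  cat("  promoter states:", paste(capture_counts(x$promoter_state$state), collapse = "  "), "\n")
  cat("  bin classes:", paste(capture_counts(x$bin_class$class), collapse = "  "), "\n")
  invisible(x)
}

capture_counts <- function(v) {
  tb <- table(v)
  sprintf("%s=%d", names(tb), as.integer(tb))
}

# Internal: four-group promoter label from K4/K27 presence.
four_group_label <- function(k4, k27) {
  dplyr::case_when(
    k4 & !k27 ~ "A", k4 & k27 ~ "B", !k4 & k27 ~ "C", TRUE ~ "D"
  )
}

# Internal: regions where the truth places a mark for one genotype, with
# their enrichment weight relative to background density 1.
enriched_regions <- function(truth, annotation, mark, genotype, config) {
  genes <- annotation$genes
  promoters <- promoters_from_genes(genes, config$promoter_flank,
                                    annotation$chrom_sizes)
  st <- truth$promoter_state$state
  fold <- config$enrichment_fold
  prom_regions <- function(token, weight) {
    sel <- state_has(st, token)
    if (!any(sel)) return(NULL)
    promoters[sel, c("chrom", "start", "end")] %>% mutate(weight = weight)
  }
  bin_regions <- function(classes, weight) {
    sel <- truth$bin_class$class %in% classes
    if (!any(sel)) return(NULL)
    truth$bin_class[sel, c("chrom", "start", "end")] %>% mutate(weight = weight)
  }
  switch(mark,
    H3K4me3 = prom_regions("K4", if (genotype == "KO") fold * config$k4_ko_attenuation else fold),
    H3K27me3 = bind_rows(
      prom_regions("K27", fold),
      if (genotype == "WT") bin_regions(c("IV", "V"), fold) else bin_regions(c("I", "II"), fold)
    ),
    H2AK119ub1 = bind_rows(
      prom_regions("ub", fold),
      if (genotype == "WT") bin_regions(c("V", "VI"), fold) else bin_regions(c("II", "III"), fold)
    ),
    H3K36me3 = {
      on <- if (genotype == "WT") truth$k36$k36_wt else truth$k36$k36_ko
      if (!any(on)) NULL else
        genes[on, c("chrom", "start", "end")] %>% mutate(weight = fold)
    },
    abort(sprintf("unknown mark '%s'", mark))
  )
}

#' Simulate a ChIP read set
#'
#' Fixed-length reads are drawn from a mixture of a uniform genomic
#' background and the regions where the planted truth puts the mark for the
#' requested genotype, weighted by `enrichment_fold`.  The total read count
#' is Poisson-jittered around `reads_per_sample`.
#'
#' @param truth An `epi_truth`.
#' @param annotation The matching annotation.
#' @param mark One of the four histone marks.
#' @param genotype `"WT"` or `"KO"`.
#' @param config The [sim_config()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return An `epi_reads`.
#' @export
simulate_chip_reads <- function(truth, annotation, mark, genotype, config,
                                seed = NULL) {
  if (!mark %in% chip_marks()) abort(sprintf("unknown mark '%s'", mark))
  if (!is.null(seed)) set.seed(seed)
  sizes <- annotation$chrom_sizes %>%
    filter(!.data$chrom %in% annotation$lambda_chrom)
  background <- tibble(chrom = sizes$chrom, start = 0L,
                       end = as.integer(sizes$length), weight = 1)
  enriched <- enriched_regions(truth, annotation, mark, genotype, config)
  # enriched regions overlay the background, so their extra weight is w - 1
  segs <- bind_rows(
    background,
    if (!is.null(enriched)) enriched %>% mutate(weight = .data$weight - 1)
  ) %>% filter(.data$weight > 0)
  n <- rpois(1, config$reads_per_sample)
  w <- (segs$end - segs$start) * segs$weight
  idx <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
  mid <- floor(runif(n, segs$start[idx], segs$end[idx]))
  len <- config$read_length
  chrom_len <- setNames(sizes$length, sizes$chrom)[segs$chrom[idx]]
  start <- pmax(0L, pmin(as.integer(mid - len %/% 2), as.integer(chrom_len - len)))
  reads <- tibble(chrom = segs$chrom[idx], start = start, end = start + as.integer(len))
  epi_reads(reads, sample_id = paste(mark, genotype, sep = "_"),
            mark = mark, genotype = genotype, total_mapped = n)
}

# Internal: deterministic cytosine layout shared by all WGBS samples of one
# genome (positions and contexts come from the annotation, not the sample).
wgbs_site_layout <- function(annotation, config) {
  withr::with_seed(config$seed + 211L, {
    sizes <- annotation$chrom_sizes %>%
      filter(!.data$chrom %in% annotation$lambda_chrom)
    main <- purrr::pmap_dfr(sizes, function(chrom, length, ...) {
      pos <- seq(as.integer(config$cytosine_spacing %/% 2), length - 1L,
                 by = config$cytosine_spacing)
      tibble(chrom = chrom, position = as.integer(pos))
    })
    main$context <- sample(names(config$context_probs), nrow(main),
                           replace = TRUE, prob = config$context_probs)
    lam_len <- annotation$chrom_sizes$length[
      annotation$chrom_sizes$chrom == config$lambda_chrom]
    lam_pos <- as.integer(floor(seq(10, lam_len - 10, length.out = config$lambda_sites)))
    lambda <- tibble(chrom = config$lambda_chrom, position = lam_pos,
                     context = sample(names(config$context_probs), config$lambda_sites,
                                      replace = TRUE, prob = config$context_probs))
    bind_rows(main, lambda)
  })
}

#' Simulate a bisulfite methylome
#'
#' Cytosine sites are tiled at fixed spacing with contexts assigned once per
#' genome; per-site methylated counts are Binomial(coverage, p), where p is
#' the planted domain mean for CpG sites (modified per genotype, per bin
#' class when the methylation coupling is on, and per ICR), a low constant
#' for CHG/CHH, and `1 - conversion_efficiency_true` on the spike
#' chromosome.  Coverage is Poisson; zero-coverage sites are kept here and
#' dropped by the reader/[site_levels()].
#'
#' @param truth An `epi_truth`.
#' @param annotation The matching annotation.
#' @param genotype `"WT"` or `"KO"`.
#' @param config The [sim_config()].
#' @param seed Optional seed.
#' @param sample_id Label stored on the result.
#' @return Coverage tibble `chrom`, `position`, `context`, `methylated`,
#'   `unmethylated` with `sample_id`/`genotype` attributes.
#' @export
simulate_wgbs <- function(truth, annotation, genotype, config,
                          seed = NULL, sample_id = paste0("WGBS_", genotype)) {
  if (!is.null(seed)) set.seed(seed)
  sites <- wgbs_site_layout(annotation, config)
  p <- wgbs_site_probs(sites, truth, annotation, genotype, config)
  coverage <- rpois(nrow(sites), config$coverage_mean)
  meth <- rbinom(nrow(sites), coverage, p)
  out <- sites %>% mutate(methylated = meth, unmethylated = coverage - meth)
  attr(out, "sample_id") <- sample_id
  attr(out, "genotype") <- genotype
  out
}

# Internal: planted per-site methylation probability.
wgbs_site_probs <- function(sites, truth, annotation, genotype, config) {
  p <- rep(config$methylation_low, nrow(sites))
  lvl_col <- if (genotype == "WT") "wt_level" else "ko_level"
  dom <- overlap_assign(
    sites %>% mutate(start = .data$position, end = .data$position + 1L),
    truth$domains %>% mutate(label = sprintf("%.6f", .data[[lvl_col]])),
    mode = "any")$label
  p[!is.na(dom)] <- as.numeric(dom[!is.na(dom)])
  if (genotype == "KO" && config$couple_methylation) {
    gain <- truth$bin_class %>% filter(.data$class %in% c("I", "II", "III"))
    in_gain <- sites_in(sites, gain)
    p[in_gain] <- pmax(0, config$methylation_high - config$meth_ko_delta)
  }
  icrs <- annotation$icrs
  if (nrow(icrs) > 0) {
    for (i in seq_len(nrow(icrs))) {
      sel <- sites$chrom == icrs$chrom[i] &
        sites$position >= icrs$start[i] & sites$position < icrs$end[i]
      p[sel] <- if (icrs$parent[i] == "maternal") {
        if (genotype == "WT") config$icr_meth_wt_maternal else config$icr_meth_ko_maternal
      } else {
        config$icr_meth_paternal
      }
    }
  }
  p[sites$context != "CpG"] <- config$chh_level
  p[sites$chrom == config$lambda_chrom] <- 1 - config$conversion_efficiency_true
  p
}

#' Simulate the expression table
#'
#' FPKM values are log-normal around the planted per-genotype means (the
#' log-scale mean is shifted by `-dispersion^2 / 2` so the arithmetic mean
#' equals the planted mean); `dispersion = 0` returns the means exactly.
#'
#' @param truth An `epi_truth`.
#' @param config The [sim_config()].
#' @param seed Optional seed.
#' @return Tibble `gene_id`, `WT`, `KO`.
#' @export
simulate_expression <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- truth$expression
  draw <- function(mu) {
    if (config$dispersion == 0) return(mu)
    rlnorm(length(mu), meanlog = log(mu) - config$dispersion^2 / 2,
           sdlog = config$dispersion)
  }
  tibble(gene_id = e$gene_id, WT = draw(e$wt_mean), KO = draw(e$ko_mean))
}

#' Simulate the full two-genotype dataset
#'
#' Runs the whole generator under one seed: toy genome, planted truth,
#' 8 ChIP read sets (4 marks x 2 genotypes), replicated WGBS methylomes per
#' genotype and the expression table.
#'
#' @param config A [sim_config()].
#' @return An `epi_simulation`: list with `annotation`, `truth`, `reads`
#'   (named list of `epi_reads`), `methylomes` (named list of coverage
#'   tibbles), `expression` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  annotation <- build_toy_genome(config)
  truth <- plant_truth(config, annotation)
  reads <- list()
  for (mark in chip_marks()) {
    for (genotype in c("WT", "KO")) {
      nm <- paste(mark, genotype, sep = "_")
      reads[[nm]] <- simulate_chip_reads(truth, annotation, mark, genotype, config)
    }
  }
  methylomes <- list()
  for (genotype in c("WT", "KO")) {
    for (rep_i in seq_len(config$n_meth_reps)) {
      nm <- sprintf("%s_rep%d", genotype, rep_i)
      methylomes[[nm]] <- simulate_wgbs(truth, annotation, genotype, config,
                                        sample_id = nm)
    }
  }
  expression <- simulate_expression(truth, config)
  structure(
    list(annotation = annotation, truth = truth, reads = reads,
         methylomes = methylomes, expression = expression, config = config),
    class = "epi_simulation"
  )
}

#' Write a simulation to a directory of plain-text fixtures
#'
#' Emits the annotation tables, one BED per ChIP sample, reference peak BEDs
#' (the regions where the truth places each mark), methylation coverage
#' tables, the FPKM table, the ground-truth tables and a manifest with an
#' MD5 checksum per file.
#'
#' @param sim An `epi_simulation`.
#' @param outdir Output directory; its parent must exist.
#' @return The manifest tibble (`path`, `md5`), invisibly.
#' @export
write_fixture_bundle <- function(sim, outdir) {
  parent <- dirname(normalizePath(outdir, mustWork = FALSE))
  if (!dir.exists(parent)) abort(sprintf("parent directory does not exist: %s", parent))
  dir.create(outdir, showWarnings = FALSE)
  cfg <- sim$config
  write_annotation_dir(sim$annotation, file.path(outdir, "annotation"))
  dir.create(file.path(outdir, "reads"), showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  chip_meta <- purrr::imap_dfr(sim$reads, function(rs, nm) {
    reads_path <- file.path("reads", paste0(nm, ".bed"))
    write_bed(rs$reads, file.path(outdir, reads_path))
    peaks <- enriched_regions(sim$truth, sim$annotation, rs$mark, rs$genotype, cfg)
    peaks_path <- file.path("peaks", paste0(nm, "_peaks.bed"))
    if (is.null(peaks)) {
      peaks <- tibble(chrom = character(), start = integer(), end = integer())
    }
    write_bed(peaks[, c("chrom", "start", "end")] %>% arrange(.data$chrom, .data$start),
              file.path(outdir, peaks_path))
    tibble(sample_id = nm, mark = rs$mark, genotype = rs$genotype,
           total_mapped = rs$total_mapped, reads = reads_path, peaks = peaks_path)
  })
  readr::write_tsv(chip_meta, file.path(outdir, "samples_chip.tsv"), progress = FALSE)
  dir.create(file.path(outdir, "methylation"), showWarnings = FALSE)
  meth_meta <- purrr::imap_dfr(sim$methylomes, function(mc, nm) {
    path <- file.path("methylation", paste0(nm, ".tsv"))
    readr::write_tsv(mc, file.path(outdir, path), progress = FALSE)
    tibble(sample_id = nm, genotype = attr(mc, "genotype"), path = path)
  })
  readr::write_tsv(meth_meta, file.path(outdir, "samples_meth.tsv"), progress = FALSE)
  readr::write_tsv(sim$expression, file.path(outdir, "fpkm.tsv"), progress = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  readr::write_tsv(sim$truth$promoter_state,
                   file.path(outdir, "truth", "promoter_states.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$bin_class,
                   file.path(outdir, "truth", "bin_classes.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$domains,
                   file.path(outdir, "truth", "domains.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$expression,
                   file.path(outdir, "truth", "expression_effects.tsv"), progress = FALSE)
  files <- sort(setdiff(
    list.files(outdir, recursive = TRUE),
    "manifest.tsv"
  ))
  manifest <- tibble(
    path = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
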