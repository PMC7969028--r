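#' Combinatorial promoter chromatin states
#'
#' A mark is called present at a promoter when its RPKM is strictly above
#' the threshold.  The state is the set of present marks among H3K4me3
#' (`K4`), H3K27me3 (`K27`) and H2AK119ub1 (`ub`), written `+`-joined in
#' that order (`"none"` for the empty set).  The four-group label ignores
#' `ub`: A = K4 without K27, B = bivalent (both), C = K27 only, D = neither.
#'
#' @param promoter_rpkm Tibble with `gene_id` and RPKM columns `K4`, `K27`,
#'   `ub` measured on the same promoter set.
#' @param threshold Presence threshold (default 1, strict `>`).
#' @return Tibble `gene_id`, `K4`, `K27`, `ub` (logical presence), `state`,
#'   `group`.
#' @export
classify_promoter_states <- function(promoter_rpkm, threshold = 1) {
  need <- c("gene_id", "K4", "K27", "ub")
  if (!all(need %in% names(promoter_rpkm))) {
    abort("promoter_rpkm needs columns gene_id, K4, K27, ub")
  }
  if (anyNA(promoter_rpkm[need])) {
    abort("promoter sets differ across marks: missing RPKM values")
  }
  x <- as_tibble(promoter_rpkm)
  k4 <- x$K4 > threshold
  k27 <- x$K27 > threshold
  ub <- x$ub > threshold
  state <- purrr::pmap_chr(list(k4, k27, ub), function(a, b, c) {
    present <- c("K4", "K27", "ub")[c(a, b, c)]
    if (length(present) == 0) "none" else paste(present, collapse = "+")
  })
  tibble(gene_id = x$gene_id, K4 = k4, K27 = k27, ub = ub,
         state = state, group = four_group_label(k4, k27))
}

# Internal: box summary with 1.5 x IQR whiskers clamped to observed values.
box_summary <- function(v) {
  if (length(v) == 0) {
    return(tibble(n = 0L, mean = NA_real_, median = NA_real_,
                  q1 = NA_real_, q3 = NA_real_,
                  whisker_low = NA_real_, whisker_high = NA_real_))
  }
  q1 <- unname(quantile(v, 0.25))
  q3 <- unname(quantile(v, 0.75))
  iqr <- q3 - q1
  tibble(
    n = length(v), mean = mean(v), median = median(v), q1 = q1, q3 = q3,
    whisker_low = min(v[v >= q1 - 1.5 * iqr]),
    whisker_high = max(v[v <= q3 + 1.5 * iqr])
  )
}

#' Expression distribution per promoter state
#'
#' Per-state count, median, quartiles and 1.5 x IQR whiskers of FPKM, ranked
#' by median.  Empty states are reported with `n = 0`.
#'
#' @param states Output of [classify_promoter_states()].
#' @param expression Tibble with `gene_id` and FPKM columns.
#' @param sample Name of the FPKM column to summarise.
#' @return Tibble `state`, box summary columns, `rank` (1 = highest median).
#' @export
expression_by_state <- function(states, expression, sample = "WT") {
  if (!sample %in% names(expression)) {
    abort(sprintf("no column '%s' in expression table", sample))
  }
  joined <- states %>% inner_join(expression, by = "gene_id")
  out <- joined %>%
    mutate(state = factor(.data$state, levels = promoter_state_names())) %>%
    group_by(.data$state, .drop = FALSE) %>%
    summarise(box_summary(.data[[sample]]), .groups = "drop") %>%
    mutate(state = as.character(.data$state))
  out$rank <- rank(-out$median, ties.method = "min", na.last = "keep")
  out
}

#' Fold-change differential expression calls
#'
#' A gene is called down when `(WT + pseudocount) / (KO + pseudocount)`
#' exceeds `fold` and WT FPKM clears the expression floor; up is symmetric.
#' The pseudocount keeps the printed ratio rule finite as FPKM approaches 0.
#'
#' @param expression Tibble with `gene_id` and the two genotype columns.
#' @param wt,ko Column names for the two genotypes.
#' @param fold Ratio threshold (default 1.5, strict `>`).
#' @param min_fpkm Expression floor on the higher genotype (default 0.5).
#' @param pseudocount Added to both FPKM values (default 0.1).
#' @return Tibble `gene_id`, `wt_fpkm`, `ko_fpkm`, `ratio`
#'   (pseudocounted WT/KO), `status` in `down`/`up`/`unchanged`.
#' @export
call_de_genes <- function(expression, wt = "WT", ko = "KO",
                          fold = 1.5, min_fpkm = 0.5, pseudocount = 0.1) {
  if (!all(c(wt, ko) %in% names(expression))) {
    abort("expression table lacks the requested genotype columns")
  }
  w <- expression[[wt]]
  k <- expression[[ko]]
  ratio <- (w + pseudocount) / (k + pseudocount)
  tibble(
    gene_id = expression$gene_id, wt_fpkm = w, ko_fpkm = k, ratio = ratio,
    status = dplyr::case_when(
      ratio > fold & w >= min_fpkm ~ "down",
      (1 / ratio) > fold & k >= min_fpkm ~ "up",
      TRUE ~ "unchanged"
    )
  )
}

#' Two-set overlap counts
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates ignored).
#' @return Tibble `a_only`, `both`, `b_only`.
#' @export
set_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  tibble(a_only = length(setdiff(a, b)), both = length(intersect(a, b)),
         b_only = length(setdiff(b, a)))
}

# Internal: per-mark directional change call between genotypes.
mark_change_call <- function(wt, ko, up_fold = 2, down_fold = 2,
                             min_rpkm = 2, pseudocount = 0.5) {
  up <- (ko + pseudocount) / (wt + pseudocount) >= up_fold & ko >= min_rpkm
  down <- (wt + pseudocount) / (ko + pseudocount) >= down_fold & wt >= min_rpkm
  dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ "none")
}

#' Six-class taxonomy of bins by directional Polycomb-mark change
#'
#' Calls each mark up/down/none between genotypes (fold change with
#' pseudocount plus an RPKM floor on the higher side), then maps the pair of
#' calls to a class: K27 up only = I, both up = II, ub up only = III,
#' K27 down only = IV, both down = V, ub down only = VI; opposite-direction
#' pairs are `mixed` and no change is `unchanged`.  The classes partition
#' the bins, and relabeling the genotypes swaps I/IV, II/V, III/VI exactly.
#'
#' @param bin_rpkm Tibble with `bin_id` and RPKM columns `k27_wt`, `k27_ko`,
#'   `ub_wt`, `ub_ko` on one shared bin tiling.
#' @param up_fold,down_fold Fold thresholds (default 2, `>=`).
#' @param min_rpkm RPKM floor on the elevated genotype (default 2).
#' @param pseudocount Added to both values in the ratio (default 0.5).
#' @return Tibble `bin_id`, the four RPKM columns, `k27_call`, `ub_call`,
#'   `class`.
#' @export
classify_bin_changes <- function(bin_rpkm, up_fold = 2, down_fold = 2,
                                 min_rpkm = 2, pseudocount = 0.5) {
  need <- c("bin_id", "k27_wt", "k27_ko", "ub_wt", "ub_ko")
  if (!all(need %in% names(bin_rpkm))) {
    abort("bin_rpkm needs columns bin_id, k27_wt, k27_ko, ub_wt, ub_ko")
  }
  if (anyNA(bin_rpkm[need])) abort("bin tilings differ across tracks: missing values")
  x <- as_tibble(bin_rpkm)
  k27 <- mark_change_call(x$k27_wt, x$k27_ko, up_fold, down_fold, min_rpkm, pseudocount)
  ub <- mark_change_call(x$ub_wt, x$ub_ko, up_fold, down_fold, min_rpkm, pseudocount)
  cls <- dplyr::case_when(
    k27 == "up" & ub == "none" ~ "I",
    k27 == "up" & ub == "up" ~ "II",
    k27 == "none" & ub == "up" ~ "III",
    k27 == "down" & ub == "none" ~ "IV",
    k27 == "down" & ub == "down" ~ "V",
    k27 == "none" & ub == "down" ~ "VI",
    k27 == "none" & ub == "none" ~ "unchanged",
    TRUE ~ "mixed"
  )
  x %>% mutate(k27_call = k27, ub_call = ub, class = cls)
}

#' Two-class change table for a single mark
#'
#' Reuses the per-mark change caller of [classify_bin_changes()] to label
#' each bin up/down/unchanged for one mark (e.g. H3K36me3).  Relabeling the
#' genotypes swaps up and down exactly.
#'
#' @param bin_rpkm Tibble with `bin_id`, `wt`, `ko` RPKM columns.
#' @inheritParams classify_bin_changes
#' @return Tibble `bin_id`, `wt`, `ko`, `change` in `up`/`down`/`unchanged`.
#' @export
bin_mark_change_classes <- function(bin_rpkm, up_fold = 2, down_fold = 2,
                                    min_rpkm = 2, pseudocount = 0.5) {
  need <- c("bin_id", "wt", "ko")
  if (!all(need %in% names(bin_rpkm))) {
    abort("bin_rpkm needs columns bin_id, wt, ko")
  }
  call <- mark_change_call(bin_rpkm$wt, bin_rpkm$ko, up_fold, down_fold,
                           min_rpkm, pseudocount)
  as_tibble(bin_rpkm) %>%
    mutate(change = if_else(call == "none", "unchanged", call))
}

#' Pooled-variance Student's t test
#'
#' Classical two-tailed Student's t: pooled-variance unpaired, or paired on
#' the differences.  Degenerate inputs are handled explicitly: zero variance
#' with equal means gives `t = 0, p = 1`; zero variance with unequal means
#' gives an infinite statistic and the smallest representable p.
#'
#' @param x,y Numeric vectors (equal length when paired).
#' @param flavor `"unpaired"` (default) or `"paired"`.
#' @return An `epi_ttest`: list with `statistic`, `df`, `p_value`, `flavor`,
#'   `estimate` (mean difference), `n_x`, `n_y`, group means.
#' @export
students_t_test <- function(x, y, flavor = c("unpaired", "paired")) {
  flavor <- match.arg(flavor)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (flavor == "paired") {
    if (length(x) != length(y)) abort("paired test needs equal group sizes")
    if (length(x) < 2) abort("paired test needs n >= 2")
  } else if (length(x) < 2 || length(y) < 2) {
    abort("unpaired test needs n >= 2 in both groups")
  }
  degenerate <- if (flavor == "paired") sd(x - y) == 0 else sd(x) == 0 && sd(y) == 0
  if (degenerate) {
    delta <- mean(x) - mean(y)
    res <- list(
      statistic = if (delta == 0) 0 else sign(delta) * Inf,
      df = if (flavor == "paired") length(x) - 1 else length(x) + length(y) - 2,
      p_value = if (delta == 0) 1 else .Machine$double.xmin,
      flavor = flavor, estimate = delta,
      n_x = length(x), n_y = length(y), mean_x = mean(x), mean_y = mean(y)
    )
    return(structure(res, class = "epi_ttest"))
  }
  ht <- stats::t.test(x, y, paired = flavor == "paired", var.equal = TRUE,
                      alternative = "two.sided")
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = max(ht$p.value, .Machine$double.xmin), flavor = flavor,
         estimate = mean(x) - mean(y),
         n_x = length(x), n_y = length(y), mean_x = mean(x), mean_y = mean(y)),
    class = "epi_ttest"
  )
}

#' @export
print.epi_ttest <- function(x, ...) {
  cat(sprintf("Two-tailed %s Student's t test\n", x$flavor))
  cat(sprintf("  t = %.4g, df = %g, p = %.4g\n", x$statistic, x$df, x$p_value))
  cat(sprintf("  mean(x) = %.4g (n = %d), mean(y) = %.4g (n = %d)\n",
              x$mean_x, x$n_x, x$mean_y, x$n_y))
  invisible(x)
}

#' Per-class covariate summaries and tests
#'
#' For each bin-change class, summarises region-level covariates (e.g. CpG
#' methylation of the bin, RPKM of another mark) per genotype and tests the
#' WT/KO difference: unpaired Student's t for region-level covariates,
#' paired for the expression of the same genes across genotypes.
#'
#' @param bin_classes Output of [classify_bin_changes()] joined to bin
#'   coordinates (`bin_id`, `chrom`, `start`, `end`, `class`).
#' @param covariates Named list; each element is a tibble
#'   `bin_id`, `wt`, `ko` of a region-level covariate resolved to bins.
#' @param expression Optional tibble `gene_id`, `wt`, `ko` of gene FPKM.
#' @param genes Gene tibble; genes are linked to bins by the body midpoint.
#'   Required when `expression` is given.
#' @return List with `summaries` (tibble class x covariate x genotype box
#'   summaries) and `tests` (tibble class x covariate with `statistic`,
#'   `df`, `p_value`, `flavor`).  Classes with no bins are reported empty.
#' @export
bin_class_covariates <- function(bin_classes, covariates = list(),
                                 expression = NULL, genes = NULL) {
  need <- c("bin_id", "chrom", "start", "end", "class")
  if (!all(need %in% names(bin_classes))) {
    abort("bin_classes needs columns bin_id, chrom, start, end, class")
  }
  cov_long <- purrr::imap_dfr(covariates, function(tb, nm) {
    bin_classes %>%
      select("bin_id", "class") %>%
      left_join(tb, by = "bin_id") %>%
      tidyr::pivot_longer(c("wt", "ko"), names_to = "genotype", values_to = "value") %>%
      mutate(covariate = nm, unit = .data$bin_id)
  })
  if (!is.null(expression)) {
    if (is.null(genes)) abort("expression covariate needs the gene table")
    mid <- interval_midpoint(genes$start, genes$end)
    gene_bin <- overlap_assign(
      tibble(chrom = genes$chrom, start = mid, end = mid + 1L),
      bin_classes %>% mutate(label = .data$bin_id), mode = "any")$label
    expr_long <- tibble(gene_id = genes$gene_id, bin_id = gene_bin) %>%
      filter(!is.na(.data$bin_id)) %>%
      inner_join(expression, by = "gene_id") %>%
      inner_join(bin_classes %>% select("bin_id", "class"), by = "bin_id") %>%
      tidyr::pivot_longer(c("wt", "ko"), names_to = "genotype", values_to = "value") %>%
      mutate(covariate = "expression", unit = .data$gene_id) %>%
      select("bin_id", "class", "genotype", "value", "covariate", "unit")
    cov_long <- bind_rows(cov_long, expr_long)
  }
  if (nrow(cov_long) == 0) {
    return(list(summaries = tibble(), tests = tibble()))
  }
  summaries <- cov_long %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$class, .data$covariate, .data$genotype) %>%
    summarise(box_summary(.data$value), .groups = "drop")
  tests <- cov_long %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$class, .data$covariate) %>%
    summarise({
      u <- .data$unit; g <- .data$genotype; v <- .data$value
      flavor <- if (dplyr::cur_group()$covariate == "expression") "paired" else "unpaired"
      wide <- tibble(unit = u, genotype = g, value = v) %>%
        tidyr::pivot_wider(names_from = "genotype", values_from = "value")
      ok <- if (flavor == "paired") {
        nrow(wide) >= 2 && all(c("wt", "ko") %in% names(wide)) &&
          all(complete.cases(wide[, c("wt", "ko")]))
      } else {
        all(c("wt", "ko") %in% names(wide)) &&
          sum(!is.na(wide$wt)) >= 2 && sum(!is.na(wide$ko)) >= 2
      }
      if (!ok) {
        tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
               flavor = flavor, n = nrow(wide))
      } else {
        tt <- students_t_test(wide$wt, wide$ko, flavor = flavor)
        tibble(statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
               flavor = flavor, n = nrow(wide))
      }
    }, .groups = "drop")
  list(summaries = summaries, tests = tests)
}

#' TSS-anchored methylation metaprofile by promoter state
#'
#' Mean CpG methylation level by signed offset from the TSS (minus-strand
#' genes flipped), separately for each promoter chromatin state.  States
#' with no genes are omitted.
#'
#' @param sites Site table from [site_levels()].
#' @param states Output of [classify_promoter_states()].
#' @param genes Gene tibble with `tss` and `strand`.
#' @param window Half-width in bp (default 2000).
#' @param step Offset bin width in bp (default 100).
#' @return Tibble `state`, `offset`, `n_sites`, `mean_level`.
#' @export
methylation_profile_by_tss_state <- function(sites, states, genes,
                                             window = 2000, step = 100) {
  if ((2 * window) %% step != 0) abort("step must divide 2 * window")
  cpg <- sites %>% filter(.data$context == "CpG")
  anchors <- genes %>%
    inner_join(states %>% select("gene_id", "state"), by = "gene_id")
  win <- tibble(chrom = anchors$chrom,
                start = pmax(0L, as.integer(anchors$tss - window)),
                end = as.integer(anchors$tss + window))
  hits <- GenomicRanges::findOverlaps(as_gr(win), points_gr(cpg$chrom, cpg$position),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(tibble(state = character(), offset = integer(),
                  n_sites = integer(), mean_level = double()))
  }
  a <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d <- ifelse(anchors$strand[a] == "-",
              anchors$tss[a] - cpg$position[s],
              cpg$position[s] - anchors$tss[a])
  ok <- d >= -window & d < window
  tibble(state = anchors$state[a][ok],
         offset = as.integer(floor(d[ok] / step) * step),
         level = cpg$level[s][ok]) %>%
    group_by(.data$state, .data$offset) %>%
    summarise(n_sites = n(), mean_level = mean(.data$level), .groups = "drop") %>%
    arrange(.data$state, .data$offset)
}

#' Compare recovered promoter states with the planted truth
#'
#' @param states Output of [classify_promoter_states()].
#' @param truth An `epi_truth`.
#' @return List with `accuracy` (fraction of genes whose recovered state
#'   equals the planted state) and `confusion` (planted x recovered counts).
#' @export
recover_promoter_states <- function(states, truth) {
  joined <- truth$promoter_state %>%
    select("gene_id", planted = "state") %>%
    inner_join(states %>% select("gene_id", recovered = "state"), by = "gene_id")
  list(
    accuracy = mean(joined$planted == joined$recovered),
    confusion = joined %>% count(.data$planted, .data$recovered)
  )
}

#' Compare recovered bin classes with the planted truth
#'
#' Accuracy is measured over the bins planted as classes I-VI: the fraction
#' assigned exactly the planted class.
#'
#' @param bin_changes Output of [classify_bin_changes()].
#' @param truth An `epi_truth`.
#' @return List with `accuracy`, `confusion`.
#' @export
recover_bin_classes <- function(bin_changes, truth) {
  joined <- truth$bin_class %>%
    select("bin_id", planted = "class") %>%
    inner_join(bin_changes %>% select("bin_id", recovered = "class"), by = "bin_id")
  changed <- joined %>% filter(.data$planted %in% bin_class_names())
  list(
    accuracy = mean(changed$planted == changed$recovered),
    confusion = joined %>% count(.data$planted, .data$recovered)
  )
}
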