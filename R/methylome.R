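#' Classify the cytosine context of a trinucleotide
#'
#' `CG*` is CpG, `C[ACT]G` is CHG and `C[ACT][ACT]` is CHH, where H is A, T
#' or C.
#'
#' @param trinucleotide Character vector of 3-letter upstream-to-downstream
#'   sequences starting with `C`, alphabet `ACGT`.
#' @return Character vector of `"CpG"`, `"CHG"` or `"CHH"`.
#' @export
classify_cytosine_context <- function(trinucleotide) {
  tri <- toupper(trinucleotide)
  if (any(nchar(tri) != 3)) abort("trinucleotide must have exactly 3 letters")
  if (any(!grepl("^[ACGT]{3}$", tri))) abort("trinucleotide alphabet must be A/C/G/T")
  if (any(substr(tri, 1, 1) != "C")) abort("trinucleotide must start with C")
  second <- substr(tri, 2, 2)
  third <- substr(tri, 3, 3)
  if_else(second == "G", "CpG", if_else(third == "G", "CHG", "CHH"))
}

#' Per-site methylation levels
#'
#' Converts raw cytosine counts into per-site levels
#' `methylated / (methylated + unmethylated)`, dropping sites below the
#' coverage floor.
#'
#' @param calls Coverage tibble from [read_methylation_coverage()] or
#'   [simulate_wgbs()].
#' @param min_coverage Minimum total calls for a site to be retained
#'   (default 1; real WGBS practice typically uses 3-5, the desk-scale
#'   default keeps shallow simulated sites).
#' @return Tibble `chrom`, `position`, `context`, `coverage`, `level`;
#'   attribute `"dropped_low_coverage"` counts removed sites.
#' @export
site_levels <- function(calls, min_coverage = 1) {
  x <- as_tibble(calls)
  cov <- x$methylated + x$unmethylated
  keep <- cov >= min_coverage
  out <- tibble(
    chrom = x$chrom[keep], position = x$position[keep],
    context = x$context[keep], coverage = cov[keep],
    level = x$methylated[keep] / cov[keep]
  )
  attr(out, "dropped_low_coverage") <- sum(!keep)
  attr(out, "sample_id") <- attr(calls, "sample_id", exact = TRUE)
  attr(out, "genotype") <- attr(calls, "genotype", exact = TRUE)
  out
}

#' Global methylation summaries by context
#'
#' Unweighted per-site mean plus distribution summaries for each cytosine
#' context.  Contexts with no sites are reported as missing (`n = 0`,
#' `NA` summaries), never as zero.
#'
#' @param sites Site table from [site_levels()].
#' @return Tibble `context`, `n`, `mean`, `q1`, `median`, `q3`.
#' @export
global_levels_by_context <- function(sites) {
  if (nrow(sites) == 0) abort("empty site table")
  all_ctx <- c("CpG", "CHG", "CHH")
  sites %>%
    mutate(context = factor(.data$context, levels = all_ctx)) %>%
    group_by(.data$context, .drop = FALSE) %>%
    summarise(n = n(),
              mean = if (n() > 0) mean(.data$level) else NA_real_,
              q1 = if (n() > 0) unname(quantile(.data$level, 0.25)) else NA_real_,
              median = if (n() > 0) median(.data$level) else NA_real_,
              q3 = if (n() > 0) unname(quantile(.data$level, 0.75)) else NA_real_,
              .groups = "drop") %>%
    mutate(context = as.character(.data$context))
}

# Internal: TRUE for sites overlapping any interval in `ivs`.
sites_in <- function(sites, ivs) {
  if (nrow(ivs) == 0 || nrow(sites) == 0) return(rep(FALSE, nrow(sites)))
  sgr <- points_gr(sites$chrom, sites$position)
  GenomicRanges::countOverlaps(sgr, as_gr(ivs[, c("chrom", "start", "end")]),
                               ignore.strand = TRUE) > 0
}

#' Mean CpG methylation by genome element
#'
#' Unweighted mean of CpG site levels over each element class.  A site may
#' contribute to several classes (a gene-body site inside a CGI counts in
#' both); `intergenic` collects CpG sites in neither a gene body nor a
#' promoter.  Element classes without intervals in the annotation (e.g.
#' exon/intron subdivision in a toy annotation) are reported as absent.
#'
#' @param sites Site table from [site_levels()].
#' @param annotation An `epi_annotation`.
#' @param promoter_flank Promoter half-width in bp.
#' @return Tibble `element`, `n_sites`, `mean_level` (`NA` when the class has
#'   no intervals or no covered sites).
#' @export
aggregate_by_element <- function(sites, annotation, promoter_flank = 2000) {
  cpg <- sites %>% filter(.data$context == "CpG",
                          !.data$chrom %in% annotation$lambda_chrom)
  genes <- annotation$genes
  promoters <- if (nrow(genes) > 0) {
    promoters_from_genes(genes, flank = promoter_flank,
                         chrom_sizes = annotation$chrom_sizes)
  } else genes
  element_sets <- list(
    promoter = promoters,
    `gene body` = genes,
    CGI = annotation$cgis,
    repeat_ = annotation$repeats,
    ICR = annotation$icrs
  )
  in_body <- sites_in(cpg, genes)
  in_prom <- sites_in(cpg, promoters)
  rows <- purrr::imap_dfr(element_sets, function(ivs, nm) {
    nm <- sub("_$", "", nm)
    if (nrow(ivs) == 0) {
      return(tibble(element = nm, n_sites = NA_integer_, mean_level = NA_real_))
    }
    inside <- sites_in(cpg, ivs)
    tibble(element = nm, n_sites = sum(inside),
           mean_level = if (any(inside)) mean(cpg$level[inside]) else NA_real_)
  })
  inter <- !in_body & !in_prom
  bind_rows(rows, tibble(element = "intergenic", n_sites = sum(inter),
                         mean_level = if (any(inter)) mean(cpg$level[inter]) else NA_real_))
}

#' Methylation of imprinting control regions
#'
#' Per-ICR unweighted mean of CpG site levels, with summaries grouped by the
#' methylated parent-of-origin.  ICRs with no covered CpG are reported with
#' `NA` (missing), not zero.
#'
#' @param sites Site table from [site_levels()].
#' @param annotation An `epi_annotation` with ICRs.
#' @return List with `per_icr` (tibble `icr_id`, `parent`, `n_sites`,
#'   `mean_level`) and `by_parent` (tibble `parent`, `n_icrs`, `mean`,
#'   `median`).
#' @export
icr_levels <- function(sites, annotation) {
  icrs <- annotation$icrs
  if (nrow(icrs) == 0) abort("annotation has no ICRs")
  cpg <- sites %>% filter(.data$context == "CpG")
  sgr <- points_gr(cpg$chrom, cpg$position)
  per_icr <- purrr::pmap_dfr(icrs, function(icr_id, chrom, start, end, parent, ...) {
    hit <- which(GenomicRanges::countOverlaps(
      sgr, as_gr(tibble(chrom = chrom, start = start, end = end)),
      ignore.strand = TRUE) > 0)
    tibble(icr_id = icr_id, parent = parent, n_sites = length(hit),
           mean_level = if (length(hit) > 0) mean(cpg$level[hit]) else NA_real_)
  })
  by_parent <- per_icr %>%
    filter(!is.na(.data$mean_level)) %>%
    group_by(.data$parent) %>%
    summarise(n_icrs = n(), mean = mean(.data$mean_level),
              median = median(.data$mean_level), .groups = "drop")
  list(per_icr = per_icr, by_parent = by_parent)
}

#' Bisulfite conversion efficiency from the unmethylated spike-in
#'
#' Pooled over every cytosine context on the spike chromosome:
#' `1 - total methylated calls / total calls`.  An unmethylated spike (e.g.
#' lambda phage DNA) should give a value close to 1.
#'
#' @param calls Coverage tibble (raw counts, not site levels).
#' @param lambda_chrom Name of the spike chromosome.
#' @return Conversion efficiency in `[0, 1]`.
#' @export
conversion_efficiency <- function(calls, lambda_chrom) {
  x <- calls %>% filter(.data$chrom == lambda_chrom)
  total <- sum(x$methylated) + sum(x$unmethylated)
  if (total == 0) abort(sprintf("no covered cytosines on spike chromosome '%s'", lambda_chrom))
  1 - sum(x$methylated) / total
}

#' Unsupervised clustering of samples by CpG methylation
#'
#' Hierarchical clustering (average linkage) on `1 - Pearson correlation`
#' over the CpG sites covered in every sample.
#'
#' @param site_tables Named list (>= 2) of site tables from [site_levels()].
#' @param min_coverage Coverage floor applied per sample before intersecting.
#' @param min_shared_sites Minimum number of CpG sites shared by all samples.
#' @return An `epi_meth_clust`: list with `hclust`, `dist`, `k2` (named
#'   integer cluster labels at the k = 2 cut), `n_shared_sites`.
#' @export
cluster_samples_by_cpg <- function(site_tables, min_coverage = 1, min_shared_sites = 100) {
  if (length(site_tables) < 2) abort("need at least 2 samples")
  nms <- names(site_tables)
  if (is.null(nms) || any(!nzchar(nms))) abort("site_tables must be a named list")
  mats <- purrr::imap(site_tables, function(s, nm) {
    s %>%
      filter(.data$context == "CpG", .data$coverage >= min_coverage) %>%
      mutate(site = paste0(.data$chrom, ":", .data$position)) %>%
      select("site", !!nm := "level")
  })
  shared <- purrr::reduce(mats, inner_join, by = "site")
  if (nrow(shared) < min_shared_sites) {
    abort(sprintf("only %d CpG sites shared by all samples (need >= %d)",
                  nrow(shared), min_shared_sites))
  }
  m <- as.matrix(shared[, nms, drop = FALSE])
  if (any(apply(m, 2, sd) == 0)) {
    abort("undefined correlation: a sample has constant methylation levels")
  }
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  structure(
    list(hclust = hc, dist = d, k2 = cutree(hc, k = 2), n_shared_sites = nrow(shared)),
    class = "epi_meth_clust"
  )
}

#' @export
print.epi_meth_clust <- function(x, ...) {
  cat(sprintf("<epi_meth_clust> %d samples over %d shared CpG sites\n",
              length(x$k2), x$n_shared_sites))
  cat("  k = 2 cut:", paste(sprintf("%s=%d", names(x$k2), x$k2), collapse = "  "), "\n")
  invisible(x)
}

#' Export a sample dendrogram in Newick format
#'
#' @param clust An `epi_meth_clust`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clust, path) {
  phy <- ape::as.phylo(clust$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
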