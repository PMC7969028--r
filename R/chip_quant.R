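#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled from 0 in steps of `bin_size`; the terminal bin is
#' truncated at the chromosome end.  Bin ids are `"chrom:start-end"`.
#'
#' @param annotation An `epi_annotation`.
#' @param bin_size Bin width in bp (default 10 kb, the resolution used for
#'   genome-wide chromatin-change maps).
#' @param include_lambda Whether to tile the spike-in chromosome too.
#' @return Tibble `bin_id`, `chrom`, `start`, `end`.
#' @export
make_bins <- function(annotation, bin_size = 10000, include_lambda = FALSE) {
  if (bin_size <= 0) abort("bin_size must be > 0")
  sizes <- annotation$chrom_sizes
  if (!include_lambda) sizes <- sizes %>% filter(!.data$chrom %in% annotation$lambda_chrom)
  purrr::pmap_dfr(sizes, function(chrom, length, ...) {
    starts <- seq(0L, length - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, length)
    tibble(
      bin_id = sprintf("%s:%d-%d", chrom, starts, ends),
      chrom = chrom, start = as.integer(starts), end = as.integer(ends)
    )
  })
}

#' Promoter windows around annotated TSSs
#'
#' Promoters are the regions flanking the annotated TSS by `flank` bp on each
#' side (default +/- 2 kb, i.e. 4-kb windows), clipped to chromosome bounds.
#'
#' @param genes Gene tibble with `tss` (see [read_gene_table()]).
#' @param flank Half-width in bp.
#' @param chrom_sizes Optional size table used to clip windows.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
promoters_from_genes <- function(genes, flank = 2000, chrom_sizes = NULL) {
  if (!all(genes$strand %in% c("+", "-"))) abort("all genes must be stranded")
  if (!"tss" %in% names(genes)) genes <- add_tss_tes(genes)
  out <- genes %>%
    mutate(start = pmax(0L, as.integer(.data$tss - flank)),
           end = as.integer(.data$tss + flank)) %>%
    select("gene_id", "chrom", "start", "end", "strand", "tss")
  if (!is.null(chrom_sizes)) {
    sz <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    out <- out %>% mutate(end = pmin(.data$end, as.integer(sz[.data$chrom])))
  }
  out
}

# Internal: count read midpoints per feature.  A read is counted in every
# feature containing its midpoint, which makes counts additive over any
# non-overlapping tiling.
count_midpoints <- function(reads, features) {
  mids <- interval_midpoint(reads$start, reads$end)
  mgr <- points_gr(reads$chrom, mids)
  fgr <- as_gr(features[, c("chrom", "start", "end")])
  hits <- GenomicRanges::countOverlaps(fgr, mgr, ignore.strand = TRUE)
  as.integer(hits)
}

#' RPKM signal over a feature set
#'
#' Reads per kilobase of feature per million mapped reads:
#' `count / (length_kb * total_mapped / 1e6)`.  A read is assigned to a
#' feature when its midpoint falls inside the feature (half-open).
#'
#' @param readset An `epi_reads`.
#' @param features Interval tibble; the first non-coordinate id column
#'   (e.g. `bin_id`, `gene_id`, `peak_id`) is carried through.
#' @return `features` with added `count` and `rpkm` columns.
#' @export
rpkm <- function(readset, features) {
  if (!inherits(readset, "epi_reads")) abort("readset must be an epi_reads object")
  if (readset$total_mapped <= 0) abort("total_mapped must be > 0")
  features <- check_intervals(features, what = "features")
  len <- features$end - features$start
  if (any(len <= 0)) abort("feature lengths must be > 0")
  cnt <- count_midpoints(readset$reads, features)
  features %>%
    mutate(count = cnt,
           rpkm = cnt / ((len / 1000) * (readset$total_mapped / 1e6)))
}

#' Quantify several samples over one feature set
#'
#' @param readsets Named list of `epi_reads` (names become column names; when
#'   unnamed, `sample_id` is used).
#' @param features Interval tibble.
#' @return `features` plus one RPKM column per sample.
#' @export
quantify_samples <- function(readsets, features) {
  nms <- names(readsets)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(readsets, function(r) r$sample_id, "")
  }
  out <- as_tibble(features)
  for (i in seq_along(readsets)) {
    out[[nms[i]]] <- rpkm(readsets[[i]], features)$rpkm
  }
  out
}

#' Exclude low-quality peaks
#'
#' Peaks with RPKM below `min_rpkm` are excluded; a peak at exactly the
#' threshold is retained (the exclusion rule is strictly `< min_rpkm`).
#'
#' @param peaks Tibble with an `rpkm` column (e.g. from [rpkm()]).
#' @param min_rpkm Exclusion threshold (default 2).
#' @return List with `retained` (tibble), `excluded` (tibble) and `report`
#'   (tibble `n_in`, `n_retained`, `n_excluded`, `min_rpkm`).
#' @export
filter_low_quality_peaks <- function(peaks, min_rpkm = 2) {
  if (!"rpkm" %in% names(peaks)) abort("peaks need an 'rpkm' column")
  keep <- peaks$rpkm >= min_rpkm
  list(
    retained = peaks[keep, , drop = FALSE],
    excluded = peaks[!keep, , drop = FALSE],
    report = tibble(n_in = nrow(peaks), n_retained = sum(keep),
                    n_excluded = sum(!keep), min_rpkm = min_rpkm)
  )
}

#' Z-score standardization of a signal table
#'
#' Centers and scales with the population standard deviation (divisor `n`).
#' Rows or columns with zero spread map to all zeros, so constant features
#' do not produce NaNs in heat maps.
#'
#' @param x Tibble with id/coordinate columns plus numeric sample columns.
#' @param axis `"feature"` standardizes each row across the sample columns;
#'   `"sample"` standardizes each sample column across features.
#' @param value_cols Character vector of the numeric columns; defaults to all
#'   numeric columns except `start`, `end`, `count`, `length`, `tss`, `tes`.
#' @return `x` with the value columns replaced by z-scores; attribute
#'   `"zscore_axis"` records the axis.
#' @export
zscore_standardize <- function(x, axis = c("feature", "sample"), value_cols = NULL) {
  axis <- match.arg(axis)
  x <- as_tibble(x)
  if (is.null(value_cols)) {
    num <- names(x)[vapply(x, is.numeric, TRUE)]
    value_cols <- setdiff(num, c("start", "end", "count", "length", "tss", "tes", "score"))
  }
  m <- as.matrix(x[, value_cols, drop = FALSE])
  pop_scale <- function(v) {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s == 0) rep(0, length(v)) else (v - mu) / s
  }
  if (axis == "feature") {
    m <- t(apply(m, 1, pop_scale))
  } else {
    m <- apply(m, 2, pop_scale)
  }
  colnames(m) <- value_cols
  for (col in value_cols) x[[col]] <- unname(m[, col])
  attr(x, "zscore_axis") <- axis
  x
}

#' Genomic distribution of peaks
#'
#' Each peak is assigned by its midpoint to one of `TSS`, `TES`, `gene body`
#' or `intergenic`, with that precedence (a midpoint inside both a TSS window
#' and a gene body counts as TSS).
#'
#' @param peaks Interval tibble.
#' @param annotation An `epi_annotation` with stranded genes.
#' @param tss_flank,tes_flank Window half-widths around TSS/TES (default 2 kb).
#' @return Tibble `category`, `n`, `fraction` (fractions sum to 1).
#' @export
peak_genomic_distribution <- function(peaks, annotation, tss_flank = 2000, tes_flank = 2000) {
  peaks <- check_intervals(peaks, what = "peaks")
  genes <- annotation$genes
  cats <- c("TSS", "TES", "gene body", "intergenic")
  if (nrow(peaks) == 0) {
    return(tibble(category = factor(cats, levels = cats), n = 0L, fraction = 0))
  }
  assigned <- rep("intergenic", nrow(peaks))
  if (nrow(genes) > 0) {
    mids <- interval_midpoint(peaks$start, peaks$end)
    mgr <- points_gr(peaks$chrom, mids)
    windows <- list(
      "TSS" = tibble(chrom = genes$chrom,
                     start = pmax(0L, as.integer(genes$tss - tss_flank)),
                     end = as.integer(genes$tss + tss_flank)),
      "TES" = tibble(chrom = genes$chrom,
                     start = pmax(0L, as.integer(genes$tes - tes_flank)),
                     end = as.integer(genes$tes + tes_flank)),
      "gene body" = genes[, c("chrom", "start", "end")]
    )
    # apply in reverse precedence so the strongest category wins last
    for (cat_name in c("gene body", "TES", "TSS")) {
      w <- windows[[cat_name]]
      hit <- GenomicRanges::countOverlaps(mgr, as_gr(w), ignore.strand = TRUE) > 0
      assigned[hit] <- cat_name
    }
  }
  tibble(category = factor(assigned, levels = cats)) %>%
    count(.data$category, .drop = FALSE) %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' TSS-anchored average enrichment profile
#'
#' Bins read midpoints by signed offset from each anchor (minus-strand
#' anchors are orientation-flipped so positive offsets are always
#' downstream), scales to RPKM per offset bin, and averages over anchors.
#'
#' @param readset An `epi_reads`.
#' @param anchors Tibble with `gene_id` (or other id), `chrom`, `pos`,
#'   `strand`.
#' @param window Half-width of the profiled window in bp.
#' @param step Offset bin width in bp; must divide `2 * window`.
#' @return An `epi_profile`: list with `aggregate` (tibble `offset`, `mean`),
#'   `values` (anchors x offsets matrix), `offsets`, `anchors`.
#' @export
average_profile <- function(readset, anchors, window = 2000, step = 100) {
  if (nrow(anchors) == 0) abort("empty anchor list")
  if ((2 * window) %% step != 0) abort("step must divide 2 * window")
  offsets <- seq(-window, window - step, by = step)
  reads <- readset$reads
  mids <- interval_midpoint(reads$start, reads$end)
  mgr <- points_gr(reads$chrom, mids)
  win <- tibble(chrom = anchors$chrom,
                start = pmax(0L, as.integer(anchors$pos - window)),
                end = as.integer(anchors$pos + window))
  hits <- GenomicRanges::findOverlaps(as_gr(win), mgr, ignore.strand = TRUE)
  n_anchor <- nrow(anchors)
  n_off <- length(offsets)
  vals <- matrix(0, nrow = n_anchor, ncol = n_off,
                 dimnames = list(NULL, as.character(offsets)))
  if (length(hits) > 0) {
    a <- S4Vectors::queryHits(hits)
    m <- mids[S4Vectors::subjectHits(hits)]
    d <- ifelse(anchors$strand[a] == "-", anchors$pos[a] - m, m - anchors$pos[a])
    ok <- d >= -window & d < window
    a <- a[ok]; d <- d[ok]
    bin <- floor(d / step) + (window %/% step) + 1L
    tab <- table(factor(a, levels = seq_len(n_anchor)),
                 factor(bin, levels = seq_len(n_off)))
    vals <- matrix(as.numeric(tab), nrow = n_anchor, ncol = n_off,
                   dimnames = list(NULL, as.character(offsets)))
  }
  vals <- vals / ((step / 1000) * (readset$total_mapped / 1e6))
  structure(
    list(
      aggregate = tibble(offset = offsets, mean = colMeans(vals)),
      values = vals, offsets = offsets, anchors = as_tibble(anchors),
      sample_id = readset$sample_id, mark = readset$mark, genotype = readset$genotype
    ),
    class = "epi_profile"
  )
}

#' @export
print.epi_profile <- function(x, ...) {
  cat(sprintf("<epi_profile> %s (%s/%s): %d anchors x %d offsets\n",
              x$sample_id %||% "", x$mark %||% "", x$genotype %||% "",
              nrow(x$values), length(x$offsets)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
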