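#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols n across all_of if_else rename
#'   distinct pull slice count full_join first
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @importFrom stats median quantile sd rbinom rpois rlnorm runif cor hclust
#'   cutree as.dist pt setNames complete.cases
#' @importFrom utils head tail
NULL

# Coordinate convention used throughout: 0-based, half-open [start, end),
# the BED convention.  length == end - start always.

#' Validate an interval tibble
#'
#' Checks the half-open coordinate invariants shared by every region table in
#' the package: integer-like `start`/`end`, `start >= 0`, `end > start`.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes Optional tibble with columns `chrom`, `length`; when
#'   given, every interval must fit inside its chromosome.
#' @param what Label used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
check_intervals <- function(x, chrom_sizes = NULL, what = "interval table") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(sprintf("%s: start < 0", what))
    if (any(x$end <= x$start)) {
      bad <- which(x$end <= x$start)[1]
      abort(sprintf("%s: end <= start at row %d", what, bad))
    }
    if (!is.null(chrom_sizes)) {
      sz <- setNames(chrom_sizes$length, chrom_sizes$chrom)
      unknown <- setdiff(unique(x$chrom), names(sz))
      if (length(unknown) > 0) {
        abort(sprintf("%s: chromosome(s) not in size map: %s",
                      what, paste(unknown, collapse = ", ")))
      }
      if (any(x$end > sz[x$chrom])) abort(sprintf("%s: interval exceeds chromosome end", what))
    }
  }
  invisible(x)
}

# Internal: interval tibble -> GRanges (shift to 1-based closed).
as_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[is.na(s) | s == "."] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Internal: point positions -> width-1 GRanges.
points_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

# Internal: midpoint of a half-open interval.
interval_midpoint <- function(start, end) floor((start + end) / 2)

#' Read a BED3/BED6 file as an interval tibble
#'
#' Lines starting with `track`, `browser` or `#` are skipped.  Coordinates are
#' kept 0-based half-open as in the file.  Column 4 is returned as `name`,
#' column 5 as `score` and column 6 as `strand` when present.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                  line_no[which(nf < 3)[1]]))
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d: non-integer coordinates",
                  line_no[which(is.na(start) | is.na(end))[1]]))
  }
  if (any(end <= start)) {
    abort(sprintf("BED line %d: end <= start", line_no[which(end <= start)[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(parts, `[[`, "", 4L)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  if (all(nf >= 6)) out$strand <- vapply(parts, `[[`, "", 6L)
  out
}

#' Write an interval tibble as BED
#'
#' Writes BED3, or BED6 when `name`/`score`/`strand` columns are present
#' (missing ones are filled with `.`/`0`).  Round-trips coordinates exactly.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, what = "BED output")
  has_extra <- any(c("name", "score", "strand") %in% names(x))
  if (has_extra) {
    out <- tibble(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if ("name" %in% names(x)) x$name else ".",
      score = if ("score" %in% names(x)) x$score else 0,
      strand = if ("strand" %in% names(x)) x$strand else "."
    )
  } else {
    out <- x[, c("chrom", "start", "end")]
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param x Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @param track_name Optional track line name; omitted when `NULL`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, value = "value", track_name = NULL) {
  check_intervals(x, what = "bedGraph output")
  if (!value %in% names(x)) abort(sprintf("no column '%s' in bedGraph input", value))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  }
  writeLines(paste(x$chrom, x$start, x$end, format(x[[value]], trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a chromosome-size table
#'
#' Two tab-separated columns, `chrom` and `length`, with a header line.
#'
#' @param path Path to the table.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), length = readr::col_double()
  ), progress = FALSE)
  if (any(x$length <= 0)) abort("chromosome lengths must be positive")
  x
}

#' Read a gene table
#'
#' Tab-separated with header `gene_id  chrom  start  end  strand`; coordinates
#' 0-based half-open.  Unstranded genes are rejected because the transcription
#' start site is undefined without orientation.
#'
#' @param path Path to the table.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   and derived `tss`, `tes` positions.
#' @export
read_gene_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    strand = readr::col_character()
  ), progress = FALSE)
  check_intervals(x, what = "gene table")
  if (anyDuplicated(x$gene_id)) abort("duplicate gene_id in gene table")
  if (!all(x$strand %in% c("+", "-"))) {
    abort("gene table: strand must be '+' or '-' (unstranded genes have no TSS)")
  }
  add_tss_tes(x)
}

# Internal: derive tss/tes from strand (tss = start on +, end-1 on -).
add_tss_tes <- function(genes) {
  genes %>%
    mutate(
      tss = if_else(.data$strand == "+", .data$start, .data$end - 1L),
      tes = if_else(.data$strand == "+", .data$end - 1L, .data$start)
    )
}

#' Read a methylation coverage table
#'
#' Tab-separated with header
#' `chrom  position  context  methylated  unmethylated`.  Positions are
#' 0-based by default; pass `one_based = TRUE` for tables in the 1-based
#' dialect (they are shifted on load).  Records with zero total coverage are
#' dropped; the number dropped is recorded in the `"dropped"` attribute.
#'
#' @param path Path to the table.
#' @param one_based Whether positions in the file are 1-based.
#' @param sample_id,genotype Optional labels stored as attributes.
#' @return Tibble with columns `chrom`, `position`, `context`, `methylated`,
#'   `unmethylated`; attributes `sample_id`, `genotype`, `dropped`.
#' @export
read_methylation_coverage <- function(path, one_based = FALSE,
                                      sample_id = NULL, genotype = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), position = readr::col_integer(),
    context = readr::col_character(),
    methylated = readr::col_integer(), unmethylated = readr::col_integer()
  ), progress = FALSE)
  bad <- !x$context %in% c("CpG", "CHG", "CHH")
  if (any(bad)) {
    abort(sprintf("unknown context '%s' at record %d",
                  x$context[which(bad)[1]], which(bad)[1]))
  }
  if (any(x$methylated < 0 | x$unmethylated < 0)) abort("negative counts in coverage table")
  if (one_based) x$position <- x$position - 1L
  total <- x$methylated + x$unmethylated
  dropped <- sum(total == 0)
  x <- x[total > 0, ]
  attr(x, "dropped") <- dropped
  attr(x, "sample_id") <- sample_id
  attr(x, "genotype") <- genotype
  x
}

#' Read a gene-by-sample FPKM table
#'
#' Tab-separated; first column `gene_id`, remaining columns one per sample.
#'
#' @param path Path to the table.
#' @return Tibble with `gene_id` and one numeric column per sample.
#' @export
read_fpkm_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (any(vals < 0)) abort("FPKM values must be non-negative")
  x
}

#' Assign each query interval to at most one labeled subject
#'
#' Deterministic single-label assignment used, e.g., to place peaks or bins
#' onto annotation features.  Ties in `max_overlap` mode are broken by
#' earliest subject start, then lexicographically by label; the same rule
#' resolves multiple hits in the other modes.
#'
#' @param queries Interval tibble.
#' @param subjects Interval tibble with a `label` column.
#' @param mode `"any"` (any overlap), `"midpoint"` (subject containing the
#'   query midpoint, half-open) or `"max_overlap"` (largest overlap in bp).
#' @return `queries` with an added `label` column (`NA` when unassigned).
#' @export
overlap_assign <- function(queries, subjects, mode = c("any", "midpoint", "max_overlap")) {
  mode <- match.arg(mode)
  check_intervals(queries, what = "queries")
  check_intervals(subjects, what = "subjects")
  if (!"label" %in% names(subjects)) abort("subjects need a 'label' column")
  queries <- as_tibble(queries)
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    queries$label <- rep(NA_character_, nrow(queries))
    return(queries)
  }
  qgr <- if (mode == "midpoint") {
    points_gr(queries$chrom, interval_midpoint(queries$start, queries$end))
  } else {
    as_gr(queries[, c("chrom", "start", "end")])
  }
  sgr <- as_gr(subjects[, c("chrom", "start", "end")])
  # disjoint chromosome namespaces simply yield no overlap, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE))
  if (length(hits) == 0) {
    queries$label <- rep(NA_character_, nrow(queries))
    return(queries)
  }
  h <- tibble(
    q = S4Vectors::queryHits(hits),
    s = S4Vectors::subjectHits(hits)
  ) %>%
    mutate(
      label = subjects$label[.data$s],
      s_start = subjects$start[.data$s],
      ov = pmin(queries$end[.data$q], subjects$end[.data$s]) -
        pmax(queries$start[.data$q], subjects$start[.data$s])
    )
  if (mode == "max_overlap") {
    h <- h %>% arrange(.data$q, -.data$ov, .data$s_start, .data$label)
  } else {
    h <- h %>% arrange(.data$q, .data$s_start, .data$label)
  }
  h <- h %>% distinct(.data$q, .keep_all = TRUE)
  lab <- rep(NA_character_, nrow(queries))
  lab[h$q] <- h$label
  queries$label <- lab
  queries
}
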