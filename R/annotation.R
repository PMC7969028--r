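#' Assemble a genome annotation
#'
#' Bundles the chromosome-size map, stranded gene models and the region lists
#' (CpG islands, repeats, imprinting control regions, methylation domains)
#' used across the pipeline.  All coordinates are 0-based half-open.
#'
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (strand mandatory, `+`/`-`); `tss`/`tes` are derived if absent.
#' @param cgis,repeats Interval tibbles (may be empty).
#' @param icrs Interval tibble with `icr_id` and `parent`
#'   (`"maternal"`/`"paternal"`) columns.
#' @param domains Optional interval tibble with a `type`
#'   (`"hyper"`/`"hypo"`) column describing large-scale methylation domains;
#'   used by the synthetic generator.
#' @param lambda_chrom Name of the unmethylated spike-in chromosome, or `NULL`.
#' @return An object of class `epi_annotation`.
#' @export
epi_annotation <- function(chrom_sizes, genes,
                           cgis = NULL, repeats = NULL, icrs = NULL,
                           domains = NULL, lambda_chrom = NULL) {
  chrom_sizes <- as_tibble(chrom_sizes)
  if (!all(c("chrom", "length") %in% names(chrom_sizes))) {
    abort("chrom_sizes needs columns 'chrom' and 'length'")
  }
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicate chromosome in size map")
  genes <- as_tibble(genes)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("all genes must be stranded ('+' or '-')")
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id")
  if (!"tss" %in% names(genes)) genes <- add_tss_tes(genes)
  check_intervals(genes, chrom_sizes, what = "genes")
  empty_iv <- tibble(chrom = character(), start = integer(), end = integer())
  if (is.null(cgis)) cgis <- empty_iv
  if (is.null(repeats)) repeats <- empty_iv
  if (is.null(icrs)) {
    icrs <- tibble(icr_id = character(), chrom = character(),
                   start = integer(), end = integer(), parent = character())
  }
  check_intervals(cgis, chrom_sizes, what = "cgis")
  check_intervals(repeats, chrom_sizes, what = "repeats")
  check_intervals(icrs, chrom_sizes, what = "icrs")
  if (nrow(icrs) > 0) {
    if (anyDuplicated(icrs$icr_id)) abort("duplicate icr_id")
    if (!all(icrs$parent %in% c("maternal", "paternal"))) {
      abort("icr parent must be 'maternal' or 'paternal'")
    }
  }
  if (!is.null(domains)) check_intervals(domains, chrom_sizes, what = "domains")
  structure(
    list(chrom_sizes = chrom_sizes, genes = as_tibble(genes),
         cgis = as_tibble(cgis), repeats = as_tibble(repeats),
         icrs = as_tibble(icrs),
         domains = if (is.null(domains)) NULL else as_tibble(domains),
         lambda_chrom = lambda_chrom),
    class = "epi_annotation"
  )
}

#' @export
print.epi_annotation <- function(x, ...) {
  cat("<epi_annotation>\n")
  cat(sprintf("  chromosomes: %d (%.1f Mb total)\n",
              nrow(x$chrom_sizes), sum(x$chrom_sizes$length) / 1e6))
  cat(sprintf("  genes: %d   CGIs: %d   repeats: %d   ICRs: %d\n",
              nrow(x$genes), nrow(x$cgis), nrow(x$repeats), nrow(x$icrs)))
  if (!is.null(x$lambda_chrom)) cat(sprintf("  spike-in chromosome: %s\n", x$lambda_chrom))
  invisible(x)
}

# Internal: chromosomes that carry genomic (non spike-in) sequence.
main_chroms <- function(annotation) {
  setdiff(annotation$chrom_sizes$chrom, annotation$lambda_chrom)
}

#' Write an annotation to a directory of plain-text tables
#'
#' Emits `chrom_sizes.tsv`, `genes.tsv`, `cgis.bed`, `repeats.bed`,
#' `icrs.bed` (name column = ICR id), `icr_parent.tsv` and, when present,
#' `domains.tsv`.
#'
#' @param annotation An `epi_annotation`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written file paths, invisibly.
#' @export
write_annotation_dir <- function(annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(annotation$chrom_sizes, p("chrom_sizes.tsv"), progress = FALSE)
  readr::write_tsv(annotation$genes[, c("gene_id", "chrom", "start", "end", "strand")],
                   p("genes.tsv"), progress = FALSE)
  write_bed(annotation$cgis, p("cgis.bed"))
  write_bed(annotation$repeats, p("repeats.bed"))
  icr_bed <- annotation$icrs
  if (nrow(icr_bed) > 0) {
    icr_bed <- icr_bed %>% mutate(name = .data$icr_id)
  }
  write_bed(icr_bed[, intersect(c("chrom", "start", "end", "name"), names(icr_bed))],
            p("icrs.bed"))
  readr::write_tsv(annotation$icrs[, intersect(c("icr_id", "parent"), names(annotation$icrs))],
                   p("icr_parent.tsv"), progress = FALSE)
  if (!is.null(annotation$domains)) {
    readr::write_tsv(annotation$domains, p("domains.tsv"), progress = FALSE)
  }
  if (!is.null(annotation$lambda_chrom)) {
    writeLines(annotation$lambda_chrom, p("lambda_chrom.txt"))
  }
  files <- list.files(dir, full.names = TRUE)
  invisible(tibble(path = files))
}

#' Read an annotation directory written by [write_annotation_dir()]
#'
#' @param dir Directory containing the annotation tables.
#' @return An `epi_annotation`.
#' @export
read_annotation_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  chrom_sizes <- read_chrom_sizes(p("chrom_sizes.tsv"))
  genes <- read_gene_table(p("genes.tsv"))
  cgis <- read_bed(p("cgis.bed"))
  repeats <- read_bed(p("repeats.bed"))
  icr_bed <- read_bed(p("icrs.bed"))
  icr_parent <- readr::read_tsv(p("icr_parent.tsv"), col_types = "cc", progress = FALSE)
  icrs <- if (nrow(icr_bed) > 0) {
    icr_bed %>%
      rename(icr_id = "name") %>%
      left_join(icr_parent, by = "icr_id") %>%
      select("icr_id", "chrom", "start", "end", "parent")
  } else NULL
  domains <- if (file.exists(p("domains.tsv"))) {
    readr::read_tsv(p("domains.tsv"), col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), type = readr::col_character()
    ), progress = FALSE)
  } else NULL
  lambda_chrom <- if (file.exists(p("lambda_chrom.txt"))) readLines(p("lambda_chrom.txt"))[1] else NULL
  epi_annotation(chrom_sizes, genes, cgis = cgis, repeats = repeats,
                 icrs = icrs, domains = domains, lambda_chrom = lambda_chrom)
}

#' Construct a read set
#'
#' A read set is the aligned-read surrogate consumed by the quantification
#' stage: fixed-length intervals plus the library's total mapped-read count
#' used for per-million normalization.
#'
#' @param reads Interval tibble of reads.
#' @param sample_id Sample label.
#' @param mark One of `H3K4me3`, `H3K27me3`, `H2AK119ub1`, `H3K36me3`.
#' @param genotype `"WT"` or `"KO"`.
#' @param total_mapped Total mapped reads in the library; defaults to
#'   `nrow(reads)` and must be at least that.
#' @return An object of class `epi_reads`.
#' @export
epi_reads <- function(reads, sample_id, mark, genotype, total_mapped = nrow(reads)) {
  marks <- c("H3K4me3", "H3K27me3", "H2AK119ub1", "H3K36me3")
  if (!mark %in% marks) abort(sprintf("mark must be one of: %s", paste(marks, collapse = ", ")))
  if (!genotype %in% c("WT", "KO")) abort("genotype must be 'WT' or 'KO'")
  reads <- check_intervals(as_tibble(reads), what = "reads")
  if (total_mapped < nrow(reads)) abort("total_mapped < number of reads")
  reads <- reads %>% arrange(.data$chrom, .data$start)
  structure(
    list(reads = reads, sample_id = sample_id, mark = mark,
         genotype = genotype, total_mapped = as.double(total_mapped)),
    class = "epi_reads"
  )
}

#' @export
print.epi_reads <- function(x, ...) {
  cat(sprintf("<epi_reads> %s  %s/%s: %d reads (%.2f M mapped)\n",
              x$sample_id, x$mark, x$genotype, nrow(x$reads), x$total_mapped / 1e6))
  invisible(x)
}
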