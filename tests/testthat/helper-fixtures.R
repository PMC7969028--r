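# Shared fixtures: a small configuration for fast unit tests and a lazily
# built, cached copy of the default-scale simulation for the acceptance
# checks (built once per test run).

tiny_config <- function(...) {
  args <- list(
    seed = 1, n_chroms = 1, chrom_length = 1e6, n_genes = 40,
    reads_per_sample = 20000, lambda_sites = 200, n_icrs = 4,
    cytosine_spacing = 200, n_meth_reps = 1
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The default study-scale dataset: 2 chromosomes x 5 Mb, 500 genes,
# 8 ChIP samples at 200k reads, seed 1.
default_sim <- function() {
  cached("default_sim", function() simulate_dataset(sim_config(seed = 1)))
}

tiny_sim <- function() {
  cached("tiny_sim", function() simulate_dataset(tiny_config()))
}

# Promoter RPKM table (WT) for a simulation.
promoter_rpkm_table <- function(sim) {
  cfg <- sim$config
  prom <- promoters_from_genes(sim$annotation$genes, cfg$promoter_flank,
                               sim$annotation$chrom_sizes)
  q <- quantify_samples(
    sim$reads[c("H3K4me3_WT", "H3K27me3_WT", "H2AK119ub1_WT")], prom)
  tibble::tibble(gene_id = q$gene_id, K4 = q$H3K4me3_WT,
                 K27 = q$H3K27me3_WT, ub = q$H2AK119ub1_WT)
}

# Bin RPKM table for the two Polycomb marks in both genotypes.
bin_rpkm_table <- function(sim) {
  bins <- make_bins(sim$annotation, sim$config$bin_size)
  q <- quantify_samples(
    sim$reads[c("H3K27me3_WT", "H3K27me3_KO", "H2AK119ub1_WT", "H2AK119ub1_KO")],
    bins)
  tibble::tibble(bin_id = q$bin_id, chrom = q$chrom, start = q$start, end = q$end,
                 k27_wt = q$H3K27me3_WT, k27_ko = q$H3K27me3_KO,
                 ub_wt = q$H2AK119ub1_WT, ub_ko = q$H2AK119ub1_KO)
}

# Build an epi_reads object from bare midpoint positions.
reads_at <- function(chrom, mids, width = 150, total_mapped = NULL, ...) {
  start <- as.integer(mids - width %/% 2)
  r <- tibble::tibble(chrom = chrom, start = pmax(0L, start),
                      end = pmax(0L, start) + as.integer(width))
  epi_reads(r, sample_id = "test", mark = "H3K4me3", genotype = "WT",
            total_mapped = if (is.null(total_mapped)) nrow(r) else total_mapped)
}

# Does a "+"-joined state string contain a mark token?
state_has_token <- function(state, token) {
  vapply(strsplit(state, "+", fixed = TRUE), function(p) token %in% p, TRUE)
}

# Vectorized permutation p-value oracle for the pooled-variance t test.
perm_t_pvalue <- function(x, y, reps = 20000) {
  z <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  t_from_sums <- function(sx, sx2) {
    mx <- sx / nx
    my <- (sum(z) - sx) / ny
    ssx <- sx2 - sx^2 / nx
    ssy <- (sum(z^2) - sx2) - (sum(z) - sx)^2 / ny
    sp2 <- (ssx + ssy) / (n - 2)
    (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  t_obs <- t_from_sums(sum(x), sum(x^2))
  picks <- replicate(reps, sample.int(n, nx))
  zx <- matrix(z[picks], nrow = nx)
  t_perm <- t_from_sums(colSums(zx), colSums(zx^2))
  mean(abs(t_perm) >= abs(t_obs) - 1e-12)
}
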