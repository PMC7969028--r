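toy_annotation <- function(len = 25000) {
  epi_annotation(
    chrom_sizes = tibble::tibble(chrom = "chr1", length = len),
    genes = tibble::tibble(gene_id = "g1", chrom = "chr1",
                           start = 10000L, end = 20000L, strand = "+")
  )
}

test_that("make_bins tiles chromosomes with a truncated terminal bin", {
  ann <- toy_annotation(25000)
  b <- make_bins(ann, 10000)
  expect_equal(b$start, c(0L, 10000L, 20000L))
  expect_equal(b$end, c(10000L, 20000L, 25000L))
  expect_equal(b$bin_id[3], "chr1:20000-25000")
  expect_equal(nrow(b), ceiling(25000 / 10000))
  expect_error(make_bins(ann, 0), "bin_size")
})

test_that("promoters are +/- flank around the strand-aware TSS, clipped at bounds", {
  genes <- tibble::tibble(gene_id = c("p", "m", "edge"), chrom = "chr1",
                          start = c(10000L, 10000L, 500L),
                          end = c(20000L, 20000L, 4000L),
                          strand = c("+", "-", "+"))
  pr <- promoters_from_genes(genes, flank = 2000)
  expect_equal(pr$start[pr$gene_id == "p"], 8000L)
  expect_equal(pr$end[pr$gene_id == "p"], 12000L)
  # minus strand: tss = end - 1 = 19999
  expect_equal(pr$start[pr$gene_id == "m"], 17999L)
  expect_equal(pr$end[pr$gene_id == "m"], 21999L)
  # tss = 500 clips at 0
  expect_equal(pr$start[pr$gene_id == "edge"], 0L)
  expect_equal(pr$end[pr$gene_id == "edge"], 2500L)
})

test_that("rpkm matches the per-element formula and is scale invariant", {
  # 10 reads in a 10-kb bin at 1 M mapped reads -> RPKM 1
  feat <- tibble::tibble(bin_id = "b", chrom = "chr1", start = 0L, end = 10000L)
  rs <- reads_at("chr1", seq(1000, 9100, by = 900), total_mapped = 1e6)
  expect_equal(nrow(rs$reads), 10)
  expect_equal(rpkm(rs, feat)$rpkm, 1.0)

  # 0 reads -> 0
  far <- tibble::tibble(bin_id = "b2", chrom = "chr1", start = 50000L, end = 60000L)
  expect_equal(rpkm(rs, far)$rpkm, 0)

  # doubling counts and total_mapped leaves RPKM unchanged exactly
  rs2 <- reads_at("chr1", rep(seq(1000, 9100, by = 900), 2), total_mapped = 2e6)
  expect_identical(rpkm(rs2, feat)$rpkm, rpkm(rs, feat)$rpkm)

  expect_error(rpkm(epi_reads(rs$reads, "s", "H3K4me3", "WT", 0), feat) ,
               "total_mapped")
})

test_that("rpkm agrees with direct formula evaluation on random triples", {
  withr::local_seed(7)
  for (batch in 1:5) {
    k <- 50
    len <- sample(200:50000, k)
    count <- sample(0:300, k, replace = TRUE)
    depth <- sample(1e5:5e6, 1)
    feats <- tibble::tibble(feature_id = sprintf("f%02d", 1:k),
                            chrom = sprintf("f%02d", 1:k),
                            start = 0L, end = as.integer(len))
    mids <- unlist(lapply(1:k, function(i) {
      if (count[i] == 0) return(integer())
      sample.int(len[i], count[i], replace = TRUE) - 1L
    }))
    chroms <- rep(feats$chrom, count)
    rs <- epi_reads(tibble::tibble(chrom = chroms, start = pmax(0L, mids - 75L),
                                   end = pmax(0L, mids - 75L) + 150L),
                    "s", "H3K4me3", "WT", total_mapped = depth)
    got <- rpkm(rs, feats)
    want <- count / ((len / 1000) * (depth / 1e6))
    expect_equal(got$count, count)
    expect_true(all(abs(got$rpkm - want) <= 1e-12 * pmax(want, 1)))
  }
})

test_that("midpoint counting is conserved over a non-overlapping tiling", {
  withr::local_seed(3)
  ann <- toy_annotation(100000)
  bins <- make_bins(ann, 7000)
  mids <- sample.int(100000, 5000, replace = TRUE) - 1L
  rs <- reads_at("chr1", mids, total_mapped = 5000)
  counted <- sum(rpkm(rs, bins)$count)
  in_span <- sum(interval_midpoint <- floor((rs$reads$start + rs$reads$end) / 2) < 100000)
  expect_equal(counted, in_span)
})

test_that("peak filter excludes strictly below the threshold and reports counts", {
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                          rpkm = c(1.9, 2.0, 5, 0))
  f <- filter_low_quality_peaks(peaks, min_rpkm = 2)
  expect_equal(f$report$n_retained, 2)
  expect_equal(f$report$n_excluded, 2)
  expect_true(all(f$retained$rpkm >= 2))
  expect_true(2.0 %in% f$retained$rpkm)   # boundary value retained
  expect_true(1.9 %in% f$excluded$rpkm)

  all_good <- filter_low_quality_peaks(dplyr::mutate(peaks, rpkm = rpkm + 10))
  expect_equal(all_good$report$n_excluded, 0)
})

test_that("z-score standardization uses the population SD and zeroes flat rows", {
  x <- tibble::tibble(id = c("a", "b"), s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  z <- zscore_standardize(x, axis = "feature", value_cols = c("s1", "s2", "s3"))
  expect_equal(unlist(z[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(z$s1[1], 4), -1.2247)
  expect_equal(unlist(z[2, c("s1", "s2", "s3")], use.names = FALSE), c(0, 0, 0))
  # row means vanish
  expect_lt(max(abs(rowMeans(as.matrix(z[, c("s1", "s2", "s3")])))), 1e-12)
})

test_that("z-score standardization is idempotent on standardized rows", {
  withr::local_seed(5)
  x <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rnorm(20), d = rnorm(20))
  z1 <- zscore_standardize(x, axis = "feature", value_cols = names(x))
  z2 <- zscore_standardize(z1, axis = "feature", value_cols = names(x))
  expect_equal(as.matrix(z1), as.matrix(z2), tolerance = 1e-12)
})

test_that("peak genomic distribution follows TSS > TES > body > intergenic precedence", {
  ann <- toy_annotation(50000)  # gene [10000,20000)+, tss 10000, tes 19999
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(10500L, 19500L, 15000L, 40000L),
    end = c(11500L, 20500L, 16000L, 41000L)
  )
  d <- peak_genomic_distribution(peaks, ann)
  got <- setNames(d$n, as.character(d$category))
  # peak 1 midpoint 11000 is in both the TSS window and the body -> TSS
  # peak 2 midpoint 20000 is in the TES window only
  expect_equal(unname(got[c("TSS", "TES", "gene body", "intergenic")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)

  no_genes <- epi_annotation(tibble::tibble(chrom = "chr1", length = 50000),
                             toy_annotation()$genes[0, ])
  d2 <- peak_genomic_distribution(peaks, no_genes)
  expect_equal(d2$n[d2$category == "intergenic"], 4L)
})

test_that("fractions sum to one on random peak fixtures", {
  withr::local_seed(9)
  ann <- toy_annotation(100000)
  for (i in 1:3) {
    st <- sample.int(99000, 50)
    peaks <- tibble::tibble(chrom = "chr1", start = st, end = st + 500L)
    expect_equal(sum(peak_genomic_distribution(peaks, ann)$fraction), 1,
                 tolerance = 1e-12)
  }
})

test_that("average_profile puts a single read at the anchor into the zero-offset bin", {
  anchors <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 5000L, strand = "+")
  rs <- reads_at("chr1", 5000L, total_mapped = 1000)
  p <- average_profile(rs, anchors, window = 2000, step = 100)
  nz <- p$aggregate$offset[p$aggregate$mean > 0]
  expect_equal(nz, 0L)
  expect_equal(sum(p$aggregate$mean > 0), 1)
  expect_error(average_profile(rs, anchors[0, ], 2000, 100), "empty anchor")
  expect_error(average_profile(rs, anchors, 2000, 300), "step")
})

test_that("minus-strand anchors are orientation-flipped", {
  anchors <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 5000L, strand = "-")
  rs <- reads_at("chr1", 5500L, total_mapped = 1000)  # 500 bp 3' of a minus TSS
  p <- average_profile(rs, anchors, window = 2000, step = 100)
  expect_equal(p$aggregate$offset[p$aggregate$mean > 0], -500L)
})

test_that("uniform reads give a flat aggregate profile within Poisson error", {
  withr::local_seed(21)
  n <- 60000
  rs <- reads_at("chr1", sample.int(1e6, n, replace = TRUE) - 1L, total_mapped = n)
  anchors <- tibble::tibble(gene_id = sprintf("g%d", 1:50), chrom = "chr1",
                            pos = as.integer(seq(10000, 990000, length.out = 50)),
                            strand = rep(c("+", "-"), 25))
  p <- average_profile(rs, anchors, window = 2000, step = 200)
  # per-offset totals are Poisson with ~600 expected counts per offset bin,
  # so 3 SD is ~12% relative deviation
  tot <- colSums(p$values)
  lambda <- mean(tot)
  expect_lt(max(abs(tot - lambda)) / lambda, 3.5 / sqrt(600))
})
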