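test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(state_frequencies = c(none = 0.5, K4 = 0.4)),
               "8 promoter states")
  bad <- c(none = 0.5, K4 = 0.6, K27 = 0, ub = 0, `K4+K27` = 0, `K4+ub` = 0,
           `K27+ub` = 0, `K4+K27+ub` = 0)
  expect_error(sim_config(state_frequencies = bad), "sum to 1")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(sim_config(methylation_low = 0.9, methylation_high = 0.8),
               "methylation_low < methylation_high")
})

test_that("the toy genome is constructed within bounds with valid gene models", {
  cfg <- tiny_config()
  ann <- build_toy_genome(cfg)
  expect_equal(nrow(ann$genes), 40)
  expect_equal(ann$genes$gene_id[1], "g0001")
  expect_equal(ann$genes$gene_id[40], "g0040")
  expect_true(all(ann$genes$end <= 1e6))
  expect_true(all(diff(ann$genes$start[ann$genes$chrom == "chr1"]) > 0))
  # spike chromosome exists and carries no genes
  expect_true("chrL" %in% ann$chrom_sizes$chrom)
  expect_false(any(ann$genes$chrom == "chrL"))
  # alternating strands, domains tile the chromosome
  expect_equal(unique(ann$genes$strand[c(1, 3)]), "+")
  expect_equal(sum(ann$domains$end - ann$domains$start), 1e6)
  # ICRs sit inside hypermethylated domains
  hyper <- ann$domains[ann$domains$type == "hyper", ]
  hyper$label <- "hyper"
  expect_true(all(overlap_assign(ann$icrs[, c("chrom", "start", "end")],
                                 hyper, "any")$label == "hyper"))
  expect_error(build_toy_genome(tiny_config(n_genes = 2000)), "cannot fit")
  expect_error(build_toy_genome(tiny_config(chrom_length = 4e5)), "50")
})

test_that("plant_truth is deterministic and honors degenerate frequencies", {
  cfg <- tiny_config()
  ann <- build_toy_genome(cfg)
  t1 <- plant_truth(cfg, ann)
  t2 <- plant_truth(cfg, ann)
  expect_identical(t1$promoter_state, t2$promoter_state)
  expect_identical(t1$bin_class, t2$bin_class)

  all_k4 <- c(none = 0, K4 = 1, K27 = 0, ub = 0, `K4+K27` = 0, `K4+ub` = 0,
              `K27+ub` = 0, `K4+K27+ub` = 0)
  tk4 <- plant_truth(tiny_config(state_frequencies = all_k4), ann)
  expect_true(all(tk4$promoter_state$state == "K4"))

  none_changed <- c(unchanged = 1, I = 0, II = 0, III = 0, IV = 0, V = 0, VI = 0)
  tu <- plant_truth(tiny_config(bin_class_frequencies = none_changed), ann)
  expect_true(all(tu$bin_class$class == "unchanged"))
})

test_that("planted change classes respect the methylation-domain coupling", {
  sim <- tiny_sim()
  bc <- sim$truth$bin_class
  dom <- sim$truth$domains
  dom$label <- dom$type
  bc$domain <- overlap_assign(bc[, c("chrom", "start", "end")], dom, "midpoint")$label
  expect_true(all(bc$domain[bc$class %in% c("I", "II", "III")] == "hyper"))
  expect_true(all(bc$domain[bc$class %in% c("IV", "V", "VI")] == "hypo"))
})

test_that("chip read simulation is reproducible and respects enrichment", {
  cfg <- tiny_config()
  ann <- build_toy_genome(cfg)
  truth <- plant_truth(cfg, ann)
  r1 <- simulate_chip_reads(truth, ann, "H3K4me3", "WT", cfg, seed = 5)
  r2 <- simulate_chip_reads(truth, ann, "H3K4me3", "WT", cfg, seed = 5)
  expect_identical(r1$reads, r2$reads)
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(r1$reads, p1); write_bed(r2$reads, p2)
  expect_identical(readLines(p1), readLines(p2))

  # planted K4 promoters have RPKM > 1 even at modest fold
  cfg8 <- tiny_config(enrichment_fold = 8)
  t8 <- plant_truth(cfg8, ann)
  r8 <- simulate_chip_reads(t8, ann, "H3K4me3", "WT", cfg8, seed = 6)
  prom <- promoters_from_genes(ann$genes, cfg8$promoter_flank, ann$chrom_sizes)
  q <- rpkm(r8, prom)
  k4 <- state_has_token(t8$promoter_state$state, "K4")
  expect_gte(mean(q$rpkm[k4] > 1), 0.99)
})

test_that("near-unit enrichment gives a uniform read density", {
  cfg <- tiny_config(enrichment_fold = 1 + 1e-12, reads_per_sample = 50000)
  ann <- build_toy_genome(cfg)
  truth <- plant_truth(cfg, ann)
  r <- simulate_chip_reads(truth, ann, "H3K27me3", "KO", cfg, seed = 8)
  # planted region density within ~3 binomial SD of its genome share
  gain <- truth$bin_class[truth$bin_class$class %in% c("I", "II"), ]
  frac_bp <- sum(gain$end - gain$start) / 1e6
  mids <- floor((r$reads$start + r$reads$end) / 2)
  inside <- overlap_assign(
    tibble::tibble(chrom = r$reads$chrom, start = mids, end = mids + 1L),
    dplyr::mutate(gain, label = "in"), "any")$label
  n <- nrow(r$reads)
  observed <- sum(!is.na(inside))
  expect_lt(abs(observed - n * frac_bp), 3.5 * sqrt(n * frac_bp * (1 - frac_bp)))
})

test_that("wgbs simulation recovers planted domain means and conversion efficiency", {
  sim <- tiny_sim()
  cfg <- sim$config
  sites <- site_levels(sim$methylomes$WT_rep1)
  dom <- sim$truth$domains
  # mean level in hyper domains, excluding ICR overrides
  hyper <- dom[dom$type == "hyper", ]
  cpg <- sites[sites$context == "CpG" & sites$chrom != "chrL", ]
  in_hyper <- !is.na(overlap_assign(
    tibble::tibble(chrom = cpg$chrom, start = cpg$position, end = cpg$position + 1L),
    dplyr::mutate(hyper, label = "h"), "any")$label)
  in_icr <- !is.na(overlap_assign(
    tibble::tibble(chrom = cpg$chrom, start = cpg$position, end = cpg$position + 1L),
    dplyr::mutate(sim$annotation$icrs, label = "i"), "any")$label)
  lev <- cpg$level[in_hyper & !in_icr]
  se <- sqrt(0.8 * 0.2 / 30) / sqrt(length(lev))
  expect_lt(abs(mean(lev) - cfg$methylation_high), 4 * se)

  # conversion efficiency within binomial error of truth
  est <- conversion_efficiency(sim$methylomes$WT_rep1, "chrL")
  expect_lt(abs(est - cfg$conversion_efficiency_true), 0.002)

  # at shallow depth, zero-coverage sites appear raw and are dropped by
  # site_levels
  shallow_cfg <- tiny_config(coverage_mean = 1)
  shallow <- simulate_wgbs(plant_truth(shallow_cfg, build_toy_genome(shallow_cfg)),
                           build_toy_genome(shallow_cfg), "WT", shallow_cfg,
                           seed = 12)
  expect_true(any(shallow$methylated + shallow$unmethylated == 0))
  expect_true(all(site_levels(shallow)$coverage >= 1))
})

test_that("expression simulation hits planted means and plants recoverable DE", {
  cfg0 <- tiny_config(dispersion = 0)
  ann <- build_toy_genome(cfg0)
  truth <- plant_truth(cfg0, ann)
  e0 <- simulate_expression(truth, cfg0, seed = 4)
  expect_identical(e0$WT, truth$expression$wt_mean)
  expect_identical(e0$KO, truth$expression$ko_mean)

  e1 <- simulate_expression(truth, tiny_config(), seed = 4)
  e2 <- simulate_expression(truth, tiny_config(), seed = 4)
  expect_identical(e1, e2)

  # planted 2-fold (or more) KO reductions are called down at threshold 1.5
  sim <- default_sim()
  de <- call_de_genes(sim$expression)
  planted_down <- sim$truth$expression$gene_id[
    sim$truth$expression$wt_mean / sim$truth$expression$ko_mean >= 2 &
      sim$truth$expression$wt_mean >= 1]
  called <- de$gene_id[de$status == "down"]
  expect_gte(mean(planted_down %in% called), 0.95)
})

test_that("full dataset simulation is deterministic under the seed", {
  s1 <- simulate_dataset(tiny_config())
  s2 <- simulate_dataset(tiny_config())
  expect_identical(s1$reads$H3K4me3_WT$reads, s2$reads$H3K4me3_WT$reads)
  expect_identical(s1$methylomes$WT_rep1$methylated, s2$methylomes$WT_rep1$methylated)
  expect_identical(s1$expression, s2$expression)
  expect_equal(length(s1$reads), 8)
})

test_that("fixture bundles round-trip with stable checksums", {
  sim <- tiny_sim()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(sim, file.path(d1, "fx"))
  m2 <- write_fixture_bundle(sim, file.path(d2, "fx"))
  expect_identical(m1$md5, m2$md5)
  expect_equal(sum(grepl("^reads/", m1$path)), 8)
  expect_error(write_fixture_bundle(sim, file.path(d1, "nope", "deeper", "fx")),
               "parent")
  # round-trip the annotation
  ann2 <- read_annotation_dir(file.path(d1, "fx", "annotation"))
  expect_equal(ann2$genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(ann2$icrs$parent, sim$annotation$icrs$parent)
  expect_equal(ann2$lambda_chrom, "chrL")
})
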