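test_that("promoter states use a strict threshold and the four-group rule", {
  x <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    K4 = c(2.0, 1.5, 0.5, 1.0, 0.2),
    K27 = c(0.5, 1.5, 2.0, 1.0, 0.1),
    ub = c(0.5, 1.5, 0.5, 1.0, 3.0)
  )
  st <- classify_promoter_states(x, threshold = 1)
  expect_equal(st$state, c("K4", "K4+K27+ub", "K27", "none", "ub"))
  expect_equal(st$group, c("A", "B", "C", "D", "D"))
  # boundary: exactly 1 is not present (strict >)
  expect_equal(st$state[st$gene_id == "d"], "none")
  expect_error(classify_promoter_states(dplyr::mutate(x, K4 = NA_real_)),
               "differ across marks")
})

test_that("promoter states partition the gene set", {
  sim <- tiny_sim()
  st <- classify_promoter_states(promoter_rpkm_table(sim))
  expect_equal(nrow(st), nrow(sim$annotation$genes))
  expect_true(all(st$state %in% c("none", "K4", "K27", "ub", "K4+K27",
                                  "K4+ub", "K27+ub", "K4+K27+ub")))
  by_state <- expression_by_state(st, sim$expression, "WT")
  expect_equal(sum(by_state$n), nrow(st))
})

test_that("expression_by_state summarises with 1.5 IQR whiskers and ranks medians", {
  st <- tibble::tibble(gene_id = c("a", "b", "c"),
                       K4 = TRUE, K27 = FALSE, ub = FALSE,
                       state = c("K4", "K4", "K27"), group = c("A", "A", "C"))
  ex <- tibble::tibble(gene_id = c("a", "b", "c"), WT = c(10, 30, 2))
  s <- expression_by_state(st, ex, "WT")
  expect_equal(s$median[s$state == "K27"], 2)     # single-gene state
  expect_equal(s$n[s$state == "none"], 0)         # empty bucket reported
  expect_equal(s$rank[s$state == "K4"], 1)
  expect_true(all(s$whisker_high <= max(ex$WT), na.rm = TRUE))
})

test_that("DE calls follow the pseudocounted fold rule with an expression floor", {
  ex <- tibble::tibble(gene_id = c("down", "flat", "floor", "up"),
                       WT = c(3.0, 2.0, 0.2, 1.0),
                       KO = c(1.9, 2.0, 0.01, 2.0))
  de <- call_de_genes(ex)
  # (3.0 + 0.1) / (1.9 + 0.1) = 1.55 > 1.5
  expect_equal(de$ratio[1], 3.1 / 2.0)
  expect_equal(de$status, c("down", "unchanged", "unchanged", "up"))
})

test_that("set_overlap partitions two gene sets", {
  expect_equal(unlist(set_overlap(c("a", "b", "c"), c("b", "c", "d"))),
               c(a_only = 1L, both = 2L, b_only = 1L))
  expect_equal(unlist(set_overlap(c("a", "b"), c("c"))),
               c(a_only = 2L, both = 0L, b_only = 1L))
  expect_equal(unlist(set_overlap(c("a"), c("a", "b", "c"))),
               c(a_only = 0L, both = 1L, b_only = 2L))
})

test_that("bin change classes map per-mark calls to the six-class taxonomy", {
  x <- tibble::tibble(
    bin_id = sprintf("b%d", 1:8),
    k27_wt = c(0.5, 0.5, 3, 4.0, 4, 3, 3, 0.5),
    k27_ko = c(4.0, 4.0, 3, 0.5, 0.5, 3, 3, 4.0),
    ub_wt  = c(3.0, 0.5, 0.5, 3, 4, 4, 3, 4.0),
    ub_ko  = c(3.0, 4.0, 4.0, 3, 0.5, 0.5, 3, 0.5)
  )
  cls <- classify_bin_changes(x)
  expect_equal(cls$class, c("I", "II", "III", "IV", "V", "VI", "unchanged", "mixed"))
})

test_that("genotype swap maps I<->IV, II<->V, III<->VI and fixes mixed/unchanged", {
  withr::local_seed(13)
  x <- tibble::tibble(
    bin_id = sprintf("b%04d", 1:1000),
    k27_wt = rexp(1000, 1 / 3), k27_ko = rexp(1000, 1 / 3),
    ub_wt = rexp(1000, 1 / 3), ub_ko = rexp(1000, 1 / 3)
  )
  fwd <- classify_bin_changes(x)
  swapped <- classify_bin_changes(dplyr::rename(
    x, k27_wt = "k27_ko", k27_ko = "k27_wt", ub_wt = "ub_ko", ub_ko = "ub_wt"))
  map <- c(I = "IV", II = "V", III = "VI", IV = "I", V = "II", VI = "III",
           mixed = "mixed", unchanged = "unchanged")
  expect_identical(unname(map[fwd$class]), swapped$class)
})

test_that("classify_bin_changes agrees with a brute-force per-bin reimplementation", {
  withr::local_seed(31)
  x <- tibble::tibble(
    bin_id = sprintf("b%04d", 1:1000),
    k27_wt = round(rexp(1000, 1 / 2), 2), k27_ko = round(rexp(1000, 1 / 2), 2),
    ub_wt = round(rexp(1000, 1 / 2), 2), ub_ko = round(rexp(1000, 1 / 2), 2)
  )
  got <- classify_bin_changes(x)$class
  call1 <- function(wt, ko) {
    if ((ko + 0.5) / (wt + 0.5) >= 2 && ko >= 2) return("up")
    if ((wt + 0.5) / (ko + 0.5) >= 2 && wt >= 2) return("down")
    "none"
  }
  want <- vapply(seq_len(1000), function(i) {
    k <- call1(x$k27_wt[i], x$k27_ko[i])
    u <- call1(x$ub_wt[i], x$ub_ko[i])
    key <- paste(k, u)
    switch(key,
           "up none" = "I", "up up" = "II", "none up" = "III",
           "down none" = "IV", "down down" = "V", "none down" = "VI",
           "none none" = "unchanged", "mixed")
  }, "")
  expect_identical(got, want)
})

test_that("single-mark change classes are symmetric under genotype relabeling", {
  x <- tibble::tibble(bin_id = c("a", "b", "c"),
                      wt = c(4.0, 0.5, 2), ko = c(0.5, 4.0, 2))
  m <- bin_mark_change_classes(x)
  expect_equal(m$change, c("down", "up", "unchanged"))
  sw <- bin_mark_change_classes(dplyr::rename(x, wt = "ko", ko = "wt"))
  expect_equal(sw$change, c("up", "down", "unchanged"))
})

test_that("Student's t reproduces the closed-form pooled-variance statistic", {
  tt <- students_t_test(c(1, 2, 3), c(4, 5, 6), "unpaired")
  # pooled variance = 1, se = sqrt(2/3), t = -3 / 0.8165 = -3.674
  expect_equal(abs(tt$statistic), 3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$statistic), 4), tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-3)

  td <- tidy(tt)
  expect_equal(td$p.value, tt$p_value)
  expect_equal(td$estimate, -3)
})

test_that("degenerate t-test inputs are handled explicitly", {
  same <- students_t_test(c(1, 2, 3), c(1, 2, 3), "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- students_t_test(c(1, 2, 3), c(2, 3, 4), "paired")  # constant diff
  expect_true(is.infinite(shifted$statistic))
  expect_gt(shifted$p_value, 0)
  const <- students_t_test(c(2, 2, 2), c(2, 2), "unpaired")
  expect_equal(const$p_value, 1)
  expect_error(students_t_test(1, c(1, 2)), "n >= 2")
  expect_error(students_t_test(c(1, 2), c(1, 2, 3), "paired"), "equal group sizes")
})

test_that("bin_class_covariates summarises per class and picks the right test flavor", {
  sim <- tiny_sim()
  bc <- sim$truth$bin_class   # planted classes: a clean oracle for the mechanics
  sites_wt <- site_levels(sim$methylomes$WT_rep1)
  sites_ko <- site_levels(sim$methylomes$KO_rep1)
  bins <- make_bins(sim$annotation, sim$config$bin_size)
  covs <- list(methylation = tibble::tibble(
    bin_id = bins$bin_id,
    wt = bin_cpg_means(sites_wt, bins)$mean_level,
    ko = bin_cpg_means(sites_ko, bins)$mean_level))
  cc <- bin_class_covariates(
    bc[, c("bin_id", "chrom", "start", "end", "class")],
    covariates = covs,
    expression = dplyr::select(sim$expression, "gene_id", wt = "WT", ko = "KO"),
    genes = sim$annotation$genes)
  expect_true(all(c("class", "covariate", "genotype", "median") %in%
                    names(cc$summaries)))
  expect_equal(unique(cc$tests$flavor[cc$tests$covariate == "expression"]), "paired")
  expect_equal(unique(cc$tests$flavor[cc$tests$covariate == "methylation"]),
               "unpaired")
  # KO methylation collapses in Polycomb-gain bins
  gain <- cc$tests[cc$tests$covariate == "methylation" &
                     cc$tests$class %in% c("I", "II", "III"), ]
  expect_true(all(gain$p_value < 0.01, na.rm = TRUE))
  # empty classes yield no rows rather than an error
  empty <- bin_class_covariates(
    tibble::tibble(bin_id = character(), chrom = character(),
                   start = integer(), end = integer(), class = character()),
    covariates = covs["methylation"])
  expect_equal(nrow(empty$tests), 0)
})

test_that("TSS methylation metaprofile is flat on uniform input and flips strand", {
  genes <- tibble::tibble(gene_id = c("p", "m"), chrom = "c",
                          start = c(10000L, 30000L), end = c(20000L, 40000L),
                          strand = c("+", "-"), tss = c(10000L, 39999L),
                          tes = c(19999L, 30000L))
  st <- tibble::tibble(gene_id = c("p", "m"), K4 = TRUE, K27 = FALSE, ub = FALSE,
                       state = "K4", group = "A")
  pos <- seq(5000L, 45000L, by = 50L)
  sites <- site_levels(tibble::tibble(chrom = "c", position = pos, context = "CpG",
                                      methylated = 3L, unmethylated = 7L))
  prof <- methylation_profile_by_tss_state(sites, st, genes, window = 2000, step = 500)
  expect_true(all(abs(prof$mean_level - 0.3) < 1e-12))
  expect_equal(sort(unique(prof$state)), "K4")
  expect_equal(nrow(prof), 8)  # states with no genes are omitted entirely
})
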