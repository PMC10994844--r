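test_that("CPM follows the formula and matches the filter threshold", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(cpm(m, lib_sizes = c(s1 = 1e6))["g1", "s1"], 10)
  expect_equal(cpm(m, lib_sizes = c(s1 = 1e6))["g2", "s1"], 0)
  # ten reads in a ~15-million-read library sit exactly at the
  # expressed-gene threshold
  expect_equal(round(cpm(m, lib_sizes = c(s1 = 15072000))["g1", "s1"], 4),
               0.6635)
  # CPM columns sum to 1e6 under column-sum library sizes
  cm <- stats::setNames(rep(c("a", "b"), each = 2), sprintf("s%d", 1:4))
  sim <- simulate_counts(200, cm, libsizes = 1e5, seed = 81)
  em <- expr_matrix(sim$expr$counts, cm)  # column-sum libraries
  expect_equal(unname(colSums(cpm(em))), rep(1e6, 4))
  expect_error(cpm(m, lib_sizes = c(s1 = 0)), "library sizes")
})

test_that("expressed-gene filtering honours the per-condition scheme", {
  cm <- stats::setNames(rep(c("a", "b"), each = 2), sprintf("s%d", 1:4))
  counts <- rbind(
    gA = c(10L, 10L, 0L, 0L),    # above threshold in both reps of a
    gB = c(5L, 5L, 5L, 5L),      # CPM 0.5 everywhere at 1e7 libraries
    gC = c(10L, 0L, 0L, 10L))    # never in all reps of one condition
  colnames(counts) <- names(cm)
  em <- expr_matrix(counts, cm, lib_sizes = stats::setNames(rep(1e7, 4),
                                                            names(cm)))
  kept <- filter_expressed(em, cpm_threshold = 0.6635)
  expect_identical(kept, "gA")
  # at threshold 0 every gene that is nonzero across one condition's
  # replicates is retained; gC has a zero replicate in both conditions
  expect_identical(filter_expressed(em, cpm_threshold = 0),
                   c("gA", "gB"))
  expect_length(filter_expressed(em, cpm_threshold = 0.6635,
                                 scheme = "all_samples"), 0)
})

test_that("NB test is calibrated under the null and powerful at lfc 4", {
  cm <- stats::setNames(rep(c("a", "b"), each = 3), sprintf("s%d", 1:6))
  sim <- simulate_counts(4000, cm, libsizes = 1e6, dispersion = 0.05,
                         seed = 82)
  de <- nb_de_test(sim$expr, c("b", "a"))
  t1 <- mean(de$pvalue < 0.05)
  expect_gte(t1, 0.02)
  expect_lte(t1, 0.08)
  # BH monotonicity
  o <- order(de$pvalue)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  # identical counts in all samples give log2fc 0
  em2 <- sim$expr
  em2$counts["G0001", ] <- 50L
  de2 <- nb_de_test(em2, c("b", "a"))
  expect_equal(de2$log2fc[de2$gene == "G0001"], 0)
  # power at planted |log2FC| = 4
  pl <- stats::setNames(rep(4, 100), sprintf("G%04d", 1:100))
  simp <- simulate_counts(2000, cm, libsizes = 1e6, dispersion = 0.05,
                          planted_de = pl, de_condition = "b", seed = 83)
  dep <- nb_de_test(simp$expr, c("b", "a"))
  expect_gte(mean(dep$fdr[1:100] < 0.05), 0.9)
  # replicate and degenerate-input contracts
  cm1 <- stats::setNames(c("a", "a", "b"), sprintf("s%d", 1:3))
  s1 <- simulate_counts(50, cm1, seed = 1)
  expect_error(nb_de_test(s1$expr, c("b", "a")), "replicates")
})

test_that("significance calls use both fold-change and FDR thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(2.5, 2.5, -3, 1),
                   pvalue = c(1e-4, 0.1, 1e-5, 0.5),
                   fdr = c(0.01, 0.2, 0.001, 0.9))
  class(de) <- c("de_result", "data.frame")
  calls <- significant_de(de)$call
  expect_identical(calls, c("up", "neither", "down", "neither"))
})

test_that("ranking metric is signed -log10(p) with deterministic ties", {
  de <- data.frame(gene = c("b", "a", "c", "d"),
                   log2fc = c(1, -1, 0.5, 0.5),
                   pvalue = c(0.01, 0.01, 1, 0.01),
                   fdr = 0.5)
  class(de) <- c("de_result", "data.frame")
  rk <- rank_metric(de)
  expect_equal(rk$score[rk$gene == "b"], 2)
  expect_equal(rk$score[rk$gene == "a"], -2)
  expect_equal(rk$score[rk$gene == "c"], 0)
  # tie between b and d broken by id
  expect_identical(rk$gene[1:2], c("b", "d"))
  # zero p-values are floored and flagged
  de$pvalue[1] <- 0
  rk2 <- rank_metric(de)
  expect_true(rk2$floored[rk2$gene == "b"])
  expect_true(is.finite(rk2$score[rk2$gene == "b"]))
})

test_that("enrichment scores behave at the extremes and flip with sign", {
  rk <- data.frame(gene = sprintf("g%04d", 1:1000),
                   score = seq(5, -5, length.out = 1000))
  top <- list(top = rk$gene[1:20])
  r <- preranked_gsea(rk, top, n_perm = 500, seed = 3)
  expect_gt(r$es, 0.9)
  expect_lte(r$pvalue, 1 / 500)
  expect_true(abs(r$es) <= 1)
  rk2 <- rk; rk2$score <- -rk2$score
  r2 <- preranked_gsea(rk2, top, n_perm = 200, seed = 3)
  expect_equal(r2$es, -r$es)
  # size rules: a 5-member set is dropped unless exempted
  s5 <- list(small = rk$gene[3:7])
  expect_equal(nrow(preranked_gsea(rk, s5, n_perm = 200, seed = 1)), 0)
  expect_equal(nrow(preranked_gsea(rk, s5, n_perm = 200,
                                   exempt_sets = "small", seed = 1)), 1)
  expect_error(preranked_gsea(rk, top, n_perm = 50, seed = 1), "n_perm")
  # agreement with an independent implementation of the weighted
  # running-sum statistic
  set.seed(9)
  myset <- sample(rk$gene[30:500], 25)
  mine <- preranked_gsea(rk, list(s = myset), n_perm = 200, seed = 2)$es
  ref <- suppressWarnings(fgsea::fgsea(
    pathways = list(s = myset),
    stats = stats::setNames(rk$score, rk$gene),
    minSize = 1, maxSize = 500, nPermSimple = 500))$ES
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("permutation p-values are uniform for random gene sets", {
  rk <- data.frame(gene = sprintf("g%04d", 1:1000),
                   score = seq(5, -5, length.out = 1000))
  set.seed(84)
  rsets <- stats::setNames(lapply(1:60, function(i) sample(rk$gene, 20)),
                           sprintf("rs%02d", 1:60))
  rn <- preranked_gsea(rk, rsets, n_perm = 1000, seed = 85)
  ks <- suppressWarnings(stats::ks.test(rn$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(rn$pvalue > 0 & rn$pvalue <= 1))
})
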