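test_that("z-scored profiles are standardized and affine-invariant", {
  cm <- stats::setNames(rep(sprintf("c%d", 1:4), each = 2),
                        sprintf("s%d", 1:8))
  sim <- simulate_counts(100, cm, libsizes = 1e6, seed = 91)
  z <- zscore_profiles(sim$expr, collapse = "sample")
  expect_equal(unname(rowMeans(z)), rep(0, 100), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 100),
               tolerance = 1e-12)
  # per-sample affine rescaling of CPM leaves z unchanged
  em2 <- sim$expr
  em2$lib_sizes <- sim$expr$lib_sizes * 3
  z2 <- zscore_profiles(em2, collapse = "sample")
  expect_equal(z, z2, ignore_attr = TRUE)
  # constant gene flagged
  em3 <- sim$expr
  em3$counts["G0001", ] <- 7L
  em3$lib_sizes <- stats::setNames(rep(1e6, 8), names(cm))
  z3 <- zscore_profiles(em3, collapse = "sample")
  expect_true("G0001" %in% attr(z3, "zero_variance"))
})

test_that("gene-set correlation reports medians with the size rule", {
  cm <- stats::setNames(rep(sprintf("c%d", 1:10), each = 2),
                        sprintf("s%02d", 1:20))
  sim <- simulate_counts(300, cm, libsizes = 1e6, dispersion = 0.05,
                         planted_regulons = list(
                           list(n_genes = 30, target_cor = 0.9,
                                amplitude = 2)),
                         seed = 92)
  z <- zscore_profiles(sim$expr)
  mem <- sim$truth$regulons$regulon01
  query <- mem[1]
  sets <- list(regulon = mem,
               nine = rownames(z)[!(rownames(z) %in% mem)][1:9],
               copies = mem)
  out <- gene_set_correlation(query, sets["regulon"], z)
  expect_gte(out$median_r, 0.8)
  expect_true(out$labelled)
  expect_equal(out$n_members_used, 29)  # query excluded from its own set
  # sets below the size floor are excluded
  out9 <- gene_set_correlation(query, sets["nine"], z)
  expect_equal(nrow(out9), 0)
  expect_error(gene_set_correlation("absent", sets, z), "absent")
  # a set that is exact copies of the query correlates perfectly
  zz <- z[c(mem, "G0201"), ]
  for (g in mem[2:12]) zz[g, ] <- zz[query, ]
  out1 <- gene_set_correlation(query, list(s = mem[2:12]), zz,
                               min_set_size = 10)
  expect_equal(out1$median_r, 1)
})

test_that("fitness categories follow the |t| and |fit| thresholds", {
  ft <- fitness_table(data.frame(
    srna = c("a", "b", "c", "d", "e"),
    experiment = "e1",
    fit = c(-1.0, 2.5, 2.5, 0.5, 2.5),
    t = c(4.5, 5.5, 5.5, 1.0, 4.5),
    success = c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  out <- categorize_fitness(ft)$calls
  expect_equal(out[out$srna == "a", c("significant", "strong", "combined")],
               data.frame(significant = TRUE, strong = FALSE,
                          combined = FALSE), ignore_attr = TRUE)
  expect_equal(unlist(out[out$srna == "b", 3:5]),
               c(significant = TRUE, strong = TRUE, combined = TRUE))
  # unsuccessful experiments yield no category at all
  expect_false(any(unlist(out[out$srna == "c", 3:5])))
  expect_false(any(unlist(out[out$srna == "d", 3:5])))
  # |t| in (4, 5] with |fit| > 2: significant but not strong
  expect_equal(unlist(out[out$srna == "e", 3:5]),
               c(significant = TRUE, strong = FALSE, combined = FALSE))
})

test_that("sRNA prioritization orders by evidence then effect then id", {
  summary <- data.frame(
    srna = c("x", "y", "z"),
    n_significant = c(2L, 10L, 2L),
    n_strong = 0L, n_combined = 0L,
    any_significant = TRUE, any_strong = FALSE, any_combined = FALSE,
    max_abs_fit = c(1.0, 0.5, 3.0), stringsAsFactors = FALSE)
  cm <- stats::setNames(rep(c("a", "b"), each = 2), sprintf("s%d", 1:4))
  counts <- matrix(50L, 2, 4, dimnames = list(c("x", "y"), names(cm)))
  counts["x", 3:4] <- 500L
  em <- expr_matrix(counts, cm)
  pr <- prioritize_srnas(summary, em)
  expect_identical(pr$srna, c("y", "z", "x"))
  expect_identical(pr$peak_condition[pr$srna == "x"], "b")
  expect_true(pr$missing_expression[pr$srna == "z"])
})

test_that("one-site binding fit recovers Kd exactly and under noise", {
  x <- 2^(3:10)
  y <- 1 * x / (100 + x)
  f <- fit_binding_curve(x, y)
  expect_equal(f$bmax, 1, tolerance = 1e-4)
  expect_equal(f$kd, 100, tolerance = 1e-4)
  expect_lt(f$rss, 1e-12)
  # 5% noise, 3 replicates: Kd within 15%
  set.seed(93)
  xn <- rep(x, 3)
  yn <- (1 * xn / (100 + xn)) * (1 + stats::rnorm(length(xn), 0, 0.05))
  fn <- fit_binding_curve(xn, yn)
  expect_lt(abs(fn$kd - 100) / 100, 0.15)
  # degenerate inputs
  expect_error(fit_binding_curve(x, rep(0, length(x))), "no binding")
  expect_error(fit_binding_curve(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               "distinct")
})
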