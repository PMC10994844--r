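test_that("genome generation places non-overlapping genes and is deterministic", {
  gg <- generate_genome(1, c(chr = 50000), n_genes = 20,
                        mean_gene_len = 900)
  g <- gg$genome$genes
  expect_equal(nrow(g), 20)
  expect_true(all(g$start >= 1 & g$end <= 50000 & g$start <= g$end))
  # non-overlap regardless of strand (sequential placement)
  o <- g[order(g$start), ]
  expect_true(all(diff(o$start) > 0))
  expect_true(all(utils::head(o$end, -1) < utils::tail(o$start, -1)))

  # byte-identical FASTA and GFF3 under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  for (d in c(d1, d2)) {
    gx <- generate_genome(7, c(chr = 30000), n_genes = 10)
    write_fasta(gx$genome$replicons, file.path(d, "g.fa"))
    write_gff3(gx$genome$genes[, c("replicon", "start", "end", "strand",
                                   "biotype", "id")],
               file.path(d, "g.gff3"))
  }
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))

  # empty case and failure case
  empty <- generate_genome(3, c(chr = 20000), n_genes = 0)
  expect_equal(nrow(empty$genome$genes), 0)
  expect_error(generate_genome(3, c(chr = 9100), n_genes = 40,
                               mean_gene_len = 900),
               "cannot place|must be")
})

test_that("planted inverted repeats have the requested geometry", {
  gg <- generate_genome(2, c(chr = 30000), n_genes = 8)
  specs <- list(list(arm_len = 12, mismatches = 0, spacer_len = 100),
                list(arm_len = 20, mismatches = 2, spacer_len = 200),
                list(arm_len = 15, mismatches = 0, spacer_len = 80,
                     homopolymeric = TRUE))
  pi <- plant_inverted_repeats(gg$genome, specs, 5, gg$truth)
  irs <- pi$truth$irs
  expect_equal(nrow(irs), 3)
  s <- pi$genome$replicons[["chr"]]
  for (i in 1:3) {
    left <- substr(s, irs$left_start[i], irs$left_end[i])
    right <- substr(s, irs$right_start[i], irs$right_end[i])
    mm <- sum(strsplit(right, "")[[1]] != strsplit(revcomp(left), "")[[1]])
    expect_equal(mm, irs$mismatches[i])
    expect_equal(irs$right_start[i] - irs$left_end[i] - 1,
                 irs$spacer_length[i])
  }
  # homopolymeric decoy: both arms one repeated letter
  left3 <- substr(s, irs$left_start[3], irs$left_end[3])
  right3 <- substr(s, irs$right_start[3], irs$right_end[3])
  expect_equal(length(unique(strsplit(left3, "")[[1]])), 1)
  expect_equal(length(unique(strsplit(right3, "")[[1]])), 1)
  # validation
  expect_error(plant_inverted_repeats(
    gg$genome, list(list(arm_len = 0, spacer_len = 10)), 1), "arm_len")
  expect_error(plant_inverted_repeats(
    gg$genome, list(list(arm_len = 10, spacer_len = -1)), 1), "spacer")
})

test_that("simulated dRNA-seq coverage carries the planted TSS enrichment", {
  gg <- generate_genome(4, c(chr = 120000), n_genes = 40)
  truth <- plant_transcripts(gg$genome, gg$truth, 6, n_orphan = 30)
  expect_gte(nrow(truth$tss), 50)
  cov <- simulate_drnaseq_coverage(gg$genome, truth,
                                   enrichment_factor = 10,
                                   tss_height = 100, noise_rate = 0.1,
                                   seed = 8)
  tp <- tm <- numeric(0)
  for (i in seq_len(nrow(truth$tss))) {
    t <- truth$tss[i, ]
    tp <- c(tp, cov_track(cov, t$replicon, "tex_plus", t$strand,
                          "starts")[t$pos])
    tm <- c(tm, cov_track(cov, t$replicon, "tex_minus", t$strand,
                          "starts")[t$pos])
  }
  ratio <- mean(tp) / mean(tm)
  expect_gte(ratio, 5)
  expect_lte(ratio, 20)

  # terminator drop: downstream window mean <= 0.2 x upstream window mean
  drops <- vapply(seq_len(nrow(truth$terminators)), function(i) {
    t <- truth$terminators[i, ]
    v <- cov_track(cov, t$replicon, "tex_minus", t$strand, "cov")
    if (t$strand == "+") {
      mean(v[(t$pos + 1):(t$pos + 50)]) / mean(v[(t$pos - 50):(t$pos - 1)])
    } else {
      mean(v[(t$pos - 50):(t$pos - 1)]) / mean(v[(t$pos + 1):(t$pos + 50)])
    }
  }, numeric(1))
  expect_true(mean(drops) <= 0.2)

  # no signal at all
  cov0 <- simulate_drnaseq_coverage(gg$genome, truth,
                                    enrichment_factor = 10,
                                    tss_height = 0, noise_rate = 0,
                                    seed = 8)
  expect_true(all(cov_track(cov0, "chr", "tex_plus", "+", "starts") == 0))
  expect_true(all(cov_track(cov0, "chr", "tex_minus", "-", "cov") == 0))
})

test_that("simulated counts reproduce planted fold changes and regulons", {
  cm <- stats::setNames(rep(c("ctrl", "trt", "c3", "c4"), each = 2),
                        sprintf("s%02d", 1:8))
  planted <- stats::setNames(rep(4, 100), sprintf("G%04d", 1:100))
  sim <- simulate_counts(2000, cm, libsizes = 1e6, dispersion = 0.05,
                         planted_de = planted, de_condition = "trt",
                         seed = 21)
  v <- cpm(sim$expr)
  trt <- names(cm)[cm == "trt"]
  ctrl <- names(cm)[cm == "ctrl"]
  emp <- log2((rowMeans(v[1:100, trt]) + 0.5) /
                (rowMeans(v[1:100, ctrl]) + 0.5))
  expect_gte(mean(emp), 3.7)
  expect_lte(mean(emp), 4.3)

  cm8 <- stats::setNames(rep(sprintf("c%d", 1:8), each = 2),
                         sprintf("s%02d", 1:16))
  simr <- simulate_counts(2000, cm8, libsizes = 3e6, dispersion = 0.05,
                          planted_regulons = list(
                            list(n_genes = 50, target_cor = 0.9,
                                 amplitude = 2)),
                          seed = 22)
  z <- zscore_profiles(simr$expr)
  mem <- simr$truth$regulons$regulon01
  cc <- stats::cor(t(z[mem, ]))
  expect_gte(stats::median(cc[upper.tri(cc)]), 0.8)

  # Poisson limit: variance ~ mean at dispersion 0
  simp <- simulate_counts(10000, cm, libsizes = 1e6, dispersion = 0,
                          seed = 23)
  m <- rowMeans(simp$expr$counts)
  vv <- apply(simp$expr$counts, 1, stats::var)
  expect_lt(abs(mean(vv / m) - 1), 0.1)

  # single-replicate condition: warning in provenance, not an error
  cm1 <- stats::setNames(c("a", "a", "b"), c("s1", "s2", "s3"))
  s1 <- simulate_counts(100, cm1, seed = 1)
  expect_match(s1$expr$provenance$warnings, "single replicate")
})

test_that("simulated fitness tables keep background inside the null band", {
  hits <- data.frame(srna = sprintf("sRNA%03d", c(1, 5, 9, 20, 33)),
                     experiment = sprintf("exp%03d", 1:5),
                     fit = -2.5, t = 6, stringsAsFactors = FALSE)
  sf <- simulate_fitness_table(80, 100, hits, seed = 3)
  tab <- as.data.frame(sf$table)
  key <- paste(tab$srna, tab$experiment)
  planted <- key %in% paste(hits$srna, hits$experiment)
  expect_true(all(abs(tab$t[!planted]) < 3))
  expect_true(all(tab$t[planted] == 6))
  cs <- categorize_fitness(sf$table)
  expect_equal(sum(cs$summary$any_significant), 5)

  # no hits -> no significant sRNAs
  s0 <- simulate_fitness_table(30, 40, NULL, seed = 4)
  expect_equal(sum(categorize_fitness(s0$table)$summary$any_significant),
               0)

  # a planted hit in an unsuccessful experiment is not counted
  hits2 <- hits[1, ]; hits2$success <- FALSE
  s2 <- simulate_fitness_table(80, 100, hits2, seed = 3)
  cs2 <- categorize_fitness(s2$table)
  expect_equal(sum(cs2$summary$any_significant), 0)

  # null-band validation
  expect_error(simulate_fitness_table(
    10, 10, data.frame(srna = "sRNA001", experiment = "exp001",
                       fit = 1, t = 2), seed = 1),
    "null band")
})
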