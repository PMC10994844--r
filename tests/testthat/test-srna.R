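test_that("transcript calling merges close runs and drops short ones", {
  v <- integer(1000)
  v[101:220] <- 50L                      # one clean block
  v[400:450] <- 30L; v[456:520] <- 30L   # 5-nt gap, merged at merge_gap 10
  v[800:819] <- 40L                      # 20 nt, below min_len 30
  cs <- make_cov(1000, tex_minus.fwd.cov = v)
  tr <- call_transcripts(cs, min_cov = 5, min_len = 30, merge_gap = 10)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$start, c(101, 400))
  expect_equal(tr$end, c(220, 520))
  # without merging the two blocks stay apart
  tr2 <- call_transcripts(cs, min_cov = 5, min_len = 30, merge_gap = 2)
  expect_equal(nrow(tr2), 3)
})

test_that("folding proxy matches the exhaustive oracle and its contracts", {
  # no pairing
  expect_equal(folding_energy(strrep("A", 50)),
               list(energy = 0, normalized = 0))
  # a strong GC hairpin is stable on the proxy scale
  hp <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
  fe <- folding_energy(hp)
  expect_lt(fe$normalized, -0.05)
  expect_equal(fe$normalized, fe$energy / nchar(hp))
  expect_error(folding_energy("ACGX"), "non-nucleotide")
  # never positive, deterministic
  set.seed(5)
  for (i in 1:10) {
    s <- rand_dna(sample(8:16, 1))
    e1 <- folding_energy(s)$energy
    expect_lte(e1, 0)
    expect_identical(e1, folding_energy(s)$energy)
    expect_equal(e1, fold_oracle(s))
  }
  # Watson-Crick-only alphabet gives reverse-complement symmetry
  set.seed(6)
  for (i in 1:5) {
    s <- paste0(sample(c("G", "C"), 14, replace = TRUE), collapse = "")
    expect_equal(folding_energy(s)$energy,
                 folding_energy(revcomp(s))$energy)
  }
})

test_that("sRNA classification follows the class precedence rules", {
  genes <- data.frame(id = "G1", replicon = "chr", start = 2000L,
                      end = 3000L, strand = "+", biotype = "CDS")
  tssr <- data.frame(replicon = "chr",
                     pos = c(500L, 2600L, 1900L),
                     strand = c("+", "-", "+"),
                     tex_plus_height = 100, tex_minus_height = 10,
                     enrichment = 10, id = c("T1", "T2", "T3"),
                     stringsAsFactors = FALSE)
  tssr$classes <- list(
    data.frame(class = "orphan", gene = NA_character_),
    data.frame(class = "antisense", gene = "G1"),
    data.frame(class = "primary", gene = "G1"))
  nops <- list()
  noterm <- data.frame(replicon = character(), start = integer(),
                       end = integer(), strand = character(),
                       method = character(), score = numeric(),
                       u_tail_length = integer())
  nops_ps <- data.frame(replicon = character(), pos = integer(),
                        strand = character())
  cands <- data.frame(
    replicon = "chr",
    start = c(500L, 2400L, 1900L),
    end = c(650L, 2600L, 1980L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  res <- classify_srnas(cands, tssr, nops_ps, genes, nops, noterm)
  expect_equal(res$class, c("intergenic", "antisense", "utr5_derived"))
  # a candidate with no support anywhere is rejected as unclassifiable
  far <- data.frame(replicon = "chr", start = 8000L, end = 8100L,
                    strand = "+")
  r2 <- classify_srnas(far, tssr, nops_ps, genes, nops, noterm)
  expect_true(is.na(r2$class))
  expect_identical(r2$rejection_reasons[[1]], "unclassifiable")
  # the partition property: one class or rejected, never both
  all_res <- rbind(res, r2)
  expect_true(all(xor(is.na(all_res$class),
                      vapply(all_res$rejection_reasons, length,
                             integer(1)) == 0)))
})

test_that("curation applies the exclusion rules with stated reasons", {
  gg <- generate_genome(51, c(chr = 30000), n_genes = 6)
  genome <- gg$genome
  genes <- genome$genes
  v <- rep(5L, 30000)
  v[10000:10150] <- 200L
  cs <- make_cov(30000, tex_minus.fwd.cov = v,
                 tex_minus.rev.cov = rep(5L, 30000))
  tssr <- data.frame(replicon = "chr", pos = 10000L, strand = "+",
                     tex_plus_height = 100, tex_minus_height = 10,
                     enrichment = 10, id = "T1", stringsAsFactors = FALSE)
  tssr$classes <- list(data.frame(class = "orphan", gene = NA_character_))
  ps <- data.frame(replicon = character(), pos = integer(),
                   strand = character())
  noterm <- data.frame(replicon = character(), start = integer(),
                       end = integer(), strand = character(),
                       method = character(), score = numeric(),
                       u_tail_length = integer())
  rec <- data.frame(id = "s1", replicon = "chr", start = 10000L,
                    end = 10150L, strand = "+", length = 151L,
                    class = "intergenic", tss_support = "T1",
                    stringsAsFactors = FALSE)
  rec$rejection_reasons <- list(character(0))
  # make the candidate sequence fold stably: insert a GC hairpin
  s <- genome$replicons[["chr"]]
  substr(s, 10040, 10089) <- paste0(strrep("G", 23), "AAAA",
                                    strrep("C", 23))
  genome$replicons[["chr"]] <- s

  cur <- curate_srnas(rec, tssr, ps, genes, noterm, cs, genome)
  expect_equal(nrow(cur$accepted), 1)
  expect_lt(cur$accepted$normalized_folding_energy, -0.05)

  # rule 1: no promoter/processing site within 50 bp upstream
  no_tss <- tssr[0, ]
  cur1 <- curate_srnas(rec, no_tss, ps, genes, noterm, cs, genome)
  expect_true("no_promoter_or_processing_site" %in%
                cur1$rejected$rejection_reasons[[1]])

  # rule 2: complete overlap with an annotated mRNA
  g2 <- rbind(genes, data.frame(id = "host", replicon = "chr",
                                start = 9900L, end = 10300L,
                                strand = "+", biotype = "CDS"))
  cur2 <- curate_srnas(rec, tssr, ps, g2, noterm, cs, genome)
  expect_true("inside_mrna" %in% cur2$rejected$rejection_reasons[[1]])

  # rule 3: complete overlap with an annotated terminator
  term3 <- data.frame(replicon = "chr", start = 9950L, end = 10200L,
                      strand = "+", method = "hairpin", score = 10,
                      u_tail_length = 5L)
  cur3 <- curate_srnas(rec, tssr, ps, genes, term3, cs, genome)
  expect_true("inside_terminator" %in%
                cur3$rejected$rejection_reasons[[1]])

  # rule 4 applies only when cis elements are supplied
  cis <- data.frame(replicon = "chr", start = 10100L, end = 10120L,
                    strand = "+")
  cur4 <- curate_srnas(rec, tssr, ps, genes, noterm, cs, genome,
                       cis_elements = cis)
  expect_true("cis_regulatory_overlap" %in%
                cur4$rejected$rejection_reasons[[1]])

  # rule 5: no evident coverage change relative to the flanks
  flat <- make_cov(30000, tex_minus.fwd.cov = rep(100L, 30000))
  cur5 <- curate_srnas(rec, tssr, ps, genes, noterm, flat, genome)
  expect_true("no_coverage_change" %in%
                cur5$rejected$rejection_reasons[[1]])

  # length filter: a 25-nt candidate fails regardless of the rest
  short <- rec
  short$end <- 10024L
  short$length <- 25L
  cur6 <- curate_srnas(short, tssr, ps, genes, noterm, cs, genome)
  expect_true("length_out_of_range" %in%
                cur6$rejected$rejection_reasons[[1]])
})

test_that("asRNA pairing labels planted anti-correlated pairs", {
  cm <- stats::setNames(rep(sprintf("c%d", 1:6), each = 2),
                        sprintf("s%02d", 1:12))
  sim <- simulate_counts(60, cm, libsizes = 1e6, dispersion = 0.01,
                         seed = 61)
  counts <- sim$expr$counts
  # construct an asRNA profile anti-correlated with genes G0001/G0002
  prof <- c(4000L, 3000L, 2000L, 1200L, 600L, 300L)
  for (g in c("G0001", "G0002"))
    counts[g, ] <- rep(prof, each = 2) + sample(0:20, 12, TRUE)
  counts <- rbind(counts,
                  asrna1 = rep(rev(prof), each = 2),
                  asrna2 = rep(500L, 12))
  # equal library sizes so the constant asRNA really has zero variance
  em <- expr_matrix(counts, cm,
                    lib_sizes = stats::setNames(rep(1e6, 12), names(cm)))
  ops <- list(list(id = "op1", replicon = "chr", strand = "+",
                   genes = c("G0001", "G0002"), span = c(1000, 3000),
                   lead_tss = NA, terminator = NA, sub_operons = list()))
  rec <- data.frame(id = c("asrna1", "asrna2"), replicon = "chr",
                    start = c(1500L, 1600L), end = c(1700L, 1800L),
                    strand = "-", length = 201L, class = "antisense",
                    tss_support = "T", stringsAsFactors = FALSE)
  out <- pair_asrna_with_targets(rec, ops, em)
  expect_equal(out$label[out$asrna == "asrna1"], "anti_correlated")
  expect_lt(out$r[out$asrna == "asrna1"], -0.5)
  # constant profile: neutral with a zero-variance note
  expect_equal(out$label[out$asrna == "asrna2"], "neutral")
  expect_equal(out$note[out$asrna == "asrna2"], "zero_variance")
})
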