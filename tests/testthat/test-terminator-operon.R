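test_that("hairpin finder scores a constructed terminator correctly", {
  # 8-bp GC stem, 4-nt loop, exactly 6 U then G; flanks cannot pair
  s <- paste0(strrep("C", 20), "GGGGCCCC", "AAAA", "GGGGCCCC",
              "TTTTTT", "G", strrep("C", 20))
  h <- find_hairpin_terminators(s, "+")
  expect_equal(nrow(h), 1)
  expect_equal(h$score, 14)         # (8 pairs - 0 mismatches) + 6 U
  expect_equal(h$u_tail_length, 6)
  # same stem without a U tail is rejected at min_u_tail = 4
  s2 <- paste0(strrep("C", 20), "GGGGCCCC", "AAAA", "GGGGCCCC",
               strrep("C", 20))
  expect_equal(nrow(find_hairpin_terminators(s2, "+")), 0)
  # poly-A has no complementarity
  expect_equal(nrow(find_hairpin_terminators(strrep("A", 500), "+")), 0)
})

test_that("hairpin finder agrees with a brute-force window enumerator", {
  brute <- function(seq, stem_range = 5:12, loop_range = 3:8,
                    max_mm = 1, min_u = 4) {
    ch <- strsplit(toupper(seq), "")[[1]]
    pair <- function(a, b) paste0(a, b) %in%
      c("AT", "TA", "GC", "CG", "GT", "TG")
    L <- length(ch)
    found <- list()
    for (i in seq_len(L)) {
      for (s in stem_range) for (l in loop_range) {
        j <- i + 2 * s + l - 1
        if (j > L) next
        mm <- sum(!vapply(seq_len(s), function(k)
          pair(ch[i + k - 1], ch[j - k + 1]), logical(1)))
        if (mm > max_mm) next
        u <- 0
        for (dd in 1:8) {
          p <- j + dd
          if (p > L || ch[p] != "T") next
          run <- 0
          while (p + run <= L && ch[p + run] == "T") run <- run + 1
          u <- max(u, run)
        }
        if (u < min_u) next
        found[[length(found) + 1]] <- c(i, j, (s - mm) - mm + u)
      }
    }
    found
  }
  set.seed(17)
  for (rep in 1:3) {
    s <- rand_dna(1500)
    mine <- find_hairpin_terminators(s, "+")
    ref <- brute(s)
    if (length(ref) == 0) {
      expect_equal(nrow(mine), 0)
      next
    }
    # every reported hit must be a brute-force hit with the same score,
    # and the best brute-force score in each overlap group must appear
    refm <- do.call(rbind, ref)
    for (i in seq_len(nrow(mine))) {
      match_row <- refm[, 1] == mine$start[i] & refm[, 2] == mine$end[i]
      expect_true(any(match_row & refm[, 3] == mine$score[i]))
    }
    expect_equal(max(mine$score), max(refm[, 3]))
  }
})

test_that("coverage-drop terminators report the drop ratio as score", {
  v <- integer(2000)
  v[500:1000] <- 100L
  v[1001:1400] <- 10L
  cs <- make_cov(2000, tex_minus.fwd.cov = v)
  g <- data.frame(id = c("g1", "g2"), replicon = "chr",
                  start = c(300L, 1450L), end = c(999L, 1800L),
                  strand = "+", biotype = "CDS")
  res <- find_coverage_drop_terminators(cs, g, window = 50,
                                        min_drop = 0.5,
                                        min_upstream_cov = 10)
  hit <- res[res$start > 999 & res$start < 1450, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$score, 0.9)
  expect_equal(hit$start, 1001)
  # flat coverage yields nothing between the genes
  flat <- make_cov(2000, tex_minus.fwd.cov = rep(50L, 2000))
  rflat <- find_coverage_drop_terminators(flat, g)
  expect_equal(nrow(rflat[rflat$start > 999 & rflat$start < 1450, ]), 0)
  # insufficient upstream support
  v2 <- integer(2000); v2[500:1000] <- 3L
  weak <- make_cov(2000, tex_minus.fwd.cov = v2)
  expect_equal(nrow(find_coverage_drop_terminators(weak, g,
                                                   min_upstream_cov = 10)),
               0)
})

test_that("operon assembly joins by gap, coverage and terminator rules", {
  v <- rep(0L, 6000)
  v[900:4500] <- 100L
  cs <- make_cov(6000, tex_minus.fwd.cov = v)
  g <- data.frame(id = c("a", "b", "c"), replicon = "chr",
                  start = c(1000L, 2100L, 3200L),
                  end = c(2050L, 3140L, 4100L),
                  strand = "+", biotype = "CDS")
  tss <- data.frame(replicon = "chr", pos = 950L, strand = "+",
                    tex_plus_height = 100, tex_minus_height = 10,
                    enrichment = 10, id = "T1",
                    stringsAsFactors = FALSE)
  tss$classes <- list(data.frame(class = "primary", gene = "a"))
  noterm <- data.frame(replicon = character(), start = integer(),
                       end = integer(), strand = character(),
                       method = character(), score = numeric(),
                       u_tail_length = integer())
  ops <- assemble_operons(g, tss, noterm, cs, max_gap = 300,
                          min_joining_cov = 5)
  expect_length(ops, 1)
  expect_equal(ops[[1]]$genes, c("a", "b", "c"))
  expect_equal(ops[[1]]$lead_tss, "T1")

  # a terminator between genes 2 and 3 splits the operon
  term <- data.frame(replicon = "chr", start = 3160L, end = 3160L,
                     strand = "+", method = "coverage_drop", score = 0.9,
                     u_tail_length = NA_integer_)
  ops2 <- assemble_operons(g, tss, term, cs)
  expect_length(ops2, 2)
  expect_equal(ops2[[1]]$genes, c("a", "b"))
  expect_equal(ops2[[2]]$genes, "c")

  # an internal primary/secondary TSS at a non-first member opens a
  # sub-operon running to the operon end
  tss2 <- rbind(tss, tss)
  tss2$pos[2] <- 2080L
  tss2$id[2] <- "T2"
  tss2$classes <- list(data.frame(class = "primary", gene = "a"),
                       data.frame(class = "secondary", gene = "b"))
  ops3 <- assemble_operons(g, tss2, noterm, cs)
  expect_length(ops3, 1)
  expect_length(ops3[[1]]$sub_operons, 1)
  expect_equal(ops3[[1]]$sub_operons[[1]]$genes, c("b", "c"))
  # sub-operon members are a subset of operon members
  expect_true(all(ops3[[1]]$sub_operons[[1]]$genes %in% ops3[[1]]$genes))

  # a coverage gap below min_joining_cov also splits
  v3 <- v; v3[3150:3180] <- 0L
  cs3 <- make_cov(6000, tex_minus.fwd.cov = v3)
  ops4 <- assemble_operons(g, tss, noterm, cs3)
  expect_length(ops4, 2)
})

test_that("operons never span replicons and sub-operons stay bounded", {
  gg <- generate_genome(41, c(chr = 40000, p1 = 12000), n_genes = 16)
  truth <- plant_transcripts(gg$genome, gg$truth, 42,
                             n_srna = c(intergenic = 1, antisense = 1,
                                        utr5 = 0, utr3 = 0,
                                        intra_operonic = 0))
  cov <- simulate_drnaseq_coverage(gg$genome, truth, seed = 43)
  cls <- classify_tss(detect_tss(cov), gg$genome$genes)
  drops <- find_coverage_drop_terminators(cov, gg$genome$genes)
  ops <- assemble_operons(gg$genome$genes, cls, drops, cov)
  for (o in ops) {
    reps <- unique(gg$genome$genes$replicon[
      gg$genome$genes$id %in% o$genes])
    expect_length(reps, 1)
    expect_lte(length(o$sub_operons), length(o$genes) - 1)
  }
})
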