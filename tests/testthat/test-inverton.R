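test_that("planted repeats obey the length-dependent mismatch budgets", {
  gg <- generate_genome(71, c(chr = 30000), n_genes = 8)
  pi <- plant_inverted_repeats(gg$genome, list(
    list(arm_len = 12, mismatches = 0, spacer_len = 100),
    list(arm_len = 20, mismatches = 2, spacer_len = 200),
    list(arm_len = 10, mismatches = 1, spacer_len = 150)),
    72, gg$truth)
  hits <- find_inverted_repeats(pi$genome$replicons[["chr"]],
                                arm_min = 8, arm_max = 25,
                                spacer_min = 30, spacer_max = 400)
  irs <- pi$truth$irs
  found <- function(i) any(hits$left_start == irs$left_start[i] &
                             hits$left_end == irs$left_end[i] &
                             hits$right_start == irs$right_start[i] &
                             hits$mismatches == irs$mismatches[i])
  expect_true(found(1))   # perfect 12-bp arms
  expect_true(found(2))   # 20-bp arms, 2 mismatches, budget 2
  # 10-bp arms with 1 mismatch are outside the budget (0 at <= 11 bp)
  expect_false(any(hits$left_start == irs$left_start[3] &
                     hits$arm_length == 10))
})

test_that("composition filters remove homopolymers and extreme GC", {
  gg <- generate_genome(73, c(chr = 25000), n_genes = 6)
  pi <- plant_inverted_repeats(gg$genome, list(
    list(arm_len = 15, mismatches = 0, spacer_len = 80,
         homopolymeric = TRUE),
    list(arm_len = 14, mismatches = 0, spacer_len = 120)),
    74, gg$truth)
  hits <- find_inverted_repeats(pi$genome$replicons[["chr"]])
  tr1 <- pi$truth$irs[1, ]
  homo_hit <- hits[hits$left_start == tr1$left_start &
                     hits$left_end == tr1$left_end &
                     hits$right_start == tr1$right_start, ]
  expect_true(homo_hit$homopolymeric)
  filt <- filter_inverted_repeats(hits)
  expect_false(any(filt$left_start == tr1$left_start &
                     filt$left_end == tr1$left_end &
                     filt$right_start == tr1$right_start))
  # GC bounds: an all-GC arm pair (gc 1.0) is removed, mixed arms are kept
  fake <- data.frame(replicon = "chr", left_start = 1, left_end = 14,
                     right_start = 100, right_end = 113, arm_length = 14,
                     mismatches = 0, spacer_length = 85,
                     gc_fraction = c(0.9, 0.5), homopolymeric = FALSE,
                     promoter_flag = NA, tss_ids = NA)
  kept <- filter_inverted_repeats(fake)
  expect_equal(kept$gc_fraction, 0.5)
})

test_that("scanner equals the brute-force enumeration on random sequence", {
  set.seed(75)
  for (i in 1:5) {
    s <- rand_dna(2500)
    a <- find_inverted_repeats(s, arm_min = 6, arm_max = 20,
                               spacer_min = 10, spacer_max = 300)
    b <- ir_brute_force(s, arm_min = 6, arm_max = 20,
                        spacer_min = 10, spacer_max = 300)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("reverse-complementing the replicon mirrors the hit set", {
  set.seed(76)
  s <- rand_dna(3000)
  a <- find_inverted_repeats(s, arm_min = 6, arm_max = 20,
                             spacer_min = 10, spacer_max = 200)
  b <- find_inverted_repeats(revcomp(s), arm_min = 6, arm_max = 20,
                             spacer_min = 10, spacer_max = 200)
  L <- nchar(s)
  # a left/right arm pair maps to the mirrored right/left pair
  key_a <- sort(sprintf("%d:%d:%d:%d", a$left_start, a$left_end,
                        a$right_start, a$right_end))
  key_b <- sort(sprintf("%d:%d:%d:%d", L - b$right_end + 1,
                        L - b$right_start + 1, L - b$left_end + 1,
                        L - b$left_start + 1))
  expect_identical(key_a, key_b)
})

test_that("false-positive control at stringent arm length", {
  set.seed(77)
  n_hits <- vapply(1:10, function(i) {
    nrow(find_inverted_repeats(rand_dna(5000), arm_min = 15))
  }, numeric(1))
  expect_lt(mean(n_hits), 0.1)
})

test_that("promoter windows upstream of TSSs flag invertons strand-aware", {
  hits <- data.frame(replicon = "chr", left_start = 940L, left_end = 951L,
                     right_start = 1040L, right_end = 1051L,
                     arm_length = 12L, mismatches = 0L,
                     spacer_length = 88L, gc_fraction = 0.5,
                     homopolymeric = FALSE, promoter_flag = NA,
                     tss_ids = NA, stringsAsFactors = FALSE)
  tss_plus <- data.frame(replicon = "chr", pos = 1060L, strand = "+",
                         tex_plus_height = 50, tex_minus_height = 5,
                         enrichment = 10, id = "T+",
                         stringsAsFactors = FALSE)
  tss_plus$classes <- list(list())
  # window [1010, 1059] intersects the IR span [940, 1051]
  expect_true(flag_promoter_invertons(hits, tss_plus)$promoter_flag)
  # a TSS 500 bp away does not flag
  tss_far <- tss_plus; tss_far$pos <- 1600L
  expect_false(flag_promoter_invertons(hits, tss_far)$promoter_flag)
  # "-" strand window sits downstream in coordinates: TSS at 940 covers
  # [941, 990], inside the IR span
  tss_minus <- tss_plus; tss_minus$pos <- 940L; tss_minus$strand <- "-"
  flagged <- flag_promoter_invertons(hits, tss_minus)
  expect_true(flagged$promoter_flag)
  expect_equal(flagged$tss_ids, "T+")
  # the same TSS on "+" has window [890, 939], outside the span
  tss_plus2 <- tss_plus; tss_plus2$pos <- 940L
  expect_false(flag_promoter_invertons(hits, tss_plus2)$promoter_flag)
  # strand-agnostic mode flags it again
  expect_true(flag_promoter_invertons(hits, tss_plus2,
                                      strand_aware = FALSE)$promoter_flag)
})
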