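# Shared fixtures and independent oracles used across test files.

# build a coverage_set from explicit vectors (defaults: zeros)
make_cov <- function(len, replicon = "chr", ...) {
  cs <- coverage_set(stats::setNames(len, replicon))
  tracks <- list(...)
  for (nm in names(tracks)) {
    # name format: library.strand.type e.g. tex_plus.fwd.starts
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    strand <- if (parts[2] == "fwd") "+" else "-"
    cov_track(cs, replicon, parts[1], strand, parts[3]) <- tracks[[nm]]
  }
  cs
}

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hand-written TSS classification truth table: single gene spanning
# [2000, 3000], one candidate at a time. Offsets are taken along the
# gene's transcription direction relative to its 5' start coordinate.
tss_grid_oracle <- function() {
  plus <- rbind(
    # gene on +: start 2000 (window [1700, 1999]), flanks [1900, 3100]
    data.frame(gene_strand = "+", cand_strand = "+",
               pos = c(1699, 1700, 1999, 2000, 2001, 2500, 3000, 3100,
                       3101),
               expected = c("orphan", "primary", "primary", "internal",
                            "internal", "internal", "internal", "orphan",
                            "orphan")),
    data.frame(gene_strand = "+", cand_strand = "-",
               pos = c(1699, 1700, 1999, 2000, 2001, 2500, 3000, 3100,
                       3101),
               expected = c("orphan", "orphan", "antisense", "antisense",
                            "antisense", "antisense", "antisense",
                            "antisense", "orphan")))
  minus <- rbind(
    # gene on -: 5' start is coordinate 3000 (window [3001, 3300])
    data.frame(gene_strand = "-", cand_strand = "-",
               pos = c(3301, 3300, 3001, 3000, 2999, 2500, 2000, 1900,
                       1899),
               expected = c("orphan", "primary", "primary", "internal",
                            "internal", "internal", "internal", "orphan",
                            "orphan")),
    data.frame(gene_strand = "-", cand_strand = "+",
               pos = c(3301, 3300, 3001, 3000, 2999, 2500, 2000, 1900,
                       1899),
               expected = c("orphan", "orphan", "antisense", "antisense",
                            "antisense", "antisense", "antisense",
                            "antisense", "orphan")))
  rbind(plus, minus)
}

run_tss_grid <- function() {
  grid <- tss_grid_oracle()
  grid$got <- NA_character_
  for (i in seq_len(nrow(grid))) {
    gene <- data.frame(id = "G", replicon = "chr", start = 2000L,
                       end = 3000L, strand = grid$gene_strand[i],
                       biotype = "CDS", stringsAsFactors = FALSE)
    cand <- data.frame(replicon = "chr", pos = grid$pos[i],
                       strand = grid$cand_strand[i],
                       tex_plus_height = 50, tex_minus_height = 5,
                       enrichment = 10, id = "t1",
                       stringsAsFactors = FALSE)
    cand$classes <- list(list())
    cls <- classify_tss(cand, gene)
    grid$got[i] <- paste(sort(unique(cls$classes[[1]]$class)),
                         collapse = ",")
  }
  grid
}

# exhaustive folding oracle: recursive enumeration over all nested
# structures, independent of the iterative dynamic program
fold_oracle <- function(s) {
  ch <- strsplit(toupper(chartr("T", "U", s)), "")[[1]]
  w <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) -3
    else if (p %in% c("AU", "UA")) -2
    else if (p %in% c("GU", "UG")) -1
    else NA_real_
  }
  best <- function(i, j) {
    if (j - i < 4) return(0)
    res <- best(i + 1, j)
    for (k in (i + 4):j) {
      wk <- w(ch[i], ch[k])
      if (!is.na(wk)) {
        inner <- if (k - i >= 6) best(i + 1, k - 1) else 0
        rest <- if (k < j) best(k + 1, j) else 0
        res <- min(res, wk + inner + rest)
      }
    }
    res
  }
  best(1, length(ch))
}
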