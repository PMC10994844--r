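# Synthetic-data generator. Produces genomes, dRNA-seq-like coverage
# tracks, count matrices and fitness tables with known planted truth so
# that every downstream stage can be tested without sequencing data. Seeds
# are mandatory arguments and the caller's RNG state is never disturbed.

#' Generate a random genome with non-overlapping genes
#'
#' Nucleotides are uniform i.i.d.; genes are laid out in operon-like blocks
#' (1-3 genes per block sharing a strand, short within-block gaps, long
#' between-block gaps), which mirrors bacterial gene organization and gives
#' the transcript planting step realistic operon structure. Gene
#' coordinates are 1-based inclusive.
#'
#' @param seed RNG seed
#' @param replicon_lengths named (or auto-named) vector of lengths (bp);
#'   each must be at least `10 * mean_gene_len`
#' @param n_genes total gene count
#' @param mean_gene_len mean gene length (bp)
#' @param block_sizes optional integer vector of operon block sizes summing
#'   to `n_genes`; drawn randomly from 1-3 when absent
#' @return list with `genome` (a `genome_bundle`) and `truth` (a
#'   `truth_set`; operon blocks recorded in `truth$operons`)
#' @export
generate_genome <- function(seed, replicon_lengths, n_genes,
                            mean_gene_len = 900, block_sizes = NULL) {
  .assert(all(replicon_lengths >= 10 * mean_gene_len),
          "every replicon must be >= 10 * mean_gene_len")
  .assert(n_genes >= 0, "n_genes must be >= 0")
  if (is.null(names(replicon_lengths)))
    names(replicon_lengths) <- if (length(replicon_lengths) == 1L) "chr"
      else c("chr", sprintf("p%d", seq_len(length(replicon_lengths) - 1L)))
  if (!is.null(block_sizes))
    .assert(sum(block_sizes) == n_genes,
            "block_sizes must sum to n_genes")
  with_seed(seed, {
    seqs <- vapply(replicon_lengths, function(L) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
             collapse = "")
    }, character(1L))
    # allocate genes to replicons proportionally to length
    alloc <- if (n_genes == 0L) integer(length(replicon_lengths)) else {
      a <- floor(n_genes * replicon_lengths / sum(replicon_lengths))
      while (sum(a) < n_genes) a[which.max(replicon_lengths - a)] <-
          a[which.max(replicon_lengths - a)] + 1L
      as.integer(a)
    }
    genes <- list()
    blocks <- list()
    gid <- 0L
    for (ri in seq_along(replicon_lengths)) {
      need <- alloc[ri]
      if (need == 0L) next
      L <- replicon_lengths[[ri]]
      rep_name <- names(replicon_lengths)[ri]
      placed <- NULL
      for (attempt in 1:20) {
        bs <- if (!is.null(block_sizes)) block_sizes else {
          out <- integer(0L)
          left <- need
          while (left > 0L) {
            b <- sample(1:3, 1L, prob = c(0.4, 0.35, 0.25))
            b <- min(b, left)
            out <- c(out, b)
            left <- left - b
          }
          out
        }
        pos <- sample(300:600, 1L)
        rows <- list()
        blk <- list()
        ok <- TRUE
        for (b in bs) {
          strand <- sample(c("+", "-"), 1L)
          ids <- character(0L)
          for (k in seq_len(b)) {
            len <- max(round(mean_gene_len * 0.3),
                       round(stats::rnorm(1L, mean_gene_len,
                                          mean_gene_len / 5)))
            if (pos + len - 1L > L - 300L) {
              ok <- FALSE
              break
            }
            id <- sprintf("G%04d", gid + length(rows) + 1L)
            rows[[length(rows) + 1L]] <- data.frame(
              id = id, replicon = rep_name, start = pos,
              end = pos + len - 1L, strand = strand, biotype = "CDS",
              stringsAsFactors = FALSE)
            ids <- c(ids, id)
            pos <- pos + len + sample(60:150, 1L)
          }
          if (!ok) break
          # genes within a block were appended left-to-right; transcription
          # order on - runs right-to-left
          if (strand == "-") ids <- rev(ids)
          blk[[length(blk) + 1L]] <- list(replicon = rep_name,
                                          strand = strand, genes = ids)
          pos <- pos + sample(450:900, 1L)
        }
        if (ok) {
          placed <- rows
          blocks <- c(blocks, blk)
          gid <- gid + length(rows)
          break
        }
      }
      if (is.null(placed))
        stop("cannot place genes: ", need, " genes of mean ",
             mean_gene_len, " bp do not fit on ", rep_name, call. = FALSE)
      genes <- c(genes, placed)
    }
    gene_df <- if (length(genes) == 0L) NULL else do.call(rbind, genes)
    truth <- .empty_truth(seed)
    truth$operons <- blocks
    list(genome = genome_bundle(seqs, gene_df,
                                provenance = list(generator = "synthetic",
                                                  seed = seed)),
         truth = truth)
  })
}

#' @noRd
.free_intergenic_regions <- function(genome, margin = 400L,
                                     occupied = NULL) {
  out <- list()
  for (rep in names(genome$replicons)) {
    L <- nchar(genome$replicons[[rep]])
    busy <- rep(FALSE, L)
    g <- genome$genes[genome$genes$replicon == rep, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      lo <- max(1L, g$start[i] - margin)
      hi <- min(L, g$end[i] + margin)
      busy[lo:hi] <- TRUE
    }
    if (!is.null(occupied)) {
      occ <- occupied[occupied$replicon == rep, , drop = FALSE]
      for (i in seq_len(nrow(occ))) {
        lo <- max(1L, occ$start[i] - margin)
        hi <- min(L, occ$end[i] + margin)
        busy[lo:hi] <- TRUE
      }
    }
    busy[seq_len(min(200L, L))] <- TRUE
    busy[seq(max(1L, L - 200L), L)] <- TRUE
    r <- rle(busy)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    free <- which(!r$values)
    for (j in free)
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep, start = starts[j], end = ends[j],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @noRd
.subst_string <- function(s, at, with) {
  for (i in seq_along(at)) substr(s, at[i], at[i]) <- with[i]
  s
}

#' Plant inverted repeats into intergenic space
#'
#' Each spec writes a left arm and the reverse complement of the left arm
#' (with the requested number of substitutions) separated by a random-
#' sequence spacer, into a free intergenic region. The four bases flanking
#' the arms (outside and inside) are set non-complementary so the planted
#' arm pair is maximal and recoverable at its exact coordinates.
#'
#' @param genome a `genome_bundle`
#' @param specs list of specs: `list(arm_len, mismatches, spacer_len,
#'   homopolymeric)` (homopolymeric defaults to `FALSE`)
#' @param seed RNG seed
#' @param truth a `truth_set` to extend (a fresh one is made when absent)
#' @return list with the modified `genome` and the extended `truth`
#'   (`truth$irs` records exact arm coordinates)
#' @export
plant_inverted_repeats <- function(genome, specs, seed, truth = NULL) {
  if (is.null(truth)) truth <- .empty_truth(seed)
  for (sp in specs) {
    .assert(sp$arm_len >= 1, "arm_len must be >= 1")
    .assert(sp$spacer_len >= 0, "spacer_len must be >= 0")
    .assert(is.null(sp$mismatches) || sp$mismatches <= sp$arm_len,
            "mismatches cannot exceed arm_len")
  }
  with_seed(seed, {
    for (sp in specs) {
      arm <- sp$arm_len
      mm <- if (is.null(sp$mismatches)) 0L else sp$mismatches
      spacer <- sp$spacer_len
      homo <- isTRUE(sp$homopolymeric)
      total <- 2L * arm + spacer + 2L   # + inner/outer breaker margin
      free <- .free_intergenic_regions(genome, margin = 200L,
                                       occupied = truth$irs[,
                                         c("replicon", "left_start",
                                           "right_end"), drop = FALSE] |>
                                         stats::setNames(c("replicon",
                                                           "start", "end")))
      free <- free[free$end - free$start + 1L >= total + 20L, ,
                   drop = FALSE]
      .assert(nrow(free) > 0L, "no intergenic region fits the IR spec (",
              arm, ", ", spacer, ")")
      row <- free[sample.int(nrow(free), 1L), ]
      offset_max <- (row$end - row$start + 1L) - total - 10L
      l_start <- row$start + sample.int(max(offset_max, 1L), 1L) + 4L
      left <- if (homo) strrep("A", arm)
        else paste0(sample(c("A", "C", "G", "T"), arm, replace = TRUE),
                    collapse = "")
      right <- revcomp(left)
      if (mm > 0L) {
        at <- sample.int(arm, mm)
        orig <- substring(right, at, at)
        with <- vapply(orig, function(ch)
          sample(setdiff(c("A", "C", "G", "T"), ch), 1L), character(1L))
        right <- .subst_string(right, at, with)
      }
      l_end <- l_start + arm - 1L
      r_start <- l_end + spacer + 1L
      r_end <- r_start + arm - 1L
      s <- genome$replicons[[row$replicon]]
      substr(s, l_start, l_end) <- left
      substr(s, r_start, r_end) <- right
      # breaker bases: outer pair and inner pair must not be complementary
      # (A opposite C can never pair), so the planted arms are maximal
      s <- .subst_string(s, c(l_start - 1L, r_end + 1L), c("A", "C"))
      if (spacer >= 2L)
        s <- .subst_string(s, c(l_end + 1L, r_start - 1L), c("A", "C"))
      genome$replicons[[row$replicon]] <- s
      truth$irs <- rbind(truth$irs, data.frame(
        replicon = row$replicon, left_start = l_start, left_end = l_end,
        right_start = r_start, right_end = r_end, arm_length = arm,
        mismatches = mm, spacer_length = spacer, homopolymeric = homo,
        stringsAsFactors = FALSE))
    }
    list(genome = genome, truth = truth)
  })
}

#' Plant transcription units, TSSs, terminators and sRNAs
#'
#' Derives the full transcript geometry from the operon blocks recorded by
#' [generate_genome()]: one transcription unit per block (TSS upstream of
#' the first gene, terminator downstream of the last), optional secondary
#' and orphan TSSs, and sRNAs of the five sub-classes with the coverage
#' geometry each class needs (own TSS for intergenic/antisense, elevated
#' 5' UTR segments, 3' UTR TSS sharing the unit terminator, and an internal
#' processing-site-anchored segment for intra-operonic sRNAs).
#'
#' @param genome a `genome_bundle` from [generate_genome()]
#' @param truth its `truth_set`
#' @param seed RNG seed
#' @param n_srna named counts per class, e.g.
#'   `c(intergenic = 4, antisense = 3, utr5 = 2, utr3 = 2,
#'   intra_operonic = 1)`
#' @param n_secondary units that receive a secondary TSS
#' @param n_orphan standalone orphan TSSs planted in free regions
#' @param embedded_level coverage multiplier of sRNA segments embedded in
#'   longer units
#' @return the extended `truth_set` (`tss`, `terminators`, `srnas`,
#'   `processing_sites`, `units` filled)
#' @export
plant_transcripts <- function(genome, truth, seed,
                              n_srna = c(intergenic = 4, antisense = 3,
                                         utr5 = 2, utr3 = 2,
                                         intra_operonic = 1),
                              n_secondary = 0, n_orphan = 0,
                              embedded_level = 4) {
  blocks <- truth$operons
  .assert(length(blocks) > 0L, "no operon blocks in truth; generate first")
  gidx <- stats::setNames(seq_len(nrow(genome$genes)), genome$genes$id)
  gene_row <- function(id) genome$genes[gidx[[id]], ]
  with_seed(seed, {
    tss <- list()
    term <- list()
    units <- list()
    srnas <- list()
    psites <- list()
    add_tss <- function(rep, pos, strand, kind, hf = 1)
      tss[[length(tss) + 1L]] <<- data.frame(
        replicon = rep, pos = as.integer(pos), strand = strand,
        kind = kind, height_factor = hf, stringsAsFactors = FALSE)
    add_unit <- function(rep, start, end, strand, level)
      units[[length(units) + 1L]] <<- data.frame(
        replicon = rep, start = as.integer(start), end = as.integer(end),
        strand = strand, level = level, stringsAsFactors = FALSE)
    add_srna <- function(id, rep, start, end, strand, class)
      srnas[[length(srnas) + 1L]] <<- data.frame(
        id = id, replicon = rep, start = as.integer(start),
        end = as.integer(end), strand = strand, class = class,
        stringsAsFactors = FALSE)

    # which blocks host utr5 / utr3 / intra sRNAs
    nb <- length(blocks)
    n_srna <- n_srna[c("intergenic", "antisense", "utr5", "utr3",
                       "intra_operonic")]
    n_srna[is.na(n_srna)] <- 0L
    names(n_srna) <- c("intergenic", "antisense", "utr5", "utr3",
                       "intra_operonic")
    multi <- which(vapply(blocks, function(b) {
      length(b$genes) >= 2L && {
        g1 <- gene_row(b$genes[1L])
        g1$end - g1$start + 1L >= 400L
      }
    }, logical(1L)))
    .assert(n_srna[["intra_operonic"]] <= length(multi),
            "not enough multi-gene blocks for intra-operonic sRNAs")
    host_intra <- if (n_srna[["intra_operonic"]] > 0L)
      sample(multi, n_srna[["intra_operonic"]]) else integer(0L)
    rest <- setdiff(seq_len(nb), host_intra)
    .assert(n_srna[["utr5"]] + n_srna[["utr3"]] <= length(rest),
            "not enough blocks for UTR-derived sRNAs")
    host_utr5 <- if (n_srna[["utr5"]] > 0L)
      utils::head(rest, n_srna[["utr5"]]) else integer(0L)
    rest <- setdiff(rest, host_utr5)
    host_utr3 <- if (n_srna[["utr3"]] > 0L)
      utils::head(rest, n_srna[["utr3"]]) else integer(0L)
    sec_hosts <- utils::head(setdiff(seq_len(nb),
                                     c(host_utr5, host_utr3)), n_secondary)

    srna_id <- 0L
    next_srna_id <- function(class) {
      srna_id <<- srna_id + 1L
      sprintf("BTnc%03d_%s", srna_id, class)
    }

    for (bi in seq_len(nb)) {
      b <- blocks[[bi]]
      first <- gene_row(b$genes[1L])
      last <- gene_row(b$genes[length(b$genes)])
      strand <- b$strand
      rep <- b$replicon
      utr5_here <- bi %in% host_utr5
      tss_off <- if (utr5_here) sample(60:100, 1L) else sample(20:50, 1L)
      term_off <- if (bi %in% host_utr3) sample(55:80, 1L)
                  else sample(20:60, 1L)
      if (strand == "+") {
        tss_pos <- first$start - tss_off
        term_pos <- last$end + term_off
        unit <- c(tss_pos, term_pos)
      } else {
        tss_pos <- first$end + tss_off
        term_pos <- last$start - term_off
        unit <- c(term_pos, tss_pos)
      }
      add_tss(rep, tss_pos, strand, "primary")
      term[[length(term) + 1L]] <- data.frame(
        replicon = rep, pos = as.integer(term_pos), strand = strand,
        stringsAsFactors = FALSE)
      add_unit(rep, unit[1L], unit[2L], strand, 1)
      if (bi %in% sec_hosts) {
        # secondary TSS a little closer to the gene start, lower height
        d <- sample(12:18, 1L)
        spos <- if (strand == "+") tss_pos + d else tss_pos - d
        add_tss(rep, spos, strand, "secondary", hf = 0.5)
      }
      if (utr5_here) {
        # 5' UTR-derived sRNA shares the unit TSS, ends before the gene
        if (strand == "+") {
          s0 <- tss_pos
          s1 <- first$start - 10L
        } else {
          s0 <- first$end + 10L
          s1 <- tss_pos
        }
        add_unit(rep, min(s0, s1), max(s0, s1), strand, embedded_level)
        add_srna(next_srna_id("utr5"), rep, min(s0, s1), max(s0, s1),
                 strand, "utr5_derived")
      }
      if (bi %in% host_utr3) {
        # 3' UTR TSS anchoring an sRNA that shares the unit terminator
        a_off <- sample(5:15, 1L)
        if (strand == "+") {
          apos <- last$end + a_off
          add_unit(rep, apos, term_pos, strand, embedded_level)
          add_srna(next_srna_id("utr3"), rep, apos, term_pos, strand,
                   "utr3_derived")
        } else {
          apos <- last$start - a_off
          add_unit(rep, term_pos, apos, strand, embedded_level)
          add_srna(next_srna_id("utr3"), rep, term_pos, apos, strand,
                   "utr3_derived")
        }
        add_tss(rep, apos, strand, "utr3_anchor")
      }
      if (bi %in% host_intra) {
        # intra-operonic sRNA: processing-site anchor inside the first
        # gene body, ending before the gene does so the boundary drop
        # stays out of the intergenic span
        g1 <- gene_row(b$genes[1L])
        len <- sample(120:180, 1L)
        # keep the 3' boundary >70 bp inside the gene so the drop-finder's
        # upstream window never reaches it from the intergenic gap
        if (strand == "+") {
          e <- g1$end - 70L
          apos <- e - len + 1L
        } else {
          e <- g1$start + 70L
          apos <- e + len - 1L
        }
        add_unit(rep, min(apos, e), max(apos, e), strand, embedded_level)
        psites[[length(psites) + 1L]] <- data.frame(
          replicon = rep, pos = as.integer(apos), strand = strand,
          stringsAsFactors = FALSE)
        add_srna(next_srna_id("intra"), rep, min(apos, e), max(apos, e),
                 strand, "intra_operonic")
      }
    }

    # antisense sRNAs inside gene bodies on the opposite strand
    n_as <- n_srna[["antisense"]]
    if (n_as > 0L) {
      big <- genome$genes[genome$genes$end - genome$genes$start + 1L >=
                            400L, , drop = FALSE]
      .assert(nrow(big) >= n_as, "not enough long genes for asRNAs")
      hosts <- big[sample.int(nrow(big), n_as), , drop = FALSE]
      for (i in seq_len(n_as)) {
        h <- hosts[i, ]
        strand <- if (h$strand == "+") "-" else "+"
        len <- sample(100:250, 1L)
        lo <- h$start + 20L
        hi <- h$end - 20L - len
        st <- sample(lo:max(lo, hi), 1L)
        en <- st + len - 1L
        p5 <- if (strand == "+") st else en
        add_tss(h$replicon, p5, strand, "srna")
        add_unit(h$replicon, st, en, strand, 1)
        add_srna(next_srna_id("as"), h$replicon, st, en, strand,
                 "antisense")
      }
    }

    # intergenic sRNAs in free regions far from genes
    n_ig <- n_srna[["intergenic"]]
    placed_sr <- if (length(srnas) > 0L) do.call(rbind, srnas) else NULL
    occupied <- rbind(
      if (!is.null(placed_sr))
        placed_sr[, c("replicon", "start", "end"), drop = FALSE],
      if (nrow(truth$irs) > 0L)
        stats::setNames(truth$irs[, c("replicon", "left_start",
                                      "right_end")],
                        c("replicon", "start", "end")))
    for (i in seq_len(n_ig)) {
      free <- .free_intergenic_regions(genome, margin = 400L,
                                       occupied = occupied)
      len <- sample(100:250, 1L)
      free <- free[free$end - free$start + 1L >= len + 100L, ,
                   drop = FALSE]
      .assert(nrow(free) > 0L, "no free region for intergenic sRNA")
      row <- free[sample.int(nrow(free), 1L), ]
      st <- row$start + 50L
      en <- st + len - 1L
      strand <- sample(c("+", "-"), 1L)
      p5 <- if (strand == "+") st else en
      add_tss(row$replicon, p5, strand, "srna")
      add_unit(row$replicon, st, en, strand, 1)
      add_srna(next_srna_id("ig"), row$replicon, st, en, strand,
               "intergenic")
      occupied <- rbind(occupied, data.frame(replicon = row$replicon,
                                             start = st, end = en,
                                             stringsAsFactors = FALSE))
    }

    # standalone orphan TSSs (no transcript behind them)
    for (i in seq_len(n_orphan)) {
      free <- .free_intergenic_regions(genome, margin = 400L,
                                       occupied = occupied)
      .assert(nrow(free) > 0L, "no free region for orphan TSS")
      row <- free[sample.int(nrow(free), 1L), ]
      pos <- row$start + sample.int(row$end - row$start + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      add_tss(row$replicon, pos, strand, "orphan")
      occupied <- rbind(occupied, data.frame(replicon = row$replicon,
                                             start = pos - 20L,
                                             end = pos + 20L,
                                             stringsAsFactors = FALSE))
    }

    truth$tss <- do.call(rbind, tss)
    truth$terminators <- do.call(rbind, term)
    truth$units <- do.call(rbind, units)
    truth$srnas <- if (length(srnas) > 0L) do.call(rbind, srnas)
                   else truth$srnas
    truth$processing_sites <- if (length(psites) > 0L)
      do.call(rbind, psites) else truth$processing_sites
    truth
  })
}

#' Simulate dRNA-seq coverage from planted truth
#'
#' Renders the planted transcription units into per-position Poisson rate
#' profiles and draws TEX+ and TEX- tracks. 5'-start counts at planted
#' TSSs average `tss_height` in the TEX+ library and
#' `tss_height / enrichment_factor` in the untreated one; processing sites
#' show the reverse pattern. Full coverage decays to
#' `(1 - terminator_drop)` of the unit level over a 100-bp tail downstream
#' of each planted terminator; the background is Poisson(`noise_rate`)
#' everywhere.
#'
#' @param genome a `genome_bundle`
#' @param truth a `truth_set` from [plant_transcripts()]
#' @param enrichment_factor TEX+/TEX- ratio at genuine TSSs (> 1)
#' @param tss_height mean TEX+ 5'-start count at a planted TSS (reads)
#' @param noise_rate background Poisson rate (reads per position)
#' @param terminator_drop fractional coverage loss at terminators, in
#'   (0, 1]
#' @param seed RNG seed
#' @param internal_start_rate per-position 5'-start rate inside transcripts
#'   as a fraction of local coverage
#' @param tail_len residual-coverage tail length after terminators (bp)
#' @return a `coverage_set`
#' @export
simulate_drnaseq_coverage <- function(genome, truth,
                                      enrichment_factor = 10,
                                      tss_height = 100, noise_rate = 0.1,
                                      terminator_drop = 0.9, seed = 1,
                                      internal_start_rate = 0.01,
                                      tail_len = 100) {
  .assert(enrichment_factor > 1, "enrichment_factor must be > 1")
  .assert(terminator_drop > 0 && terminator_drop <= 1,
          "terminator_drop must lie in (0, 1]")
  .assert(noise_rate >= 0 && tss_height >= 0, "negative rate")
  lens <- .replicon_lengths(genome)
  cs <- coverage_set(lens)
  with_seed(seed, {
    for (rep in names(lens)) {
      L <- lens[[rep]]
      for (strand in c("+", "-")) {
        lam <- numeric(L)
        u <- truth$units[truth$units$replicon == rep &
                           truth$units$strand == strand, , drop = FALSE]
        for (i in seq_len(nrow(u)))
          lam[u$start[i]:u$end[i]] <-
            pmax(lam[u$start[i]:u$end[i]], tss_height * u$level[i])
        tt <- truth$terminators[truth$terminators$replicon == rep &
                                  truth$terminators$strand == strand, ,
                                drop = FALSE]
        for (i in seq_len(nrow(tt))) {
          p <- tt$pos[i]
          resid_lam <- lam[p] * (1 - terminator_drop)
          # read-through decays linearly to background over the tail
          decay <- resid_lam * seq(1, 0, length.out = tail_len)
          span <- if (strand == "+") (p + 1L):min(L, p + tail_len)
                  else max(1L, p - tail_len):(p - 1L)
          dist <- abs(span - p)                     # 1..tail_len
          lam[span] <- pmax(lam[span], decay[dist])
        }
        cov_tm <- stats::rpois(L, lam + noise_rate)
        cov_tp <- stats::rpois(L, lam + noise_rate)
        st_tm <- stats::rpois(L, lam * internal_start_rate + noise_rate)
        # TEX degrades processed (5'-monophosphate) ends, so internal
        # starts are depleted in the treated library
        st_tp <- stats::rpois(
          L, lam * internal_start_rate / enrichment_factor + noise_rate)
        ts <- truth$tss[truth$tss$replicon == rep &
                          truth$tss$strand == strand, , drop = FALSE]
        for (i in seq_len(nrow(ts))) {
          h <- tss_height * ts$height_factor[i]
          p <- ts$pos[i]
          st_tp[p] <- st_tp[p] + stats::rpois(1L, h)
          st_tm[p] <- st_tm[p] + stats::rpois(1L, h / enrichment_factor)
        }
        ps <- truth$processing_sites[
          truth$processing_sites$replicon == rep &
            truth$processing_sites$strand == strand, , drop = FALSE]
        for (i in seq_len(nrow(ps))) {
          p <- ps$pos[i]
          st_tm[p] <- st_tm[p] + stats::rpois(1L, tss_height)
          st_tp[p] <- st_tp[p] +
            stats::rpois(1L, tss_height / enrichment_factor)
        }
        cov_track(cs, rep, "tex_minus", strand, "cov") <- cov_tm
        cov_track(cs, rep, "tex_plus", strand, "cov") <- cov_tp
        cov_track(cs, rep, "tex_minus", strand, "starts") <- st_tm
        cov_track(cs, rep, "tex_plus", strand, "starts") <- st_tp
      }
    }
    cs
  })
}

#' Simulate a count matrix with planted effects
#'
#' Counts are drawn negative-binomially (Poisson when `dispersion = 0`)
#' around condition means. Planted differentially expressed genes change
#' their mean by `2^log2fc` in `de_condition`; genes in a planted regulon
#' share a latent per-condition profile scaled to reach the target
#' inter-gene correlation.
#'
#' @param n_genes gene count
#' @param condition_map named character vector, sample name to condition;
#'   the first condition is the control
#' @param libsizes reads per sample (scalar or per-sample vector)
#' @param dispersion NB dispersion (>= 0)
#' @param planted_de named numeric vector, gene id to true log2 fold change
#' @param de_condition condition carrying the planted fold changes
#'   (default: the second condition)
#' @param planted_regulons list of specs `list(n_genes, target_cor,
#'   amplitude)`; member genes are drawn from unplanted genes
#' @param seed RNG seed
#' @return list with `expr` (an `expr_matrix`) and `truth` (planted DE map
#'   and regulon membership); single-replicate conditions are recorded as a
#'   provenance warning, not an error
#' @export
simulate_counts <- function(n_genes, condition_map, libsizes = 3e6,
                            dispersion = 0.05, planted_de = numeric(0L),
                            de_condition = NULL,
                            planted_regulons = list(), seed = 1) {
  .assert(dispersion >= 0, "dispersion must be >= 0")
  conds <- unique(condition_map)
  .assert(length(conds) >= 1L, "need at least one condition")
  if (is.null(de_condition))
    de_condition <- if (length(conds) >= 2L) conds[2L] else conds[1L]
  samples <- names(condition_map)
  if (length(libsizes) == 1L)
    libsizes <- stats::setNames(rep(libsizes, length(samples)), samples)
  genes <- sprintf("G%04d", seq_len(n_genes))
  .assert(all(names(planted_de) %in% genes),
          "planted_de names must be gene ids within 1..n_genes")
  provenance <- list(warnings = character(0L))
  tab <- table(condition_map)
  if (any(tab < 2L))
    provenance$warnings <- c(provenance$warnings,
                             paste("single replicate in condition(s):",
                                   paste(names(tab)[tab < 2L],
                                         collapse = ", ")))
  with_seed(seed, {
    q <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
    q <- q / sum(q)
    effect <- matrix(0, n_genes, length(conds),
                     dimnames = list(genes, conds))
    if (length(planted_de) > 0L)
      effect[names(planted_de), de_condition] <- planted_de
    truth <- .empty_truth(seed)
    truth$de <- planted_de
    regulon_members <- list()
    taken <- names(planted_de)
    for (ri in seq_along(planted_regulons)) {
      spec <- planted_regulons[[ri]]
      rho <- spec$target_cor
      amp <- if (is.null(spec$amplitude)) 2 else spec$amplitude
      pool <- setdiff(genes, taken)
      .assert(length(pool) >= spec$n_genes, "not enough genes for regulon")
      members <- sample(pool, spec$n_genes)
      taken <- c(taken, members)
      z <- stats::rnorm(length(conds))
      e <- matrix(stats::rnorm(spec$n_genes * length(conds)),
                  spec$n_genes, length(conds))
      effect[members, ] <- effect[members, ] +
        amp * (sqrt(rho) * matrix(z, spec$n_genes, length(conds),
                                  byrow = TRUE) +
                 sqrt(1 - rho) * e)
      regulon_members[[sprintf("regulon%02d", ri)]] <- members
    }
    truth$regulons <- regulon_members
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      cc <- condition_map[[samples[j]]]
      mu <- q * libsizes[[samples[j]]] * 2^effect[, cc]
      counts[, j] <- if (dispersion < 1e-12) stats::rpois(n_genes, mu)
        else stats::rnbinom(n_genes, size = 1 / dispersion, mu = mu)
    }
    em <- expr_matrix(counts, condition_map, lib_sizes = libsizes)
    em$provenance <- provenance
    list(expr = em, truth = truth)
  })
}

#' Simulate an sRNA fitness table
#'
#' Background entries draw `fit` from a small-variance normal and `t`
#' uniformly inside the null band (|t| < 3); planted hits carry their
#' specified `fit` and `t`. A random subset of background entries is
#' flagged unsuccessful; planted hits honour their own `success` field
#' (default successful).
#'
#' @param n_srnas,n_experiments table dimensions
#' @param planted_hits data.frame with columns `srna`, `experiment`,
#'   `fit`, `t` and optional `success`
#' @param seed RNG seed
#' @param p_unsuccessful probability a background entry is unsuccessful
#' @return list with `table` (a `fitness_table`) and `truth`
#' @export
simulate_fitness_table <- function(n_srnas, n_experiments,
                                   planted_hits = NULL, seed = 1,
                                   p_unsuccessful = 0.05) {
  srnas <- sprintf("sRNA%03d", seq_len(n_srnas))
  exps <- sprintf("exp%03d", seq_len(n_experiments))
  if (!is.null(planted_hits) && nrow(planted_hits) > 0L) {
    .assert(all(abs(planted_hits$t) >= 3),
            "planted |t| must lie outside the null band (|t| < 3)")
    .assert(all(planted_hits$srna %in% srnas) &&
              all(planted_hits$experiment %in% exps),
            "planted hits reference unknown srna/experiment ids")
    if (is.null(planted_hits$success)) planted_hits$success <- TRUE
  }
  with_seed(seed, {
    tab <- data.frame(
      srna = rep(srnas, each = n_experiments),
      experiment = rep(exps, times = n_srnas),
      fit = stats::rnorm(n_srnas * n_experiments, 0, 0.5),
      t = stats::runif(n_srnas * n_experiments, -2.9, 2.9),
      success = stats::runif(n_srnas * n_experiments) > p_unsuccessful,
      stringsAsFactors = FALSE)
    if (!is.null(planted_hits) && nrow(planted_hits) > 0L) {
      for (i in seq_len(nrow(planted_hits))) {
        h <- planted_hits[i, ]
        sel <- tab$srna == h$srna & tab$experiment == h$experiment
        tab$fit[sel] <- h$fit
        tab$t[sel] <- h$t
        tab$success[sel] <- h$success
      }
    }
    truth <- .empty_truth(seed)
    truth$fitness_hits <- if (is.null(planted_hits))
      truth$fitness_hits else planted_hits
    list(table = fitness_table(tab), truth = truth)
  })
}
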