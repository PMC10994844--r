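# Small-RNA discovery: transcript calling from coverage, processing-site
# detection, candidate derivation anchored at 5' ends, a folding-stability
# proxy, classification into the five sub-classes and automated curation.

#' Call transcript intervals from full coverage
#'
#' Maximal runs of untreated full coverage of at least `min_cov` are
#' reported per strand; runs separated by at most `merge_gap` bp are
#' merged and runs shorter than `min_len` dropped.
#'
#' @param coverage a `coverage_set`
#' @param min_cov minimum coverage (reads)
#' @param min_len minimum transcript length (nt)
#' @param merge_gap maximum gap bridged when merging (bp)
#' @return data.frame: `replicon`, `start`, `end`, `strand`
#' @export
call_transcripts <- function(coverage, min_cov = 5, min_len = 30,
                             merge_gap = 10) {
  out <- list()
  for (rep in names(coverage$lengths)) {
    for (strand in c("+", "-")) {
      v <- cov_track(coverage, rep, "tex_minus", strand, "cov")
      r <- rle(v >= min_cov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- data.frame(start = starts[r$values], end = ends[r$values])
      if (nrow(runs) == 0L) next
      # merge runs separated by <= merge_gap
      merged <- runs[1L, , drop = FALSE]
      if (nrow(runs) > 1L) {
        for (i in 2:nrow(runs)) {
          gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
          if (gap <= merge_gap) {
            merged$end[nrow(merged)] <- runs$end[i]
          } else {
            merged <- rbind(merged, runs[i, , drop = FALSE])
          }
        }
      }
      merged <- merged[merged$end - merged$start + 1L >= min_len, ,
                       drop = FALSE]
      if (nrow(merged) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep, start = merged$start, end = merged$end,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect RNA processing sites
#'
#' A processing site is defined operationally as a position where the
#' untreated full coverage steps up by at least `step_ratio` over the mean
#' of the `smooth` upstream positions (strand-aware), reaches `min_cov`
#' reads, and is not TEX-enriched (so it is not a TSS candidate: the
#' TEX+/TEX- 5'-start ratio stays below `tss_min_enrichment`).
#'
#' @param coverage a `coverage_set`
#' @param min_cov minimum coverage at the site (reads)
#' @param step_ratio minimum upward coverage step
#' @param tss_min_enrichment TEX enrichment above which a step is treated
#'   as a TSS, not a processing site
#' @param smooth upstream positions averaged for the step baseline
#' @return data.frame: `replicon`, `pos`, `strand`
#' @export
detect_processing_sites <- function(coverage, min_cov = 10, step_ratio = 3,
                                    tss_min_enrichment = 2, smooth = 5) {
  out <- list()
  for (rep in names(coverage$lengths)) {
    for (strand in c("+", "-")) {
      v <- cov_track(coverage, rep, "tex_minus", strand, "cov")
      tp <- cov_track(coverage, rep, "tex_plus", strand, "starts")
      tm <- cov_track(coverage, rep, "tex_minus", strand, "starts")
      L <- length(v)
      pos <- which(v >= min_cov)
      if (length(pos) == 0L) next
      base <- vapply(pos, function(p) {
        if (strand == "+") .win_mean(v, p - smooth, p - 1L)
        else .win_mean(v, p + 1L, p + smooth)
      }, numeric(1L))
      base[is.na(base)] <- 0
      step_up <- v[pos] >= step_ratio * pmax(1, base)
      # TEX-enriched 5' ends are TSSs, not processing sites; exclude the
      # step position and its immediate neighbourhood
      tss_like_pos <- which(tp >= min_cov &
                              tp / pmax(tm, 1) >= tss_min_enrichment)
      near_tss <- rep(FALSE, L)
      for (d in -3:3) {
        idx <- tss_like_pos + d
        idx <- idx[idx >= 1L & idx <= L]
        near_tss[idx] <- TRUE
      }
      keep <- pos[step_up & !near_tss[pos]]
      if (length(keep) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep, pos = keep, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(replicon = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive sRNA candidate intervals anchored at 5' ends
#'
#' For every 5' anchor (detected TSS or processing site) the untreated
#' coverage is walked downstream while it stays at or above
#' `keep_frac` of the level just downstream of the anchor (and above
#' `min_cov`); the candidate ends where coverage falls below that bar or
#' after `max_len` nt. This recovers sRNAs that are embedded in longer
#' transcription units (UTR-derived, intra-operonic) as well as standalone
#' ones.
#'
#' @param coverage a `coverage_set`
#' @param tss_records detected (optionally classified) `tss_records`
#' @param processing_sites data.frame from [detect_processing_sites()]
#' @param min_len,max_len candidate length bounds (nt)
#' @param keep_frac fraction of the anchor-level coverage below which the
#'   candidate ends
#' @param min_cov absolute coverage floor (reads)
#' @return data.frame: `replicon`, `start`, `end`, `strand`, `anchor`
#'   (`"tss"` or `"processing_site"`), `anchor_pos`
#' @export
derive_srna_candidates <- function(coverage, tss_records, processing_sites,
                                   min_len = 30, max_len = 500,
                                   keep_frac = 0.5, min_cov = 5) {
  anchors <- rbind(
    if (nrow(tss_records) > 0L)
      data.frame(replicon = tss_records$replicon, pos = tss_records$pos,
                 strand = tss_records$strand, anchor = "tss",
                 stringsAsFactors = FALSE),
    if (nrow(processing_sites) > 0L)
      data.frame(replicon = processing_sites$replicon,
                 pos = processing_sites$pos,
                 strand = processing_sites$strand,
                 anchor = "processing_site", stringsAsFactors = FALSE))
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      anchor = character(), anchor_pos = integer(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    v <- cov_track(coverage, a$replicon, "tex_minus", a$strand, "cov")
    L <- length(v)
    dirn <- if (a$strand == "+") 1L else -1L
    # anchor level: mean coverage over the first few transcribed positions
    lvl <- .win_mean(v, min(a$pos, a$pos + dirn * 4L),
                     max(a$pos, a$pos + dirn * 4L))
    if (is.na(lvl) || lvl < min_cov) next
    bar <- max(min_cov, keep_frac * lvl)
    p <- a$pos
    steps <- 0L
    while (steps < max_len - 1L) {
      nxt <- p + dirn
      if (nxt < 1L || nxt > L || v[nxt] < bar) break
      p <- nxt
      steps <- steps + 1L
    }
    st <- min(a$pos, p)
    en <- max(a$pos, p)
    if (en - st + 1L < min_len) next
    out[[length(out) + 1L]] <- data.frame(
      replicon = a$replicon, start = st, end = en, strand = a$strand,
      anchor = a$anchor, anchor_pos = a$pos, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      anchor = character(), anchor_pos = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("replicon", "start", "end", "strand")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Folding-stability proxy for an RNA sequence
#'
#' A weighted Nussinov-style dynamic program over nested structures
#' (GC = -3, AU = -2, GU = -1 per pair; hairpin loops of at least 3 nt)
#' stands in for a full thermodynamic model. The normalized value is the
#' energy divided by the sequence length; values below the stability
#' threshold (default -0.05 on this proxy scale) mark stably structured
#' RNAs. The proxy is deterministic, never positive, and 0 for sequences
#' with no complementary pairing.
#'
#' @param sequence character scalar (A/C/G/T/U)
#' @return list with `energy` and `normalized` (energy per nt)
#' @export
folding_energy <- function(sequence) {
  .assert(is.character(sequence) && length(sequence) == 1L &&
            nchar(sequence) >= 1L, "sequence must be one non-empty string")
  s <- toupper(sequence)
  .assert(!grepl("[^ACGTU]", s), "non-nucleotide characters in sequence")
  e <- .fold_energy_cpp(s)
  list(energy = e, normalized = e / nchar(s))
}

#' @noRd
.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

# 5'/3' ends of an interval in transcription orientation
#' @noRd
.five_prime <- function(start, end, strand) ifelse(strand == "+", start, end)
#' @noRd
.three_prime <- function(start, end, strand) ifelse(strand == "+", end, start)

#' Classify sRNA candidates into sub-classes
#'
#' Each candidate receives exactly one class by the precedence
#' intergenic, antisense, 5' UTR-derived, 3' UTR-derived, intra-operonic
#' (first satisfied wins); candidates satisfying none are rejected with
#' reason `"unclassifiable"`.
#'
#' Rules: intergenic needs a (non-mRNA) TSS at the 5' end and no gene
#' overlap on either strand; antisense needs a TSS and an opposite-strand
#' gene overlap without a same-strand one; 5' UTR-derived shares a
#' primary/secondary TSS with an mRNA and ends before that gene's start;
#' 3' UTR-derived starts (TSS or processing site) within the 3' UTR of a
#' gene and ends at a shared terminator or processing site; intra-operonic
#' lies inside an operon with a TSS or processing site at its 5' end.
#'
#' @param transcripts candidate intervals (`replicon`, `start`, `end`,
#'   `strand`), e.g. from [derive_srna_candidates()] or
#'   [call_transcripts()]
#' @param tss_records classified `tss_records`
#' @param processing_sites data.frame from [detect_processing_sites()]
#' @param genes gene data.frame
#' @param operons list from [assemble_operons()]
#' @param terminators terminator data.frame
#' @param end_tol tolerance (bp) when matching TSSs, processing sites and
#'   terminators to candidate ends
#' @param utr3_len assumed maximal 3' UTR extent (bp)
#' @param utr5_margin assumed maximal 5' UTR extent (bp); together with
#'   `utr3_len` it widens operon spans into transcript extents for the
#'   intergenic no-overlap test, which considers any genetic feature
#'   (genes and mRNA transcripts) on either strand
#' @return data.frame of class `srna_records` with `id`, coordinates,
#'   `class`, `tss_support`, `length`, `rejection_reasons` (list-column;
#'   empty for classified candidates)
#' @export
classify_srnas <- function(transcripts, tss_records, processing_sites,
                           genes, operons, terminators, end_tol = 10,
                           utr3_len = 300, utr5_margin = 150) {
  n <- nrow(transcripts)
  cls_tab <- tss_classes_table(tss_records)
  res <- transcripts[, c("replicon", "start", "end", "strand"),
                     drop = FALSE]
  res$length <- res$end - res$start + 1L
  res$class <- NA_character_
  res$tss_support <- NA_character_
  reasons <- replicate(n, character(0L), simplify = FALSE)

  op_tab <- if (length(operons) > 0L) operon_table(operons) else NULL
  # genetic-feature spans for the intergenic no-overlap test: gene bodies
  # plus operon spans widened into transcript extents by the UTR margins
  feat <- genes[, c("replicon", "start", "end"), drop = FALSE]
  if (!is.null(op_tab) && nrow(op_tab) > 0L) {
    ext <- data.frame(
      replicon = op_tab$replicon,
      start = ifelse(op_tab$strand == "+", op_tab$start - utr5_margin,
                     op_tab$start - utr3_len),
      end = ifelse(op_tab$strand == "+", op_tab$end + utr3_len,
                   op_tab$end + utr5_margin),
      stringsAsFactors = FALSE)
    feat <- rbind(feat, ext)
  }

  for (i in seq_len(n)) {
    x <- res[i, ]
    p5 <- .five_prime(x$start, x$end, x$strand)
    p3 <- .three_prime(x$start, x$end, x$strand)
    # TSS at the 5' end
    near_tss <- tss_records[tss_records$replicon == x$replicon &
                              tss_records$strand == x$strand &
                              abs(tss_records$pos - p5) <= end_tol, ,
                            drop = FALSE]
    has_tss <- nrow(near_tss) > 0L
    tss_id <- if (has_tss) near_tss$id[1L] else NA_character_
    tss_classes <- if (has_tss)
      cls_tab$class[cls_tab$id %in% near_tss$id] else character(0L)
    tss_is_mrna <- any(tss_classes %in% c("primary", "secondary"))
    # processing site at the 5' end
    has_ps5 <- nrow(processing_sites) > 0L &&
      any(processing_sites$replicon == x$replicon &
            processing_sites$strand == x$strand &
            abs(processing_sites$pos - p5) <= end_tol)
    # gene overlaps
    gsel <- genes$replicon == x$replicon &
      .overlaps(x$start, x$end, genes$start, genes$end)
    over_sense <- any(gsel & genes$strand == x$strand)
    over_anti <- any(gsel & genes$strand != x$strand)
    # terminator / processing site at the 3' end
    has_term3 <- nrow(terminators) > 0L &&
      any(terminators$replicon == x$replicon &
            terminators$strand == x$strand &
            terminators$start - end_tol <= p3 &
            terminators$end + end_tol >= p3)
    has_ps3 <- nrow(processing_sites) > 0L &&
      any(processing_sites$replicon == x$replicon &
            processing_sites$strand == x$strand &
            abs(processing_sites$pos - p3) <= end_tol)

    over_feat <- any(feat$replicon == x$replicon &
                       .overlaps(x$start, x$end, feat$start, feat$end))

    assigned <- NA_character_
    if (has_tss && !tss_is_mrna && !over_feat) {
      assigned <- "intergenic"
    } else if (has_tss && over_anti && !over_sense) {
      assigned <- "antisense"
    } else if (has_tss && tss_is_mrna) {
      # 5' UTR-derived: shares the TSS with an mRNA and ends before the
      # coding start of that gene
      gids <- unique(cls_tab$gene[cls_tab$id %in% near_tss$id &
                                    cls_tab$class %in%
                                      c("primary", "secondary")])
      host <- genes[genes$id %in% gids, , drop = FALSE]
      before_start <- nrow(host) > 0L && any(
        ifelse(host$strand == "+", p3 < host$start, p3 > host$end))
      if (before_start) assigned <- "utr5_derived"
    }
    if (is.na(assigned) && (has_tss || has_ps5)) {
      # 3' UTR-derived: 5' end within a gene's 3' UTR, 3' end shared with
      # the mRNA's terminator or a processing site
      same_g <- genes[genes$replicon == x$replicon &
                        genes$strand == x$strand, , drop = FALSE]
      in_utr3 <- nrow(same_g) > 0L && any(
        ifelse(same_g$strand == "+",
               p5 > same_g$end & p5 <= same_g$end + utr3_len,
               p5 < same_g$start & p5 >= same_g$start - utr3_len))
      if (in_utr3 && (has_term3 || has_ps3)) assigned <- "utr3_derived"
    }
    if (is.na(assigned) && (has_tss || has_ps5) && !is.null(op_tab)) {
      in_op <- any(op_tab$replicon == x$replicon &
                     op_tab$strand == x$strand &
                     op_tab$start <= x$start & op_tab$end >= x$end)
      # the candidate's 3' boundary itself evidences the coverage drop
      if (in_op) assigned <- "intra_operonic"
    }
    if (is.na(assigned)) {
      reasons[[i]] <- "unclassifiable"
    } else {
      res$class[i] <- assigned
      res$tss_support[i] <- if (has_tss) tss_id else "processing_site"
    }
  }
  res$id <- sprintf("srna_%s_%d%s", res$replicon, res$start,
                    ifelse(res$strand == "+", "f", "r"))
  res$rejection_reasons <- reasons
  res <- res[, c("id", "replicon", "start", "end", "strand", "length",
                 "class", "tss_support", "rejection_reasons")]
  class(res) <- c("srna_records", "data.frame")
  res
}

#' Curate classified sRNA candidates
#'
#' Applies the exclusion rules used for manual curation of automated sRNA
#' predictions: (1) no promoter (TSS) or processing site up to `window` bp
#' upstream of the 5' end; (2) complete overlap with an annotated mRNA on
#' the same strand; (3) complete overlap with an annotated terminator;
#' (4) overlap with supplied cis-regulatory elements (applied only when
#' `cis_elements` is given); (5) no evident coverage change relative to
#' flanking regions (inside/flank mean ratio below `cov_change_min`).
#' Accepted records must additionally have length within
#' `length_range` and a normalized folding-proxy energy below
#' `energy_threshold`. Every rejection lists all violated rules.
#'
#' @param records `srna_records` from [classify_srnas()]
#' @param tss_records detected `tss_records`
#' @param processing_sites data.frame of processing sites
#' @param genes gene data.frame
#' @param terminators terminator data.frame
#' @param coverage a `coverage_set` (for rule 5)
#' @param genome a `genome_bundle` (for the folding proxy)
#' @param window upstream search window for rule 1 (bp)
#' @param cis_elements optional data.frame (`replicon`, `start`, `end`,
#'   `strand`) of riboswitches/thermometers for rule 4
#' @param cov_change_min minimum inside/flank coverage fold change (rule 5)
#' @param length_range accepted length bounds (nt)
#' @param energy_threshold normalized folding-proxy threshold
#' @return list with `accepted` and `rejected` (`srna_records`; rejected
#'   rows carry their reasons); both carry `folding_energy` and
#'   `normalized_folding_energy`
#' @export
curate_srnas <- function(records, tss_records, processing_sites, genes,
                         terminators, coverage, genome, window = 50,
                         cis_elements = NULL, cov_change_min = 2,
                         length_range = c(30, 500),
                         energy_threshold = -0.05) {
  n <- nrow(records)
  energy <- numeric(n)
  norm_energy <- numeric(n)
  reasons <- records$rejection_reasons
  for (i in seq_len(n)) {
    x <- records[i, ]
    p5 <- .five_prime(x$start, x$end, x$strand)
    # rule 1: promoter or processing site within `window` bp upstream
    if (x$strand == "+") {
      up_lo <- p5 - window
      up_hi <- p5
    } else {
      up_lo <- p5
      up_hi <- p5 + window
    }
    has_prom <- nrow(tss_records) > 0L &&
      any(tss_records$replicon == x$replicon &
            tss_records$strand == x$strand &
            tss_records$pos >= up_lo & tss_records$pos <= up_hi)
    has_ps <- nrow(processing_sites) > 0L &&
      any(processing_sites$replicon == x$replicon &
            processing_sites$strand == x$strand &
            processing_sites$pos >= up_lo & processing_sites$pos <= up_hi)
    if (!has_prom && !has_ps)
      reasons[[i]] <- c(reasons[[i]], "no_promoter_or_processing_site")
    # rule 2: complete overlap with an annotated mRNA (same strand)
    inside_mrna <- any(genes$replicon == x$replicon &
                         genes$strand == x$strand &
                         genes$start <= x$start & genes$end >= x$end)
    if (inside_mrna) reasons[[i]] <- c(reasons[[i]], "inside_mrna")
    # rule 3: complete overlap with an annotated terminator
    inside_term <- nrow(terminators) > 0L &&
      any(terminators$replicon == x$replicon &
            terminators$strand == x$strand &
            terminators$start <= x$start & terminators$end >= x$end)
    if (inside_term) reasons[[i]] <- c(reasons[[i]], "inside_terminator")
    # rule 4: cis-regulatory element overlap, only when supplied
    if (!is.null(cis_elements) && nrow(cis_elements) > 0L) {
      hit <- any(cis_elements$replicon == x$replicon &
                   .overlaps(x$start, x$end, cis_elements$start,
                             cis_elements$end))
      if (hit) reasons[[i]] <- c(reasons[[i]], "cis_regulatory_overlap")
    }
    # rule 5: no evident coverage change relative to flanking regions
    v <- cov_track(coverage, x$replicon, "tex_minus", x$strand, "cov")
    inside <- .win_mean(v, x$start, x$end)
    flank <- mean(c(.win_mean(v, x$start - window, x$start - 1L),
                    .win_mean(v, x$end + 1L, x$end + window)), na.rm = TRUE)
    if (is.nan(flank)) flank <- 0
    if (inside < cov_change_min * max(flank, 1))
      reasons[[i]] <- c(reasons[[i]], "no_coverage_change")
    # stability and length acceptance filters
    len <- x$end - x$start + 1L
    if (len < length_range[1L] || len > length_range[2L])
      reasons[[i]] <- c(reasons[[i]], "length_out_of_range")
    seq <- substr(genome$replicons[[x$replicon]], x$start, x$end)
    if (x$strand == "-") seq <- revcomp(seq)
    fe <- folding_energy(seq)
    energy[i] <- fe$energy
    norm_energy[i] <- fe$normalized
    if (!(fe$normalized < energy_threshold))
      reasons[[i]] <- c(reasons[[i]], "unstable_structure")
  }
  records$folding_energy <- energy
  records$normalized_folding_energy <- norm_energy
  records$rejection_reasons <- reasons
  ok <- vapply(reasons, length, integer(1L)) == 0L
  list(accepted = records[ok, , drop = FALSE],
       rejected = records[!ok, , drop = FALSE])
}

#' Correlate antisense RNAs with their cognate operons
#'
#' For every antisense sRNA the cognate operon is the opposite-strand
#' operon its interval overlaps. The Pearson correlation between the
#' asRNA's z-scored CPM profile and the mean member-gene z-profile is
#' reported and labelled anti-correlated (r < -0.5), correlated (r > 0.5)
#' or neutral. Pairs absent from the matrix are skipped with a note;
#' zero-variance profiles are labelled neutral and flagged.
#'
#' @param asrna_records `srna_records` (antisense class)
#' @param operons list from [assemble_operons()] (with spans)
#' @param expression an `expr_matrix` containing asRNA and gene rows
#' @return data.frame: `asrna`, `operon`, `r`, `label`, `note`
#' @export
pair_asrna_with_targets <- function(asrna_records, operons, expression) {
  z <- zscore_profiles(expression, collapse = "sample")
  zv <- attr(z, "zero_variance")
  out <- list()
  op_tab <- operon_table(operons)
  for (i in seq_len(nrow(asrna_records))) {
    a <- asrna_records[i, ]
    sel <- op_tab$replicon == a$replicon & op_tab$strand != a$strand &
      op_tab$start <= a$end & op_tab$end >= a$start
    if (!any(sel)) next
    for (j in which(sel)) {
      members <- strsplit(op_tab$genes[j], ";", fixed = TRUE)[[1L]]
      if (!(a$id %in% rownames(z)) || !any(members %in% rownames(z))) {
        out[[length(out) + 1L]] <- data.frame(
          asrna = a$id, operon = op_tab$id[j], r = NA_real_,
          label = NA_character_, note = "absent_from_matrix",
          stringsAsFactors = FALSE)
        next
      }
      members <- intersect(members, rownames(z))
      if (a$id %in% zv || all(members %in% zv)) {
        out[[length(out) + 1L]] <- data.frame(
          asrna = a$id, operon = op_tab$id[j], r = NA_real_,
          label = "neutral", note = "zero_variance",
          stringsAsFactors = FALSE)
        next
      }
      prof <- colMeans(z[setdiff(members, zv), , drop = FALSE])
      r <- stats::cor(z[a$id, ], prof)
      label <- if (is.na(r)) "neutral"
               else if (r < -0.5) "anti_correlated"
               else if (r > 0.5) "correlated" else "neutral"
      out[[length(out) + 1L]] <- data.frame(
        asrna = a$id, operon = op_tab$id[j], r = r, label = label,
        note = "", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(asrna = character(), operon = character(),
                      r = numeric(), label = character(), note = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
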