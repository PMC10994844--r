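# Intrinsic (rho-independent) terminator prediction by two heuristics:
# a hairpin scan (GC-rich stem + short loop + U-rich tail) and a coverage
# drop between adjacent genes. The two evidence types are emitted with
# method labels and never merged.

#' @noRd
.code_seq <- function(s) {
  chartr("ACGT", "1234", s)
}

# stem pairing: Watson-Crick plus G.U wobble (RNA context)
#' @noRd
.pair_ok_mat <- local({
  m <- matrix(FALSE, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

#' Scan a sequence for hairpin (rho-independent) terminators
#'
#' Reports loci where a stem of `s` base pairs (allowing up to
#' `max_stem_mismatches` non-complementary pairs; G.U wobble counts as a
#' match), a loop within `loop_range`, and a downstream run of at least
#' `min_u_tail` U/T starting within 8 nt of the stem co-occur. The score is
#' (matched pairs - mismatches) + U-tail length. Overlapping hits are
#' reduced to the maximum-score hit.
#'
#' @param sequence character scalar, the replicon sequence (DNA alphabet)
#' @param strand `"+"` scans the sequence as given; `"-"` scans the reverse
#'   complement and reports coordinates on the given sequence
#' @param stem_range integer vector of stem lengths (pairs), within 4..30
#' @param loop_range integer vector of loop lengths (nt), within 3..10
#' @param max_stem_mismatches allowed non-complementary stem positions
#' @param min_u_tail minimum U/T run length
#' @param replicon replicon name for the output records
#' @return data.frame: `replicon`, `start`, `end`, `strand`,
#'   `method = "hairpin"`, `score`, `u_tail_length`
#' @export
find_hairpin_terminators <- function(sequence, strand = "+",
                                     stem_range = 5:12, loop_range = 3:8,
                                     max_stem_mismatches = 1,
                                     min_u_tail = 4, replicon = "chr") {
  .assert(all(stem_range >= 4 & stem_range <= 30),
          "stem_range must lie within [4, 30]")
  .assert(all(loop_range >= 3 & loop_range <= 10),
          "loop_range must lie within [3, 10]")
  seq <- toupper(sequence)
  L <- nchar(seq)
  scan_seq <- if (strand == "+") seq else revcomp(seq)
  chars <- strsplit(scan_seq, "", fixed = TRUE)[[1L]]
  is_t <- chars == "T"
  # t_run[i]: length of the T run starting at i
  t_run <- integer(L)
  run <- 0L
  for (i in rev(seq_len(L))) {
    run <- if (is_t[i]) run + 1L else 0L
    t_run[i] <- run
  }
  hits <- list()
  for (s in stem_range) {
    for (l in loop_range) {
      span <- 2L * s + l
      n <- L - span + 1L
      if (n < 1L) next
      idx <- seq_len(n)
      mism <- integer(n)
      for (k in seq_len(s)) {
        a <- chars[idx + k - 1L]
        b <- chars[idx + span - k]
        ok <- .pair_ok_mat[cbind(match(a, c("A", "C", "G", "T")),
                                 match(b, c("A", "C", "G", "T")))]
        ok[is.na(ok)] <- FALSE
        mism <- mism + !ok
      }
      cand <- which(mism <= max_stem_mismatches)
      if (length(cand) == 0L) next
      stem_end <- cand + span - 1L
      u_len <- integer(length(cand))
      for (d in 1:8) {
        p <- stem_end + d
        v <- ifelse(p <= L, t_run[pmin(p, L)], 0L)
        u_len <- pmax(u_len, v)
      }
      sel <- u_len >= min_u_tail
      if (!any(sel)) next
      hits[[length(hits) + 1L]] <- data.frame(
        scan_start = cand[sel], scan_end = stem_end[sel],
        score = (s - mism[cand[sel]]) - mism[cand[sel]] + u_len[sel],
        u_tail_length = u_len[sel], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      method = character(), score = numeric(),
                      u_tail_length = integer(), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  # reduce overlapping hits to the maximum score (tie: leftmost, shortest)
  h <- h[order(h$scan_start, h$scan_end), , drop = FALSE]
  keep <- logical(nrow(h))
  grp_end <- -1L
  grp_idx <- integer(0L)
  flush <- function(grp_idx) {
    if (length(grp_idx) == 0L) return()
    best <- grp_idx[order(-h$score[grp_idx], h$scan_start[grp_idx],
                          h$scan_end[grp_idx])][1L]
    keep[best] <<- TRUE
  }
  for (i in seq_len(nrow(h))) {
    if (h$scan_start[i] > grp_end) {
      flush(grp_idx)
      grp_idx <- i
      grp_end <- h$scan_end[i]
    } else {
      grp_idx <- c(grp_idx, i)
      grp_end <- max(grp_end, h$scan_end[i])
    }
  }
  flush(grp_idx)
  h <- h[keep, , drop = FALSE]
  if (strand == "+") {
    start <- h$scan_start
    end <- h$scan_end
  } else {
    start <- L - h$scan_end + 1L
    end <- L - h$scan_start + 1L
  }
  out <- data.frame(replicon = replicon, start = start, end = end,
                    strand = strand, method = "hairpin", score = h$score,
                    u_tail_length = h$u_tail_length,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Predict terminators from inter-genic coverage drops
#'
#' For every same-strand adjacent gene pair the intergenic span is scanned
#' for the position maximizing `1 - downstream/upstream` mean coverage over
#' `window` bp (orientation follows the strand of transcription). Positions
#' reaching `min_drop` with upstream support of at least `min_upstream_cov`
#' are reported; the score is the drop ratio.
#'
#' @param coverage a `coverage_set` (the untreated, TEX- full coverage is
#'   used)
#' @param genes gene data.frame
#' @param window averaging window (bp)
#' @param min_drop minimum drop fraction in (0, 1)
#' @param min_upstream_cov minimum upstream mean coverage (reads)
#' @return data.frame like [find_hairpin_terminators()] with
#'   `method = "coverage_drop"`
#' @export
find_coverage_drop_terminators <- function(coverage, genes, window = 50,
                                           min_drop = 0.5,
                                           min_upstream_cov = 10) {
  .assert(min_drop > 0 && min_drop < 1, "min_drop must lie in (0, 1)")
  out <- list()
  for (rep in unique(genes$replicon)) {
    for (strand in c("+", "-")) {
      g <- genes[genes$replicon == rep & genes$strand == strand, ,
                 drop = FALSE]
      if (nrow(g) < 1L) next
      g <- g[order(g$start), , drop = FALSE]
      v <- cov_track(coverage, rep, "tex_minus", strand, "cov")
      L <- length(v)
      # inter-genic spans plus the boundary spans flanking the first and
      # last gene of the strand
      spans <- list(c(1L, g$start[1L] - 1L),
                    c(g$end[nrow(g)] + 1L, L))
      for (i in seq_len(nrow(g) - 1L))
        spans[[length(spans) + 1L]] <- c(g$end[i] + 1L,
                                         g$start[i + 1L] - 1L)
      for (sp in spans) {
        lo <- sp[1L]
        hi <- sp[2L]
        if (hi < lo) next
        span <- lo:hi
        if (strand == "+") {
          up <- vapply(span, function(p) .win_mean(v, p - window, p - 1L),
                       numeric(1L))
          dn <- vapply(span, function(p) .win_mean(v, p, p + window - 1L),
                       numeric(1L))
        } else {
          up <- vapply(span, function(p) .win_mean(v, p + 1L, p + window),
                       numeric(1L))
          dn <- vapply(span, function(p) .win_mean(v, p - window + 1L, p),
                       numeric(1L))
        }
        ok <- !is.na(up) & !is.na(dn) & up >= min_upstream_cov
        if (!any(ok)) next
        drop <- ifelse(ok, 1 - dn / up, -Inf)
        # the reported position is chosen by the absolute coverage loss,
        # which pins the call to the main cliff instead of the low-coverage
        # read-through tail; the drop ratio remains score and threshold
        abs_drop <- ifelse(ok & drop >= min_drop, up - dn, -Inf)
        if (!any(is.finite(abs_drop))) next
        j <- which.max(abs_drop)
        if (drop[j] >= min_drop) {
          out[[length(out) + 1L]] <- data.frame(
            replicon = rep, start = span[j], end = span[j], strand = strand,
            method = "coverage_drop", score = drop[j],
            u_tail_length = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      method = character(), score = numeric(),
                      u_tail_length = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
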