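#' Detect TSS candidates from TEX+/TEX- 5'-end enrichment
#'
#' A position is a candidate when its TEX+ 5'-start count reaches
#' `min_height` and the enrichment over the untreated library (with a
#' pseudocount on the TEX- height) reaches `min_enrichment`. Candidates
#' within `cluster_window` bp of each other on the same strand are merged,
#' keeping the highest TEX+ height (ties resolved to the most upstream
#' position in transcription orientation).
#'
#' @param coverage a `coverage_set`
#' @param min_height minimum TEX+ start count (reads)
#' @param min_enrichment minimum TEX+/TEX- ratio
#' @param cluster_window merge window (bp)
#' @param pseudocount added floor for the TEX- height in the ratio
#' @return data.frame of class `tss_records`: `replicon`, `pos`, `strand`,
#'   `tex_plus_height`, `tex_minus_height`, `enrichment`, plus an empty
#'   `classes` list-column, sorted by replicon and position
#' @export
detect_tss <- function(coverage, min_height = 10, min_enrichment = 2,
                       cluster_window = 3, pseudocount = 1) {
  .assert(min_height >= 1, "min_height must be >= 1")
  .assert(min_enrichment > 1, "min_enrichment must be > 1")
  out <- list()
  for (rep in names(coverage$lengths)) {
    for (strand in c("+", "-")) {
      tp <- cov_track(coverage, rep, "tex_plus", strand, "starts")
      tm <- cov_track(coverage, rep, "tex_minus", strand, "starts")
      enr <- tp / pmax(tm, pseudocount)
      idx <- which(tp >= min_height & enr >= min_enrichment)
      if (length(idx) == 0L) next
      # chain-merge candidates separated by <= cluster_window
      grp <- cumsum(c(1L, diff(idx) > cluster_window))
      keep <- vapply(split(idx, grp), function(pp) {
        h <- tp[pp]
        best <- pp[h == max(h)]
        # most upstream: smallest coordinate on +, largest on -
        if (strand == "+") min(best) else max(best)
      }, integer(1L))
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep, pos = unname(keep), strand = strand,
        tex_plus_height = tp[keep], tex_minus_height = tm[keep],
        enrichment = enr[keep], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0L) {
    data.frame(replicon = character(), pos = integer(), strand = character(),
               tex_plus_height = numeric(), tex_minus_height = numeric(),
               enrichment = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  res <- res[order(res$replicon, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res$id <- if (nrow(res) > 0L)
    sprintf("TSS_%s_%d%s", res$replicon, res$pos,
            ifelse(res$strand == "+", "f", "r")) else character(0L)
  res$classes <- replicate(nrow(res), list(), simplify = FALSE)
  class(res) <- c("tss_records", "data.frame")
  res
}

#' Classify TSS candidates against gene annotation
#'
#' Implements the positional scheme used for dRNA-seq maps: per gene, among
#' same-strand candidates within the `upstream_window` upstream of the gene
#' start, the one with the highest enrichment is primary (tie broken to the
#' candidate closest to the gene start) and all others secondary; sense
#' candidates inside a gene body are internal; antisense candidates
#' overlapping a gene extended by `antisense_flank` on both sides are
#' antisense; candidates acquiring no class are orphan. One candidate may
#' hold several classes with respect to different genes.
#'
#' @param candidates `tss_records` from [detect_tss()]
#' @param genes gene data.frame (`id`, `replicon`, `start`, `end`, `strand`)
#' @param upstream_window bp upstream of a gene start searched for its
#'   primary TSS; the window is the `upstream_window` positions immediately
#'   upstream of the start coordinate
#' @param antisense_flank bp added to each side of a gene for the antisense
#'   test
#' @return the candidates with the `classes` list-column filled: each
#'   element is a data.frame with columns `class` and `gene`; also adds
#'   `divergent_primary` flagging TSSs primary for more than one gene
#' @export
classify_tss <- function(candidates, genes, upstream_window = 300,
                         antisense_flank = 100) {
  .assert(all(c("pos", "strand", "enrichment") %in% names(candidates)),
          "candidates must carry pos, strand and enrichment")
  .assert(!any(is.na(genes$strand)) && .strand_ok(genes$strand),
          "every gene needs a '+'/'-' strand")
  n <- nrow(candidates)
  cls <- replicate(n, data.frame(class = character(), gene = character(),
                                 stringsAsFactors = FALSE),
                   simplify = FALSE)
  add <- function(i, class, gene) {
    cls[[i]] <<- rbind(cls[[i]],
                       data.frame(class = class, gene = gene,
                                  stringsAsFactors = FALSE))
  }
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    same_rep <- candidates$replicon == gene$replicon
    sense <- same_rep & candidates$strand == gene$strand
    anti <- same_rep & candidates$strand != gene$strand
    if (gene$strand == "+") {
      win_lo <- gene$start - upstream_window
      win_hi <- gene$start - 1L
    } else {
      win_lo <- gene$end + 1L
      win_hi <- gene$end + upstream_window
    }
    in_win <- which(sense & candidates$pos >= win_lo &
                      candidates$pos <= win_hi)
    if (length(in_win) > 0L) {
      enr <- candidates$enrichment[in_win]
      best <- in_win[enr == max(enr)]
      if (length(best) > 1L) {
        d <- if (gene$strand == "+") gene$start - candidates$pos[best]
             else candidates$pos[best] - gene$end
        best <- best[which.min(d)]
      }
      add(best, "primary", gene$id)
      for (i in setdiff(in_win, best)) add(i, "secondary", gene$id)
    }
    inside <- which(sense & candidates$pos >= gene$start &
                      candidates$pos <= gene$end)
    for (i in inside) add(i, "internal", gene$id)
    as_hit <- which(anti & candidates$pos >= gene$start - antisense_flank &
                      candidates$pos <= gene$end + antisense_flank)
    for (i in as_hit) add(i, "antisense", gene$id)
  }
  for (i in seq_len(n)) {
    if (nrow(cls[[i]]) == 0L)
      cls[[i]] <- data.frame(class = "orphan", gene = NA_character_,
                             stringsAsFactors = FALSE)
  }
  candidates$classes <- cls
  candidates$divergent_primary <- vapply(cls, function(d)
    sum(d$class == "primary") > 1L, logical(1L))
  class(candidates) <- c("tss_records", "data.frame")
  candidates
}

#' Long-format view of TSS classes
#' @param tss classified `tss_records`
#' @return data.frame with one row per (TSS, class, gene)
#' @export
tss_classes_table <- function(tss) {
  if (nrow(tss) == 0L)
    return(data.frame(id = character(), replicon = character(),
                      pos = integer(), strand = character(),
                      class = character(), gene = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(tss)), function(i) {
    d <- tss$classes[[i]]
    data.frame(id = tss$id[i], replicon = tss$replicon[i], pos = tss$pos[i],
               strand = tss$strand[i], class = d$class, gene = d$gene,
               stringsAsFactors = FALSE)
  }))
}

#' Compare two TSS sets by greedy positional matching
#'
#' Positions on the same replicon and strand are matched greedily to the
#' nearest unmatched partner within `tolerance` bp.
#'
#' @param set_a,set_b data.frames with `replicon`, `pos`, `strand`
#' @param tolerance maximum distance (bp) for two TSSs to be the same
#' @return list with `shared`, `unique_to_a`, `unique_to_b` counts
#' @export
compare_tss_sets <- function(set_a, set_b, tolerance = 3) {
  shared <- 0L
  for (rep in union(set_a$replicon, set_b$replicon)) {
    for (strand in c("+", "-")) {
      a <- sort(set_a$pos[set_a$replicon == rep & set_a$strand == strand])
      b <- sort(set_b$pos[set_b$replicon == rep & set_b$strand == strand])
      used <- logical(length(b))
      for (p in a) {
        if (length(b) == 0L) break
        d <- abs(b - p)
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) == 1L && is.finite(d[j]) && d[j] <= tolerance) {
          used[j] <- TRUE
          shared <- shared + 1L
        }
      }
    }
  }
  list(shared = shared,
       unique_to_a = nrow(set_a) - shared,
       unique_to_b = nrow(set_b) - shared)
}
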