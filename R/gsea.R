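# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov-style running
# sum with a gene-label permutation null and Benjamini-Hochberg FDR across
# sets.

# ES from the positions of set members in the ranking; w holds |score| at
# those positions. Piecewise-linear deviation extremes occur at member
# positions and just before the next member.
#' @noRd
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  o <- order(pos)
  pos <- pos[o]
  w <- w[o]
  W <- sum(w)
  if (W <= 0) w <- rep(1, k)  # all-zero scores: fall back to unweighted
  W <- sum(w)
  cw <- cumsum(w) / W
  miss_den <- N - k
  j <- seq_len(k)
  d_after <- cw - (pos - j) / miss_den
  d_before <- c(0, cw[-k]) - (pos - 1 - (j - 1)) / miss_den
  d <- c(d_after, d_before)
  d[which.max(abs(d))]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted running-sum enrichment score (hit increments
#' proportional to |score|) for every gene set against a ranked gene list,
#' with a gene-label permutation null: member positions are resampled
#' uniformly from the ranking and the two-sided permutation p-value is the
#' fraction of permutations with |ES| at least as large as observed. FDR is
#' Benjamini-Hochberg across sets. Sets with fewer than `min_size` members
#' present in the ranking are dropped unless exempted.
#'
#' @param ranking data.frame from [rank_metric()] (`gene`, `score`), or any
#'   two-column equivalent, ordered by decreasing score
#' @param gene_sets named list of member vectors (see [read_gmt()])
#' @param n_perm permutations per set (>= 100)
#' @param min_size minimum members present in the ranking
#' @param exempt_sets set names kept regardless of size
#' @param seed RNG seed for the permutations
#' @return data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `pvalue`, `fdr`; dropped-member notes in the `"notes"` attribute
#' @export
preranked_gsea <- function(ranking, gene_sets, n_perm = 10000,
                           min_size = 10, exempt_sets = character(0L),
                           seed = 1) {
  .assert(n_perm >= 100, "n_perm < 100 gives unstable p-values")
  .assert(all(c("gene", "score") %in% names(ranking)),
          "ranking needs columns gene and score")
  ranking <- ranking[order(-ranking$score, ranking$gene), , drop = FALSE]
  genes <- ranking$gene
  absw <- abs(ranking$score)
  N <- length(genes)
  idx <- stats::setNames(seq_len(N), genes)
  notes <- character(0L)
  rows <- list()
  with_seed(seed, {
    for (nm in names(gene_sets)) {
      members <- unique(gene_sets[[nm]])
      present <- members[members %in% genes]
      if (length(present) < length(members))
        notes <- c(notes, sprintf("%s: %d member(s) absent from ranking",
                                  nm, length(members) - length(present)))
      k <- length(present)
      if (k == 0L || k >= N) next
      if (k < min_size && !(nm %in% exempt_sets)) next
      pos <- unname(idx[present])
      es <- .es_from_positions(pos, absw[pos], N)
      perm <- vapply(seq_len(n_perm), function(b) {
        pp <- sample.int(N, k)
        .es_from_positions(pp, absw[pp], N)
      }, numeric(1L))
      p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, size = k, es = es, pvalue = p, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows) == 0L)
    data.frame(set = character(), size = integer(), es = numeric(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  attr(out, "notes") <- notes
  class(out) <- c("enrichment_result", "data.frame")
  out
}
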