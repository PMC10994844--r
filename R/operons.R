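#' Assemble operons and sub-operons
#'
#' Consecutive same-strand genes are joined into one operon when the
#' intergenic gap is at most `max_gap`, the minimum intergenic coverage
#' (untreated full coverage) is at least `min_joining_cov`, and no
#' same-strand terminator lies between them. The operon lead TSS is the
#' primary TSS of the first gene when present. Every primary or secondary
#' TSS assigned to a non-first member opens a sub-operon reaching from that
#' member to the operon end.
#'
#' @param genes gene data.frame
#' @param tss_records classified `tss_records` (see [classify_tss()])
#' @param terminators terminator data.frame (both methods may be mixed)
#' @param coverage a `coverage_set`
#' @param max_gap maximum intergenic gap (bp)
#' @param min_joining_cov minimum intergenic coverage to join (reads)
#' @return list of operon records: `id`, `replicon`, `strand`, `genes`
#'   (ids in transcription order), `span` (c(start, end)), `lead_tss`,
#'   `terminator`, `sub_operons` (list of `list(tss, genes)`)
#' @export
assemble_operons <- function(genes, tss_records, terminators, coverage,
                             max_gap = 300, min_joining_cov = 5) {
  cls_tab <- tss_classes_table(tss_records)
  primary_of <- function(gid) {
    hit <- cls_tab[cls_tab$class == "primary" & !is.na(cls_tab$gene) &
                     cls_tab$gene == gid, , drop = FALSE]
    if (nrow(hit) > 0L) hit$id[1L] else NA_character_
  }
  tss_of <- function(gid, classes) {
    hit <- cls_tab[cls_tab$class %in% classes & !is.na(cls_tab$gene) &
                     cls_tab$gene == gid, , drop = FALSE]
    if (nrow(hit) > 0L) hit$id else character(0L)
  }
  operons <- list()
  for (rep in unique(genes$replicon)) {
    for (strand in c("+", "-")) {
      g <- genes[genes$replicon == rep & genes$strand == strand, ,
                 drop = FALSE]
      if (nrow(g) == 0L) next
      if (is.unsorted(g$start))
        g <- g[order(g$start), , drop = FALSE]
      v <- cov_track(coverage, rep, "tex_minus", strand, "cov")
      term <- terminators[terminators$replicon == rep &
                            terminators$strand == strand, , drop = FALSE]
      joined <- logical(max(nrow(g) - 1L, 0L))
      for (i in seq_len(nrow(g) - 1L)) {
        lo <- g$end[i] + 1L
        hi <- g$start[i + 1L] - 1L
        gap <- hi - lo + 1L
        if (gap > max_gap) next
        min_cov <- if (gap <= 0L) Inf else min(v[lo:hi])
        if (min_cov < min_joining_cov) next
        term_between <- nrow(term) > 0L &&
          any(term$start <= hi & term$end >= lo)
        if (term_between) next
        joined[i] <- TRUE
      }
      blocks <- split(seq_len(nrow(g)),
                      cumsum(c(1L, as.integer(!joined))))
      for (b in blocks) {
        members <- g[b, , drop = FALSE]
        # transcription order: leftmost first on +, rightmost first on -
        ord <- if (strand == "+") order(members$start)
               else order(-members$start)
        members <- members[ord, , drop = FALSE]
        span <- c(min(members$start), max(members$end))
        lead <- primary_of(members$id[1L])
        # terminal terminator: nearest same-strand terminator just
        # downstream of the operon end (within max_gap)
        if (strand == "+") {
          cand <- term[term$start >= span[2L] &
                         term$start <= span[2L] + max_gap, , drop = FALSE]
          tid <- if (nrow(cand) > 0L)
            cand[which.min(cand$start), , drop = FALSE] else NULL
        } else {
          cand <- term[term$end <= span[1L] &
                         term$end >= span[1L] - max_gap, , drop = FALSE]
          tid <- if (nrow(cand) > 0L)
            cand[which.max(cand$end), , drop = FALSE] else NULL
        }
        term_id <- if (is.null(tid)) NA_character_ else
          sprintf("term_%s_%d_%s", tid$replicon, tid$start, tid$method)
        subs <- list()
        if (nrow(members) > 1L) {
          for (k in 2:nrow(members)) {
            # one sub-operon per member at most (primary preferred)
            ids <- tss_of(members$id[k], c("primary", "secondary"))
            if (length(ids) > 0L) {
              subs[[length(subs) + 1L]] <-
                list(tss = ids[1L], genes = members$id[k:nrow(members)])
            }
          }
        }
        operons[[length(operons) + 1L]] <- list(
          id = sprintf("op_%s_%d", rep, span[1L]),
          replicon = rep, strand = strand, genes = members$id,
          span = span, lead_tss = lead, terminator = term_id,
          sub_operons = subs)
      }
    }
  }
  operons
}

#' Flat table view of operons
#' @param operons list from [assemble_operons()]
#' @return data.frame with one row per operon
#' @export
operon_table <- function(operons) {
  if (length(operons) == 0L)
    return(data.frame(id = character(), replicon = character(),
                      strand = character(), n_genes = integer(),
                      genes = character(), start = integer(),
                      end = integer(), lead_tss = character(),
                      terminator = character(), n_sub_operons = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(operons, function(o) data.frame(
    id = o$id, replicon = o$replicon, strand = o$strand,
    n_genes = length(o$genes), genes = paste(o$genes, collapse = ";"),
    start = o$span[1L], end = o$span[2L], lead_tss = o$lead_tss,
    terminator = o$terminator, n_sub_operons = length(o$sub_operons),
    stringsAsFactors = FALSE)))
}
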