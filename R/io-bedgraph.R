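# bedGraph tracks are written one file per library x strand x track type,
# 0-based half-open on disk (bedGraph convention) and converted to the
# package's dense 1-based vectors at this boundary.

#' @noRd
.bg_file_name <- function(prefix, library, strand, type) {
  sprintf("%s_%s_%s_%s.bedgraph", prefix,
          ifelse(library == "tex_plus", "TEXplus", "TEXminus"),
          ifelse(strand == "+", "fwd", "rev"), type)
}

#' Write a coverage set as bedGraph files
#'
#' Eight files are produced under `dir`: one per library (TEX+/TEX-),
#' strand and track type (`starts`/`cov`). Zero runs are omitted; the track
#' line names library and strand.
#'
#' @param cs a `coverage_set`
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_bedgraph <- function(cs, dir, prefix = "coverage") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0L)
  for (library in c("tex_plus", "tex_minus")) {
    for (strand in c("+", "-")) {
      for (type in c("starts", "cov")) {
        path <- file.path(dir, .bg_file_name(prefix, library, strand, type))
        con <- file(path, "w")
        writeLines(sprintf(
          "track type=bedGraph name=\"%s %s %s\"",
          ifelse(library == "tex_plus", "TEX+", "TEX-"), strand, type), con)
        for (rep in names(cs$lengths)) {
          v <- cov_track(cs, rep, library, strand, type)
          r <- rle(v)
          ends <- cumsum(r$lengths)
          starts0 <- ends - r$lengths          # 0-based half-open starts
          keep <- r$values != 0L
          if (any(keep)) {
            writeLines(sprintf("%s\t%d\t%d\t%d", rep, starts0[keep],
                               ends[keep], r$values[keep]), con)
          }
        }
        close(con)
        paths <- c(paths, path)
      }
    }
  }
  invisible(paths)
}

#' @noRd
.read_bedgraph_file <- function(path, replicon_lengths) {
  .assert(file.exists(path), "no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(replicon_lengths, function(L) integer(L))
  if (length(gr) == 0L) return(out)
  missing <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                     names(replicon_lengths))
  .assert(length(missing) == 0L, path, ": interval on undeclared replicon: ",
          paste(missing, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  .assert(length(hits) == 0L,
          path, ": overlapping bedGraph intervals are ambiguous")
  df <- as.data.frame(gr)
  for (rep in unique(as.character(df$seqnames))) {
    sub <- df[df$seqnames == rep, , drop = FALSE]
    .assert(all(sub$end <= replicon_lengths[[rep]]),
            path, ": interval beyond length of replicon ", rep)
    .assert(all(sub$score >= 0), path, ": negative coverage value")
    v <- out[[rep]]
    for (i in seq_len(nrow(sub)))
      v[sub$start[i]:sub$end[i]] <- as.integer(round(sub$score[i]))
    out[[rep]] <- v
  }
  out
}

#' Read bedGraph files into a coverage set
#'
#' Expects the file layout of [write_bedgraph()]. Intervals beyond the
#' replicon length and overlapping intervals raise errors.
#'
#' @param dir directory holding the bedGraph files
#' @param replicon_lengths named vector of replicon lengths
#' @param prefix file-name prefix used at write time
#' @return a `coverage_set`
#' @export
read_bedgraph <- function(dir, replicon_lengths, prefix = "coverage") {
  cs <- coverage_set(replicon_lengths)
  for (library in c("tex_plus", "tex_minus")) {
    for (strand in c("+", "-")) {
      for (type in c("starts", "cov")) {
        path <- file.path(dir, .bg_file_name(prefix, library, strand, type))
        vecs <- .read_bedgraph_file(path, replicon_lengths)
        for (rep in names(vecs))
          cov_track(cs, rep, library, strand, type) <- vecs[[rep]]
      }
    }
  }
  cs
}
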