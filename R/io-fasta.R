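#' Read a FASTA file of replicon sequences
#'
#' Sequences are upper-cased on read; if any lowercase letters were present
#' this is recorded in the `"lowercased"` attribute. Duplicate headers and
#' non-IUPAC characters raise a parse error carrying the offending line
#' number.
#'
#' @param path FASTA file
#' @return named character vector of sequences, with attribute
#'   `lowercased` (logical)
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(lines) > 0L && length(hdr) == 0L && any(nzchar(lines)))
    stop("not FASTA (no '>' header): ", path, call. = FALSE)
  nms <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(nms)) {
    dup <- nms[duplicated(nms)][1L]
    at <- hdr[nms == dup][2L]
    stop("duplicate FASTA header '", dup, "' at line ", at, call. = FALSE)
  }
  seq_lines <- setdiff(seq_along(lines), hdr)
  bad <- seq_lines[grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv.\\-]",
                         lines[seq_lines])]
  if (length(bad) > 0L)
    stop("non-IUPAC character in FASTA at line ", bad[1L], call. = FALSE)
  if (length(hdr) == 0L) {
    out <- stats::setNames(character(0L), character(0L))
    attr(out, "lowercased") <- FALSE
    return(out)
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("^\\s*(\\S+).*$", "\\1", names(set))
  had_lower <- any(grepl("[a-z]", lines[seq_lines]))
  seqs <- toupper(seqs)
  attr(seqs, "lowercased") <- had_lower
  seqs
}

#' Write replicon sequences to FASTA
#' @param replicons named character vector of sequences
#' @param path output file
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(replicons, path, width = 70L) {
  .assert(length(replicons) == 0L || !is.null(names(replicons)),
          "replicons must be named")
  .assert(!anyDuplicated(names(replicons)), "duplicate replicon names")
  set <- Biostrings::DNAStringSet(toupper(replicons))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
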