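#' Construct a genome bundle
#'
#' A genome bundle holds replicon sequences together with gene features on
#' 1-based inclusive coordinates (GFF3 convention) and provenance metadata.
#'
#' @param replicons named character vector, one uppercase nucleotide
#'   sequence per replicon
#' @param genes data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `strand`, `biotype`
#' @param provenance optional list (source files, checksums, notes)
#' @return object of class `genome_bundle`
#' @export
genome_bundle <- function(replicons, genes = NULL, provenance = list()) {
  .assert(is.character(replicons), "replicons must be a character vector")
  .assert(length(replicons) == 0L || !is.null(names(replicons)),
          "replicons must be named")
  .assert(!anyDuplicated(names(replicons)), "duplicate replicon names")
  replicons <- toupper(replicons)
  if (is.null(genes)) {
    genes <- data.frame(id = character(), replicon = character(),
                        start = integer(), end = integer(),
                        strand = character(), biotype = character(),
                        stringsAsFactors = FALSE)
  }
  need <- c("id", "replicon", "start", "end", "strand", "biotype")
  .assert(all(need %in% names(genes)),
          "genes must have columns: ", paste(need, collapse = ", "))
  if (nrow(genes) > 0L) {
    .assert(!anyDuplicated(genes$id), "gene ids must be unique")
    .assert(.strand_ok(genes$strand), "gene strand must be '+' or '-'")
    .assert(all(genes$replicon %in% names(replicons)),
            "gene on undeclared replicon: ",
            paste(setdiff(genes$replicon, names(replicons)), collapse = ", "))
    len <- nchar(replicons)[genes$replicon]
    .assert(all(genes$start >= 1L & genes$start <= genes$end &
                  genes$end <= len),
            "gene coordinates must satisfy 1 <= start <= end <= replicon length")
  }
  structure(list(replicons = replicons, genes = genes,
                 provenance = provenance),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$replicons), "replicon(s),",
      nrow(x$genes), "gene(s)\n")
  for (nm in names(x$replicons))
    cat("  ", nm, ": ", nchar(x$replicons[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' @noRd
.replicon_lengths <- function(genome) {
  stats::setNames(nchar(genome$replicons), names(genome$replicons))
}

#' Construct an empty coverage set
#'
#' A coverage set stores, per replicon, strand and library (TEX-treated
#' `tex_plus`, untreated `tex_minus`), two position-indexed integer vectors:
#' `starts` (5'-end read starts) and `cov` (full read coverage).
#'
#' @param replicon_lengths named integer vector of replicon lengths
#' @return object of class `coverage_set` with all-zero tracks
#' @export
coverage_set <- function(replicon_lengths) {
  .assert(is.numeric(replicon_lengths) && !is.null(names(replicon_lengths)),
          "replicon_lengths must be a named numeric vector")
  tracks <- lapply(replicon_lengths, function(L) {
    z <- integer(L)
    list(
      tex_plus = list(`+` = list(starts = z, cov = z),
                      `-` = list(starts = z, cov = z)),
      tex_minus = list(`+` = list(starts = z, cov = z),
                       `-` = list(starts = z, cov = z))
    )
  })
  structure(list(tracks = tracks,
                 lengths = stats::setNames(as.integer(replicon_lengths),
                                           names(replicon_lengths))),
            class = "coverage_set")
}

#' Extract one coverage track
#' @param cs a `coverage_set`
#' @param replicon replicon name
#' @param library `"tex_plus"` or `"tex_minus"`
#' @param strand `"+"` or `"-"`
#' @param type `"starts"` or `"cov"`
#' @return integer vector of per-position values
#' @export
cov_track <- function(cs, replicon, library = c("tex_minus", "tex_plus"),
                      strand = c("+", "-"), type = c("cov", "starts")) {
  library <- match.arg(library)
  strand <- match.arg(strand)
  type <- match.arg(type)
  .assert(replicon %in% names(cs$tracks), "unknown replicon: ", replicon)
  cs$tracks[[replicon]][[library]][[strand]][[type]]
}

#' Replace one coverage track
#' @inheritParams cov_track
#' @param value integer vector of replicon length, all values >= 0
#' @return the modified `coverage_set`
#' @export
`cov_track<-` <- function(cs, replicon, library, strand, type, value) {
  .assert(length(value) == cs$lengths[[replicon]],
          "track length must equal replicon length")
  .assert(all(value >= 0), "coverage values must be >= 0")
  cs$tracks[[replicon]][[library]][[strand]][[type]] <- as.integer(value)
  cs
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("coverage_set:", length(x$lengths), "replicon(s):",
      paste(sprintf("%s (%d bp)", names(x$lengths), x$lengths),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' Gene-by-sample non-negative integer counts with a sample-to-condition
#' map. Library sizes default to column sums.
#'
#' @param counts integer matrix, genes in rows (rownames), samples in
#'   columns (colnames)
#' @param conditions named character vector mapping sample to condition
#' @param lib_sizes optional named numeric vector of library sizes
#' @return object of class `expr_matrix`
#' @export
expr_matrix <- function(counts, conditions, lib_sizes = NULL) {
  .assert(is.matrix(counts) && !is.null(rownames(counts)) &&
            !is.null(colnames(counts)), "counts must be a named matrix")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(all(colnames(counts) %in% names(conditions)),
          "every sample needs a condition")
  conditions <- conditions[colnames(counts)]
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  .assert(all(lib_sizes > 0), "library sizes must be > 0")
  lib_sizes <- lib_sizes[colnames(counts)]
  structure(list(counts = counts, conditions = conditions,
                 lib_sizes = lib_sizes),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", length(unique(x$conditions)), "condition(s)\n")
  invisible(x)
}

#' Construct a fitness table
#'
#' Per sRNA-by-experiment fitness entries from pooled transposon-mutant
#' competitions: `fit` is the average log2 change in relative mutant
#' abundance, `t` its moderated t-like statistic, and `success` whether the
#' experiment passed the barcode-count quality bar.
#'
#' @param entries data.frame with columns `srna`, `experiment`, `fit`, `t`,
#'   `success`
#' @return object of class `fitness_table` (a validated data.frame)
#' @export
fitness_table <- function(entries) {
  need <- c("srna", "experiment", "fit", "t", "success")
  .assert(all(need %in% names(entries)),
          "fitness table needs columns: ", paste(need, collapse = ", "))
  .assert(is.logical(entries$success), "success must be logical")
  .assert(all(is.finite(entries$t[entries$success])),
          "t must be finite for successful experiments")
  class(entries) <- c("fitness_table", "data.frame")
  entries
}

#' @noRd
.empty_truth <- function(seed = NA_integer_) {
  structure(list(
    seed = seed,
    tss = data.frame(replicon = character(), pos = integer(),
                     strand = character(), kind = character(),
                     stringsAsFactors = FALSE),
    terminators = data.frame(replicon = character(), pos = integer(),
                             strand = character(), stringsAsFactors = FALSE),
    srnas = data.frame(id = character(), replicon = character(),
                       start = integer(), end = integer(),
                       strand = character(), class = character(),
                       stringsAsFactors = FALSE),
    irs = data.frame(replicon = character(), left_start = integer(),
                     left_end = integer(), right_start = integer(),
                     right_end = integer(), arm_length = integer(),
                     mismatches = integer(), spacer_length = integer(),
                     homopolymeric = logical(), stringsAsFactors = FALSE),
    processing_sites = data.frame(replicon = character(), pos = integer(),
                                  strand = character(),
                                  stringsAsFactors = FALSE),
    units = data.frame(replicon = character(), start = integer(),
                       end = integer(), strand = character(),
                       level = numeric(), tss = integer(),
                       terminator = integer(), stringsAsFactors = FALSE),
    operons = list(),
    de = numeric(),
    regulons = list(),
    fitness_hits = data.frame(srna = character(), experiment = character(),
                              fit = numeric(), t = numeric(),
                              success = logical(), stringsAsFactors = FALSE)
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set (seed ", x$seed, "): ", nrow(x$tss), " TSS, ",
      nrow(x$terminators), " terminators, ", nrow(x$srnas), " sRNAs, ",
      nrow(x$irs), " IRs, ", length(x$operons), " operons\n", sep = "")
  invisible(x)
}
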