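#' @noRd
.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed so independent generators fed from one
# master seed do not share RNG streams. Kept below 2^31 - 1.
#' @noRd
.child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + stream * 12347L) %% 2147483587L
}

#' Reverse complement of a DNA string (ACGTN, case-insensitive)
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", U = "A")
    out <- comp[chars]
    out[is.na(out)] <- "N"
    paste0(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' @noRd
.strand_ok <- function(s) all(s %in% c("+", "-"))

# Mean of a coverage window clipped to the vector bounds; NA when the
# clipped window is empty.
#' @noRd
.win_mean <- function(v, from, to) {
  from <- max(1L, from)
  to <- min(length(v), to)
  if (from > to) return(NA_real_)
  mean(v[from:to])
}

#' @noRd
.file_checksums <- function(paths) {
  paths <- paths[file.exists(paths) & !dir.exists(paths)]
  if (length(paths) == 0L) return(character(0L))
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}
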