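# Invertible-repeat (inverton) discovery: genome-wide inverted-repeat
# scanning under length-dependent mismatch budgets (no mismatches for arms
# up to 11 bp, one for 12-19 bp, two above 19 bp), composition filters and
# promoter-window integration with the TSS map.

#' @noRd
.ir_finalize <- function(df, sequence, replicon) {
  if (nrow(df) == 0L) {
    return(data.frame(
      replicon = character(), left_start = integer(), left_end = integer(),
      right_start = integer(), right_end = integer(), arm_length = integer(),
      mismatches = integer(), spacer_length = integer(),
      gc_fraction = numeric(), homopolymeric = logical(),
      promoter_flag = logical(), tss_ids = character(),
      stringsAsFactors = FALSE))
  }
  left_start <- df$left0 + 1L
  left_end <- left_start + df$arm - 1L
  right_start <- left_end + df$spacer + 1L
  right_end <- right_start + df$arm - 1L
  arms <- paste0(substr(rep(sequence, nrow(df)), left_start, left_end),
                 substr(rep(sequence, nrow(df)), right_start, right_end))
  gc <- vapply(arms, function(a) {
    ch <- strsplit(a, "", fixed = TRUE)[[1L]]
    mean(ch %in% c("G", "C"))
  }, numeric(1L), USE.NAMES = FALSE)
  homo <- vapply(seq_len(nrow(df)), function(i) {
    la <- substr(sequence, left_start[i], left_end[i])
    ra <- substr(sequence, right_start[i], right_end[i])
    one_letter <- function(s) {
      ch <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
      length(ch) == 1L
    }
    one_letter(la) && one_letter(ra)
  }, logical(1L))
  out <- data.frame(
    replicon = replicon, left_start = left_start, left_end = left_end,
    right_start = right_start, right_end = right_end,
    arm_length = df$arm, mismatches = df$mismatches,
    spacer_length = df$spacer, gc_fraction = gc, homopolymeric = homo,
    promoter_flag = NA, tss_ids = NA_character_, stringsAsFactors = FALSE)
  out[order(out$left_start, out$right_start), , drop = FALSE]
}

# containment suppression: a hit is removed when both of its arms are
# contained in another hit's arms that has at most as many mismatches
#' @noRd
.ir_suppress <- function(df) {
  n <- nrow(df)
  if (n < 2L) return(df)
  le <- df$left0 + df$arm - 1L          # left arm end, 0-based
  r0 <- df$left0 + df$arm + df$spacer   # right arm start, 0-based
  re <- r0 + df$arm - 1L
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    contained <- df$left0 >= df$left0[i] & le <= le[i] &
      r0 >= r0[i] & re <= re[i] & df$mismatches >= df$mismatches[i]
    contained[i] <- FALSE
    keep[contained] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Find inverted repeats under length-dependent mismatch budgets
#'
#' Reports all maximal arm pairs with arm length within
#' `[arm_min, arm_max]`, spacer within `[spacer_min, spacer_max]`, and a
#' mismatch count within the length-dependent budget (0 for arms up to
#' 11 bp, 1 for 12-19 bp, 2 above 19 bp). A hit contained in another hit
#' with at most as many mismatches is suppressed as non-maximal.
#'
#' @param sequence character scalar (DNA)
#' @param arm_min,arm_max arm length bounds (bp); `arm_min` must be >= 5
#' @param spacer_min,spacer_max spacer length bounds (bp)
#' @param replicon replicon name for the output records
#' @return data.frame: `replicon`, `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_length`, `mismatches`, `spacer_length`,
#'   `gc_fraction` (over both arms), `homopolymeric`, `promoter_flag`
#'   (unset), `tss_ids`
#' @export
find_inverted_repeats <- function(sequence, arm_min = 12, arm_max = 25,
                                  spacer_min = 30, spacer_max = 1000,
                                  replicon = "chr") {
  .assert(arm_min >= 5, "arm_min must be >= 5")
  .assert(arm_max >= arm_min, "arm_max must be >= arm_min")
  .assert(spacer_min >= 0 && spacer_max >= spacer_min,
          "invalid spacer range")
  seq <- toupper(sequence)
  raw <- .ir_scan_cpp(seq, as.integer(arm_min), as.integer(arm_max),
                      as.integer(spacer_min), as.integer(spacer_max))
  raw <- .ir_suppress(raw)
  .ir_finalize(raw, seq, replicon)
}

#' Brute-force inverted-repeat enumeration (reference oracle)
#'
#' Enumerates every (left start, arm length, spacer) triple and checks the
#' right arm against the reverse complement of the left arm by direct
#' character comparison, then filters by the same length-dependent budgets
#' and suppresses contained hits. Exists to validate
#' [find_inverted_repeats()]; quadratic bookkeeping, use on short
#' sequences.
#'
#' @inheritParams find_inverted_repeats
#' @return data.frame in the same layout as [find_inverted_repeats()]
#' @export
ir_brute_force <- function(sequence, arm_min = 12, arm_max = 25,
                           spacer_min = 30, spacer_max = 1000,
                           replicon = "chr") {
  seq <- toupper(sequence)
  raw <- .ir_enum_cpp(seq, as.integer(arm_min), as.integer(arm_max),
                      as.integer(spacer_min), as.integer(spacer_max))
  # independent containment filter, written pairwise
  n <- nrow(raw)
  if (n > 1L) {
    ls <- raw$left0
    le <- raw$left0 + raw$arm - 1L
    rs <- raw$left0 + raw$arm + raw$spacer
    re <- rs + raw$arm - 1L
    suppressed <- vapply(seq_len(n), function(i) {
      any(ls <= ls[i] & le >= le[i] & rs <= rs[i] & re >= re[i] &
            raw$mismatches <= raw$mismatches[i] &
            !(ls == ls[i] & le == le[i] & rs == rs[i] & re == re[i]))
    }, logical(1L))
    raw <- raw[!suppressed, , drop = FALSE]
  }
  .ir_finalize(raw, seq, replicon)
}

#' Filter inverted repeats by composition
#'
#' Removes homopolymeric repeats (both arms a single repeated nucleotide)
#' and repeats whose GC fraction over both arms lies outside
#' `[gc_min, gc_max]`; survivors pass unchanged.
#'
#' @param hits data.frame from [find_inverted_repeats()]
#' @param gc_min,gc_max GC-fraction bounds
#' @param drop_homopolymeric remove homopolymeric repeats
#' @return the filtered data.frame
#' @export
filter_inverted_repeats <- function(hits, gc_min = 0.15, gc_max = 0.85,
                                    drop_homopolymeric = TRUE) {
  keep <- hits$gc_fraction >= gc_min & hits$gc_fraction <= gc_max
  if (drop_homopolymeric) keep <- keep & !hits$homopolymeric
  hits[keep, , drop = FALSE]
}

#' Flag inverted repeats containing potential promoters
#'
#' An inverted repeat is flagged when any of its arms or its spacer
#' intersects the `window`-bp region immediately upstream (strand-aware by
#' default) of any mapped TSS; the supporting TSS ids are recorded.
#'
#' @param hits data.frame from [find_inverted_repeats()]
#' @param tss_records `tss_records` (classified or not)
#' @param window upstream promoter window (bp)
#' @param strand_aware when `FALSE` the window is taken on both sides of
#'   each TSS
#' @return `hits` with `promoter_flag` and `tss_ids` filled
#' @export
flag_promoter_invertons <- function(hits, tss_records, window = 50,
                                    strand_aware = TRUE) {
  if (nrow(hits) == 0L) return(hits)
  hits$promoter_flag <- FALSE
  hits$tss_ids <- ""
  if (nrow(tss_records) == 0L) return(hits)
  win_lo <- ifelse(tss_records$strand == "+",
                   tss_records$pos - window, tss_records$pos + 1L)
  win_hi <- ifelse(tss_records$strand == "+",
                   tss_records$pos - 1L, tss_records$pos + window)
  if (!strand_aware) {
    win_lo <- tss_records$pos - window
    win_hi <- tss_records$pos + window
  }
  for (i in seq_len(nrow(hits))) {
    span_lo <- hits$left_start[i]
    span_hi <- hits$right_end[i]
    sel <- tss_records$replicon == hits$replicon[i] &
      win_lo <= span_hi & win_hi >= span_lo
    if (any(sel)) {
      hits$promoter_flag[i] <- TRUE
      hits$tss_ids[i] <- paste(tss_records$id[sel], collapse = ";")
    }
  }
  hits
}
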