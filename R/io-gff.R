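#' Read features from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive (the in-memory convention of the
#' whole package). `ID` and `Name` attributes are preserved; the GFF `type`
#' column becomes `biotype`. Features on replicons absent from
#' `replicon_lengths` (when supplied) raise an error naming the replicon.
#'
#' @param path GFF3 file (must start with a `##gff-version` pragma)
#' @param replicon_lengths optional named vector used for referential checks
#' @return data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `strand`, `biotype`, `name`, plus any extra attribute columns
#' @export
read_gff3 <- function(path, replicon_lengths = NULL) {
  .assert(file.exists(path), "no such file: ", path)
  first <- readLines(path, n = 1L)
  .assert(length(first) == 1L && grepl("^##gff-version", first),
          "missing ##gff-version pragma: ", path)
  # locate malformed coordinate rows before handing off to the importer so
  # the error carries a line number
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.integer(f[4L]))
      e <- suppressWarnings(as.integer(f[5L]))
      if (!is.na(s) && !is.na(e) && e < s)
        stop("GFF3 parse error at line ", i, ": end < start", call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if (all(is.na(id)) && length(gr) > 0L)
    id <- sprintf("feat%05d", seq_along(gr))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else NA_character_
  out <- data.frame(
    id = id,
    replicon = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    biotype = as.character(df$type),
    name = nm, stringsAsFactors = FALSE)
  extra <- setdiff(names(md), c("source", "type", "score", "phase",
                                "ID", "Name"))
  for (col in extra) {
    v <- md[[col]]
    if (is(v, "List")) v <- vapply(v, paste, character(1L), collapse = ",")
    out[[col]] <- as.vector(v)
  }
  if (!is.null(replicon_lengths)) {
    missing <- setdiff(out$replicon, names(replicon_lengths))
    .assert(length(missing) == 0L,
            "feature on undeclared replicon: ",
            paste(missing, collapse = ", "))
    over <- out$end > replicon_lengths[out$replicon]
    .assert(!any(over), "feature beyond replicon end on: ",
            paste(unique(out$replicon[over]), collapse = ", "))
  }
  out
}

#' Write features to GFF3
#'
#' @param features data.frame with columns `replicon`, `start`, `end`,
#'   `strand`, `biotype` (GFF type) and `id`; any further columns are
#'   written as GFF3 attributes
#' @param path output file
#' @param source GFF source column
#' @return `path`, invisibly
#' @export
write_gff3 <- function(features, path, source = "bactatlas") {
  need <- c("replicon", "start", "end", "strand", "biotype", "id")
  .assert(all(need %in% names(features)),
          "features must have columns: ", paste(need, collapse = ", "))
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  .assert(all(features$end >= features$start), "end < start in features")
  gr <- GenomicRanges::GRanges(
    seqnames = features$replicon,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  md <- S4Vectors::DataFrame(source = source, type = features$biotype,
                             ID = features$id)
  extra <- setdiff(names(features), c(need, "name"))
  if ("name" %in% names(features)) md$Name <- features$name
  for (col in extra) md[[col]] <- features[[col]]
  S4Vectors::mcols(gr) <- md
  # codon phase is not modelled here; silence the exporter's reminder
  withCallingHandlers(
    rtracklayer::export(gr, path, format = "gff3"),
    warning = function(w) {
      if (grepl("phase information", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}
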