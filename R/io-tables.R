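#' Read gene sets from a GMT file
#'
#' Tab-delimited, one set per line: name, description, members. An empty
#' set name or a set defined twice is an error; duplicate members within a
#' set are de-duplicated with a warning.
#'
#' @param path GMT file
#' @return named list of character vectors of member genes
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[`, character(1L), 1L)
  .assert(all(nzchar(nms) & !is.na(nms)), "empty gene-set name in ", path)
  if (anyDuplicated(nms))
    stop("gene set defined twice: ", nms[duplicated(nms)][1L], call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  names(sets) <- nms
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) {
      warning("duplicate members in gene set '", nm, "' de-duplicated",
              call. = FALSE)
      sets[[nm]] <- unique(sets[[nm]])
    }
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output file
#' @param descriptions optional character vector of descriptions
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  .assert(!is.null(names(sets)) && all(nzchar(names(sets))),
          "all sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix and its condition map
#'
#' @param counts_path TSV with a `gene` column and one column per sample
#' @param conditions_path TSV with columns `sample`, `condition`
#' @return an `expr_matrix`
#' @export
read_counts_tsv <- function(counts_path, conditions_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  .assert("gene" %in% names(tab), "counts TSV needs a 'gene' column")
  m <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  rownames(m) <- tab$gene
  cond <- utils::read.delim(conditions_path, stringsAsFactors = FALSE)
  .assert(all(c("sample", "condition") %in% names(cond)),
          "condition TSV needs columns 'sample' and 'condition'")
  expr_matrix(m, stats::setNames(cond$condition, cond$sample))
}

#' Write a count matrix and its condition map
#' @param x an `expr_matrix`
#' @param counts_path,conditions_path output TSV paths
#' @return invisibly, the two paths
#' @export
write_counts_tsv <- function(x, counts_path, conditions_path) {
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cond <- data.frame(sample = names(x$conditions),
                     condition = unname(x$conditions))
  utils::write.table(cond, conditions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, conditions_path))
}

#' Read a fitness table TSV
#'
#' Expects columns `srna`, `experiment`, `fit`, `t`, `success`.
#' @param path TSV file
#' @return a `fitness_table`
#' @export
read_fitness_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("srna", "experiment", "fit", "t", "success")
  .assert(all(need %in% names(tab)),
          "fitness TSV needs columns: ", paste(need, collapse = ", "))
  tab$success <- as.logical(tab$success)
  fitness_table(tab)
}

#' Write a fitness table TSV
#' @param ft a `fitness_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fitness_tsv <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Accepts externally computed DE tables (for example from an edgeR fit) so
#' the package's significance thresholds can be applied to them verbatim.
#' @param path TSV with columns `gene`, `log2fc`, `pvalue`, `fdr`
#' @return data.frame of class `de_result`
#' @export
read_de_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "fdr")
  .assert(all(need %in% names(tab)),
          "DE TSV needs columns: ", paste(need, collapse = ", "))
  class(tab) <- c("de_result", "data.frame")
  tab
}

#' Write inverted repeats as blocked BED
#'
#' One BED12 record per arm pair: the record spans left-arm start to
#' right-arm end with the two arms as blocks, 0-based half-open on disk.
#'
#' @param hits inverted-repeat data.frame (see [find_inverted_repeats()])
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_inverton_bed <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    chromStart <- h$left_start - 1L            # to 0-based
    chromEnd <- h$right_end
    blockSizes <- paste0(h$arm_length, ",", h$arm_length)
    blockStarts <- paste0(0L, ",", h$right_start - h$left_start)
    paste(h$replicon, chromStart, chromEnd,
          sprintf("IR_%s_%d", h$replicon, h$left_start),
          h$mismatches, "+", chromStart, chromEnd, "0,0,0", 2L,
          blockSizes, blockStarts, sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write any record table as TSV
#' @param x data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_records_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]]))
      x[[col]] <- vapply(x[[col]], function(v)
        paste(unlist(v), collapse = ";"), character(1L))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
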