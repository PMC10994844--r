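# Integration layer: co-expression of genes against gene sets, fitness
# phenotype categorization of sRNA mutants, expression-aware mutant
# prioritization and the one-site binding-curve fit.

#' Z-scored CPM expression profiles
#'
#' Per gene, `(CPM - mean) / sd` across samples, or across condition means
#' (replicates averaged) when `collapse = "condition_mean"`. Zero-variance
#' genes are kept in the matrix but flagged in the `"zero_variance"`
#' attribute and must be excluded from correlation analyses.
#'
#' @param x an `expr_matrix` (needs >= 3 samples)
#' @param collapse `"condition_mean"` (default) averages replicates per
#'   condition before z-scoring; `"sample"` z-scores per-sample profiles
#' @return matrix of z-scores with attribute `zero_variance` (gene ids)
#' @export
zscore_profiles <- function(x, collapse = c("condition_mean", "sample")) {
  collapse <- match.arg(collapse)
  v <- cpm(x)
  .assert(ncol(v) >= 3L, "need >= 3 samples")
  if (collapse == "condition_mean") {
    conds <- unique(x$conditions)
    v <- vapply(conds, function(cc) {
      rowMeans(v[, names(x$conditions)[x$conditions == cc], drop = FALSE])
    }, numeric(nrow(v)))
    colnames(v) <- conds
  }
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  zero <- rownames(v)[sdv == 0 | is.na(sdv)]
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- (v - mu) / sdv
  attr(z, "zero_variance") <- zero
  z
}

#' Median correlation of a query gene with each gene set
#'
#' For every gene set the median Pearson correlation between the query
#' gene's z-scored CPM profile and each member's profile is reported
#' (the query is excluded from its own sets; zero-variance members are
#' skipped). Sets with fewer than `min_set_size` usable members are
#' excluded. Sets with `|median r| > 0.5` are labelled.
#'
#' @param query gene id present in `profiles`
#' @param gene_sets named list of member vectors
#' @param profiles z-score matrix from [zscore_profiles()]
#' @param min_set_size minimum usable members per set
#' @return data.frame of class `coexpression_summary`: `set`, `median_r`,
#'   `n_members_used`, `labelled`
#' @export
gene_set_correlation <- function(query, gene_sets, profiles,
                                 min_set_size = 10) {
  .assert(query %in% rownames(profiles), "query gene absent: ", query)
  zv <- attr(profiles, "zero_variance")
  .assert(!(query %in% zv), "query gene has zero variance: ", query)
  q <- profiles[query, ]
  rows <- lapply(names(gene_sets), function(nm) {
    members <- setdiff(unique(gene_sets[[nm]]), query)
    members <- intersect(members, rownames(profiles))
    members <- setdiff(members, zv)
    if (length(members) < min_set_size) return(NULL)
    rs <- vapply(members, function(g) stats::cor(q, profiles[g, ]),
                 numeric(1L))
    data.frame(set = nm, median_r = stats::median(rs),
               n_members_used = length(members),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows) == 0L)
    data.frame(set = character(), median_r = numeric(),
               n_members_used = integer(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  out$labelled <- abs(out$median_r) > 0.5
  class(out) <- c("coexpression_summary", "data.frame")
  out
}

#' Categorize fitness phenotypes of sRNA mutants
#'
#' Thresholds applied per (sRNA, experiment) entry: significant when
#' `|t| > 4`, strong when `|fit| > 2` and `|t| > 5`, combined when both.
#' Entries from unsuccessful experiments receive no category. The summary
#' counts experiments per category per sRNA.
#'
#' @param table a `fitness_table`
#' @return list with `calls` (per-entry logical categories) and `summary`
#'   (per-sRNA counts `n_significant`, `n_strong`, `n_combined` and
#'   any-category flags)
#' @export
categorize_fitness <- function(table) {
  tab <- as.data.frame(table)
  ok <- tab$success
  significant <- ok & abs(tab$t) > 4
  strong <- ok & abs(tab$fit) > 2 & abs(tab$t) > 5
  combined <- significant & strong
  calls <- data.frame(srna = tab$srna, experiment = tab$experiment,
                      significant = significant, strong = strong,
                      combined = combined, stringsAsFactors = FALSE)
  agg <- function(v) tapply(v, tab$srna, sum)
  srnas <- sort(unique(tab$srna))
  summary <- data.frame(
    srna = srnas,
    n_significant = as.integer(agg(significant)[srnas]),
    n_strong = as.integer(agg(strong)[srnas]),
    n_combined = as.integer(agg(combined)[srnas]),
    stringsAsFactors = FALSE)
  summary$any_significant <- summary$n_significant > 0L
  summary$any_strong <- summary$n_strong > 0L
  summary$any_combined <- summary$n_combined > 0L
  mx <- tapply(ifelse(ok, abs(tab$fit), -Inf), tab$srna, max)
  summary$max_abs_fit <- as.numeric(mx[srnas])
  summary$max_abs_fit[!is.finite(summary$max_abs_fit)] <- NA_real_
  list(calls = calls, summary = summary)
}

#' Prioritize sRNA mutants by fitness evidence
#'
#' Orders sRNAs by the number of significant experiments (descending),
#' then maximum |fit| (descending), then id, and attaches expression
#' context (maximum CPM and the condition where it peaks). sRNAs absent
#' from the expression matrix are kept with a missing-context flag.
#'
#' @param summary per-sRNA summary from [categorize_fitness()]
#' @param expression an `expr_matrix` with sRNA rows
#' @return ranked data.frame with `rank`, expression context and
#'   `missing_expression` flag
#' @export
prioritize_srnas <- function(summary, expression) {
  v <- cpm(expression)
  out <- summary
  out$max_cpm <- NA_real_
  out$peak_condition <- NA_character_
  out$missing_expression <- !(out$srna %in% rownames(v))
  conds <- unique(expression$conditions)
  for (i in which(!out$missing_expression)) {
    prof <- vapply(conds, function(cc) {
      mean(v[out$srna[i],
             names(expression$conditions)[expression$conditions == cc]])
    }, numeric(1L))
    out$max_cpm[i] <- max(prof)
    out$peak_condition[i] <- conds[which.max(prof)]
  }
  mx <- ifelse(is.na(out$max_abs_fit), -Inf, out$max_abs_fit)
  ord <- order(-out$n_significant, -mx, out$srna)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit a one-site specific binding curve
#'
#' Least-squares fit of `Y = Bmax * X / (Kd + X)` (`X` ligand
#' concentration, `Y` specific binding). The default start takes
#' `Bmax = max(y)` and `Kd` as the concentration at half-maximal binding
#' by linear interpolation.
#'
#' @param x concentration series (>= 3 distinct positive values)
#' @param y response series (same length)
#' @param start optional named list/vector with `bmax` and `kd`
#' @return list of class `binding_fit`: `bmax`, `kd`, `rss`, `fitted`
#' @export
fit_binding_curve <- function(x, y, start = NULL) {
  .assert(length(x) == length(y), "x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  .assert(length(unique(x[x > 0])) >= 3L,
          ">= 3 distinct positive concentrations required")
  .assert(any(y != 0), "no binding signal: all responses are zero")
  if (is.null(start)) {
    bmax0 <- max(y)
    half <- bmax0 / 2
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    above <- which(ys >= half)
    kd0 <- if (length(above) == 0L) max(xs) else {
      j <- above[1L]
      if (j == 1L) xs[1L]
      else xs[j - 1L] + (half - ys[j - 1L]) * (xs[j] - xs[j - 1L]) /
        max(ys[j] - ys[j - 1L], 1e-12)
    }
    start <- list(bmax = bmax0, kd = max(kd0, min(x[x > 0])))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bmax * x / (kd + x),
                      start = list(bmax = start$bmax, kd = start$kd),
                      lower = c(bmax = 1e-12, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("binding-curve fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  structure(list(bmax = unname(est["bmax"]), kd = unname(est["kd"]),
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("one-site binding fit: Bmax = %.4g, Kd = %.4g (RSS %.3g)\n",
              x$bmax, x$kd, x$rss))
  invisible(x)
}
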