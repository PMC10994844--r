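# Conditional-expression analysis: CPM normalization, expressed-gene
# filtering, a common-dispersion negative-binomial differential test (a
# documented stand-in for a full tagwise GLM fit), significance calls and
# the preranked enrichment ranking metric.

#' Counts per million
#'
#' `CPM(g, s) = counts(g, s) / library_size(s) * 1e6`. Library sizes are
#' column sums unless supplied at construction.
#'
#' @param x an `expr_matrix`, or a counts matrix with `lib_sizes`
#' @param lib_sizes library sizes when `x` is a plain matrix
#' @return matrix of CPM values
#' @export
cpm <- function(x, lib_sizes = NULL) {
  if (inherits(x, "expr_matrix")) {
    counts <- x$counts
    lib_sizes <- x$lib_sizes
  } else {
    counts <- x
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  }
  .assert(all(lib_sizes > 0), "library sizes must be > 0")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Filter expressed genes by a CPM threshold
#'
#' Under the default scheme a gene is retained when there is at least one
#' condition in which every replicate exceeds `cpm_threshold` CPM; the
#' alternative scheme requires all samples to exceed it.
#'
#' @param x an `expr_matrix`
#' @param cpm_threshold CPM cutoff (default 0.6635, roughly ten reads in a
#'   15-million-read library)
#' @param scheme `"any_condition"` (default) or `"all_samples"`
#' @return character vector of retained gene ids
#' @export
filter_expressed <- function(x, cpm_threshold = 0.6635,
                             scheme = c("any_condition", "all_samples")) {
  scheme <- match.arg(scheme)
  v <- cpm(x)
  if (scheme == "all_samples") {
    keep <- rowSums(v > cpm_threshold) == ncol(v)
  } else {
    conds <- unique(x$conditions)
    keep_mat <- vapply(conds, function(cc) {
      cols <- names(x$conditions)[x$conditions == cc]
      rowSums(v[, cols, drop = FALSE] > cpm_threshold) == length(cols)
    }, logical(nrow(v)))
    keep <- rowSums(as.matrix(keep_mat)) > 0L
  }
  rownames(v)[keep]
}

# negative-binomial log-likelihood at per-sample means mu * s_j, common
# dispersion phi, vectorised over genes (rows of y)
#' @noRd
.nb_ll <- function(y, mu, s, phi) {
  # y: genes x samples matrix; mu: per-gene mean vector; s: size factors
  m <- outer(mu, s)
  if (phi < 1e-8) {
    rowSums(stats::dpois(y, pmax(m, 1e-10), log = TRUE))
  } else {
    size <- 1 / phi
    rowSums(stats::dnbinom(y, size = size, mu = pmax(m, 1e-10), log = TRUE))
  }
}

# maximum-likelihood per-gene NB mean under size factors; with equal size
# factors this is the sample mean, otherwise a few Newton steps on log mu
#' @noRd
.nb_mu_hat <- function(y, s, phi) {
  mu <- pmax(rowSums(y) / sum(s), 1e-8)
  if (max(abs(s - mean(s))) / mean(s) < 1e-12 || phi < 1e-8) return(mu)
  for (it in 1:5) {
    m <- outer(mu, s)
    w <- 1 + phi * m
    grad <- rowSums((y - m) / (mu * w))
    hess <- rowSums(-(y * phi * m + m) / (mu^2 * w^2)) # d2ll/dmu2 approx
    step <- grad / pmin(hess, -1e-12)
    mu <- pmax(mu - step, 1e-8)
  }
  mu
}

#' Estimate a common NB dispersion by method of moments
#'
#' Counts are scaled to a common library size; within each group the
#' excess of the per-gene variance over the mean is pooled across genes as
#' a ratio of sums, `sum(var - mean) / sum(mean^2)`, which is far less
#' noisy at small replicate numbers than averaging per-gene ratios.
#'
#' @param x an `expr_matrix`
#' @param groups optional character vector of conditions to use
#' @return non-negative dispersion estimate
#' @export
estimate_common_dispersion <- function(x, groups = NULL) {
  conds <- x$conditions
  if (!is.null(groups)) conds <- conds[conds %in% groups]
  sf <- x$lib_sizes / mean(x$lib_sizes)
  y <- sweep(x$counts[, names(conds), drop = FALSE], 2L,
             sf[names(conds)], "/")
  num <- 0
  den <- 0
  for (cc in unique(conds)) {
    cols <- names(conds)[conds == cc]
    if (length(cols) < 2L) next
    sub <- y[, cols, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    ok <- m >= 1
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Two-group negative-binomial differential expression test
#'
#' A likelihood-ratio test per gene between a two-mean and a common-mean
#' negative-binomial model with one common dispersion (estimated by method
#' of moments on the supplied matrix unless given). Log2 fold changes come
#' from mean CPM with a pseudocount; p-values from the chi-square(1)
#' approximation; FDR by Benjamini-Hochberg. This is a deliberately simple,
#' documented stand-in for a tagwise-dispersion GLM fit and also accepts
#' externally computed DE tables downstream (see [read_de_tsv()]).
#'
#' @param x an `expr_matrix`
#' @param contrast length-2 character vector `c(test, control)`
#' @param dispersion optional fixed common dispersion
#' @param pseudocount CPM pseudocount for the fold change
#' @return data.frame of class `de_result`: `gene`, `log2fc`, `pvalue`,
#'   `fdr`, with the contrast stored as an attribute
#' @export
nb_de_test <- function(x, contrast, dispersion = NULL, pseudocount = 0.5) {
  .assert(length(contrast) == 2L, "contrast must be c(test, control)")
  .assert(all(contrast %in% x$conditions),
          "contrast conditions absent from the matrix")
  cols_t <- names(x$conditions)[x$conditions == contrast[1L]]
  cols_c <- names(x$conditions)[x$conditions == contrast[2L]]
  .assert(length(cols_t) >= 2L && length(cols_c) >= 2L,
          "need >= 2 replicates per group")
  y <- x$counts[, c(cols_t, cols_c), drop = FALSE]
  .assert(any(y[, seq_along(cols_t)] > 0) &&
            any(y[, length(cols_t) + seq_along(cols_c)] > 0),
          "a group has all-zero counts for every gene")
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(x, groups = contrast)
  sf <- (x$lib_sizes / mean(x$lib_sizes[c(cols_t, cols_c)]))[
    c(cols_t, cols_c)]
  it <- seq_along(cols_t)
  ic <- length(cols_t) + seq_along(cols_c)
  mu_t <- .nb_mu_hat(y[, it, drop = FALSE], sf[it], dispersion)
  mu_c <- .nb_mu_hat(y[, ic, drop = FALSE], sf[ic], dispersion)
  mu_0 <- .nb_mu_hat(y, sf, dispersion)
  ll1 <- .nb_ll(y[, it, drop = FALSE], mu_t, sf[it], dispersion) +
    .nb_ll(y[, ic, drop = FALSE], mu_c, sf[ic], dispersion)
  ll0 <- .nb_ll(y, mu_0, sf, dispersion)
  lrt <- pmax(2 * (ll1 - ll0), 0)
  pvalue <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  v <- cpm(x)
  log2fc <- log2((rowMeans(v[, cols_t, drop = FALSE]) + pseudocount) /
                   (rowMeans(v[, cols_c, drop = FALSE]) + pseudocount))
  out <- data.frame(gene = rownames(y), log2fc = log2fc, pvalue = pvalue,
                    fdr = stats::p.adjust(pvalue, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "dispersion") <- dispersion
  class(out) <- c("de_result", "data.frame")
  out
}

#' Call significantly regulated genes
#'
#' Up means `log2fc > lfc_cut` and `fdr < fdr_cut`; down is symmetric;
#' everything else is neither.
#'
#' @param de a `de_result`
#' @param lfc_cut absolute log2 fold-change threshold
#' @param fdr_cut FDR threshold
#' @return the table with an added `call` column (`"up"`, `"down"`,
#'   `"neither"`)
#' @export
significant_de <- function(de, lfc_cut = 2, fdr_cut = 0.05) {
  call <- rep("neither", nrow(de))
  call[de$log2fc > lfc_cut & de$fdr < fdr_cut] <- "up"
  call[de$log2fc < -lfc_cut & de$fdr < fdr_cut] <- "down"
  de$call <- call
  de
}

#' Rank genes for preranked enrichment
#'
#' The ranking score is `-log10(p) * sign(log2fc)`. Zero p-values are
#' floored at the smallest representable double and flagged. Ties are
#' broken by gene id for determinism; genes are returned in descending
#' score order.
#'
#' @param de a `de_result`
#' @return data.frame: `gene`, `score`, `floored`, sorted by score
#' @export
rank_metric <- function(de) {
  p <- de$pvalue
  floored <- p <= 0 | p < .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  score <- -log10(p) * sign(de$log2fc)
  out <- data.frame(gene = de$gene, score = score, floored = floored,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}
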