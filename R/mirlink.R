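#' Fit a context-specific miRNA-mRNA interactome
#'
#' The central fitting function. Given paired miRNA and mRNA expression,
#' a two-group phenotype and target-prediction databases, it (1) annotates
#' every feature with two-group differential expression, (2) tests every
#' miRNA-mRNA pair for negative correlation (one-sided), with
#' multiple-testing control over the full pair family, and (3) intersects
#' the significant pairs with the databases, producing the combined
#' interaction table with the deregulation score.
#'
#' @param mirna miRNA log2 expression matrix (from [expression_matrix()] or
#'   [read_expression()]), or an aligned `mir_dataset` (then `mrna` and
#'   `pheno` are ignored).
#' @param mrna mRNA log2 expression matrix.
#' @param pheno two-group phenotype from [phenotype_table()].
#' @param databases list of [target_db()] objects; empty list stops the
#'   analysis after the correlation stage.
#' @param de_method differential-expression method.
#' @param cor_method correlation coefficient.
#' @param alpha significance threshold for the correlation test.
#' @param sig_on apply `alpha` to `"adj.pval"` (FDR, default) or `"pval"`.
#' @param adjust multiple-testing method for both DE and correlation.
#' @param min_dat_sum minimum number of databases supporting a pair.
#' @param trend mean-variance trend for the moderated t.
#' @param equal_var pooled variance for the t-test.
#' @param n_perm permutations for the rank-product test.
#' @param block_rows block size for the pair table assembly.
#' @return object of class `mirlink`: list with `dataset`, `de_mirna`,
#'   `de_mrna`, `pairs` (all-pairs table), `significant`, `combined`
#'   (`NULL` without databases), `databases`, `params`, `call`.
#' @seealso [summary.mirlink()], [build_network()], [run_pipeline()]
#' @examples
#' sim <- simulate_dataset(simulation_config(n_mirna = 20, n_mrna = 50,
#'   n_control = 10, n_case = 10, n_true_pairs = 10, seed = 7))
#' fit <- mirlink(sim$dataset, databases = sim$databases)
#' fit
#' @export
mirlink <- function(mirna, mrna = NULL, pheno = NULL, databases = list(),
                    de_method = c("modt", "ttest", "wilcoxon", "rankprod"),
                    cor_method = c("pearson", "spearman", "kendall"),
                    alpha = 0.05, sig_on = c("adj.pval", "pval"),
                    adjust = c("BH", "bonferroni"), min_dat_sum = 1L,
                    trend = FALSE, equal_var = FALSE, n_perm = 500L,
                    block_rows = 512L) {
  de_method <- match.arg(de_method)
  cor_method <- match.arg(cor_method)
  sig_on <- match.arg(sig_on)
  adjust <- match.arg(adjust)
  ds <- if (inherits(mirna, "mir_dataset")) mirna
        else align_dataset(mirna, mrna, pheno)
  run_de <- function(m) switch(de_method,
    modt = diffexp_modt(m, ds$pheno, trend = trend, adjust = adjust),
    ttest = diffexp_ttest(m, ds$pheno, equal_var = equal_var, adjust = adjust),
    wilcoxon = diffexp_wilcoxon(m, ds$pheno, adjust = adjust),
    rankprod = diffexp_rankprod(m, ds$pheno, n_perm = n_perm))
  de_mirna <- run_de(ds$mirna)
  de_mrna <- run_de(ds$mrna)
  pairs <- correlate_all(ds, method = cor_method, block_rows = block_rows,
                         adjust = adjust)
  sig <- significant_pairs(pairs, alpha = alpha, on = sig_on)
  combined <- NULL
  if (length(databases)) {
    combined <- intersect_with_targets(sig, de_mirna, de_mrna, databases,
                                       min_dat_sum = min_dat_sum)
  } else {
    message("no target databases supplied; stopping after the correlation stage")
  }
  structure(list(
    dataset = ds, de_mirna = de_mirna, de_mrna = de_mrna,
    pairs = pairs, significant = sig, combined = combined,
    databases = databases,
    params = list(de_method = de_method, cor_method = cor_method,
                  alpha = alpha, sig_on = sig_on, adjust = adjust,
                  min_dat_sum = min_dat_sum),
    call = match.call()
  ), class = "mirlink")
}

#' @export
print.mirlink <- function(x, ...) {
  cat("miRNA-mRNA interactome fit\n")
  cat("  dataset:     ", nrow(x$dataset$mirna), "miRNAs x",
      nrow(x$dataset$mrna), "mRNAs,", ncol(x$dataset$mirna), "samples\n")
  cat("  pairs tested:", format(nrow(x$pairs), big.mark = ","),
      sprintf("(%s, one-sided negative)\n", x$params$cor_method))
  cat(sprintf("  significant: %s (%s < %g)\n",
              format(nrow(x$significant), big.mark = ","),
              x$params$sig_on, x$params$alpha))
  if (!is.null(x$combined))
    cat("  interactions:", format(nrow(x$combined), big.mark = ","),
        sprintf("(supported by >= %d database(s))\n", x$params$min_dat_sum))
  else cat("  interactions: not computed (no databases)\n")
  invisible(x)
}

#' Summarise a fitted interactome
#'
#' Correlation-density summary, counts at the standard cutoffs, the
#' significant/predicted/overlap decomposition and the top interactions.
#'
#' @param object a `mirlink` fit.
#' @param n_top number of top interactions to carry.
#' @param ... unused.
#' @export
summary.mirlink <- function(object, n_top = 15L, ...) {
  n_pred <- NA_integer_
  if (length(object$databases)) {
    expressed <- intersect_with_targets(
      object$pairs, object$de_mirna, object$de_mrna, object$databases,
      min_dat_sum = 1L)
    n_pred <- nrow(expressed)
  }
  out <- list(
    dims = c(n_mirna = nrow(object$dataset$mirna),
             n_mrna = nrow(object$dataset$mrna),
             n_samples = ncol(object$dataset$mirna)),
    density = correlation_density_summary(object$pairs),
    n_pairs = nrow(object$pairs),
    n_significant = nrow(object$significant),
    n_predicted = n_pred,
    n_interactions = if (is.null(object$combined)) NA_integer_
                     else nrow(object$combined),
    top = if (is.null(object$combined)) NULL
          else top_interactions(object$combined, n = n_top),
    params = object$params
  )
  class(out) <- "summary.mirlink"
  out
}

#' @export
print.summary.mirlink <- function(x, ...) {
  cat("Interactome summary:", x$dims[["n_mirna"]], "miRNAs x",
      x$dims[["n_mrna"]], "mRNAs,", x$dims[["n_samples"]], "samples\n\n")
  print(x$density)
  cat("\nDecision rule (", x$params$sig_on, " < ", x$params$alpha,
      " and predicted in >= ", x$params$min_dat_sum, " database(s)):\n", sep = "")
  cat("  significant negative pairs:", format(x$n_significant, big.mark = ","), "\n")
  cat("  predicted pairs (any db):  ",
      if (is.na(x$n_predicted)) "n/a" else format(x$n_predicted, big.mark = ","), "\n")
  cat("  final interactions:        ",
      if (is.na(x$n_interactions)) "n/a" else format(x$n_interactions, big.mark = ","), "\n")
  if (!is.null(x$top) && nrow(x$top)) {
    cat("\nTop interactions:\n")
    print(utils::head(x$top[, c("miRNA", "mRNA", "cor", "adj.pval", "dat.sum",
                                "score")], 10), digits = 3)
  }
  invisible(x)
}

#' Plot the correlation coefficient distribution of a fit
#'
#' Density of the pair correlation coefficients with vertical lines at the
#' coefficient values corresponding to the standard significance cutoffs.
#'
#' @param x a `mirlink` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirlink <- function(x, ...) {
  d <- stats::density(x$pairs$cor, from = -1, to = 1)
  graphics::plot(d, main = "miRNA-mRNA correlation coefficients",
                 xlab = "correlation", ...)
  cuts <- list(c("pval", 0.05, "grey60"), c("pval", 0.01, "grey40"),
               c("adj.pval", 0.05, "red3"), c("adj.pval", 0.01, "red4"))
  for (cc in cuts) {
    sel <- x$pairs[[cc[[1]]]] < as.numeric(cc[[2]])
    if (any(sel))
      graphics::abline(v = max(x$pairs$cor[sel]), lty = 2, col = cc[[3]])
  }
  invisible(x)
}
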