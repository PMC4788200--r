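# Two-group differential expression. Every method reports the same four
# quantities per feature -- logratio (case minus control, log2 units), mean
# expression, p value, adjusted p value -- because downstream stages
# (interaction score, node colouring) consume exactly those. DE is an
# annotation here, never a filter: dropping features by DE before the
# correlation step risks false negatives when the control arm is small.

# canonical per-group column indices: sorted sample names within each group,
# so that results are invariant to the input column order
split_groups <- function(m, pheno) {
  miss <- setdiff(colnames(m), names(pheno))
  if (length(miss))
    stop("samples without phenotype assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ph <- pheno[colnames(m)]
  lv <- levels(ph)
  if (length(lv) != 2L) stop("phenotype must have exactly two levels")
  ctrl <- sort(colnames(m)[ph == lv[1L]])
  case <- sort(colnames(m)[ph == lv[2L]])
  if (length(ctrl) < 2L || length(case) < 2L)
    stop("need at least 2 samples per group (", lv[1L], "=", length(ctrl),
         ", ", lv[2L], "=", length(case), ")")
  list(ctrl = ctrl, case = case, levels = lv)
}

de_table <- function(m, grp, pval, method, adjust) {
  x0 <- m[, grp$ctrl, drop = FALSE]
  x1 <- m[, grp$case, drop = FALSE]
  out <- data.frame(
    feature = rownames(m),
    logratio = rowMeans(x1) - rowMeans(x0),
    meanExp = rowMeans(m[, c(grp$ctrl, grp$case), drop = FALSE]),
    pval = pval,
    adj.pval = adjust_pvalues(pval, adjust),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  out
}

#' Two-sample t-test per feature
#'
#' Welch by default (`equal_var = FALSE`) or pooled-variance t. Features
#' with zero variance in both groups get p = 1 when the group means are
#' equal and the smallest representable p otherwise, with a warning; the
#' reference distribution is undefined there and this keeps the output
#' total.
#'
#' @param m log2 expression matrix.
#' @param pheno phenotype factor from [phenotype_table()].
#' @param equal_var pool the within-group variances.
#' @param adjust multiple-testing method, see [adjust_pvalues()].
#' @return data.frame with columns `feature`, `logratio`, `meanExp`,
#'   `pval`, `adj.pval` (one row per feature, input order).
#' @export
diffexp_ttest <- function(m, pheno, equal_var = FALSE, adjust = c("BH", "bonferroni")) {
  grp <- split_groups(m, pheno)
  x0 <- m[, grp$ctrl, drop = FALSE]; n0 <- ncol(x0)
  x1 <- m[, grp$case, drop = FALSE]; n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  if (equal_var) {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep_len(n0 + n1 - 2, nrow(m))
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- se^4 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " feature(s) with zero variance in both groups; ",
            "p set to 1 (equal means) or the smallest representable value")
    p[degen] <- ifelse(m1[degen] == m0[degen], 1, .Machine$double.xmin)
  }
  de_table(m, grp, p, "ttest", match.arg(adjust))
}

#' Wilcoxon rank-sum test per feature
#'
#' Two-sided rank-sum p (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as in [stats::wilcox.test()]).
#' Effect summaries (`logratio`, `meanExp`) stay mean-based so all methods
#' report comparable columns. Fully tied features get p = 1.
#'
#' @inheritParams diffexp_ttest
#' @export
diffexp_wilcoxon <- function(m, pheno, adjust = c("BH", "bonferroni")) {
  grp <- split_groups(m, pheno)
  x0 <- m[, grp$ctrl, drop = FALSE]
  x1 <- m[, grp$case, drop = FALSE]
  p <- vapply(seq_len(nrow(m)), function(i) {
    pv <- tryCatch(
      suppressWarnings(stats::wilcox.test(x1[i, ], x0[i, ])$p.value),
      error = function(e) NA_real_)
    if (!is.finite(pv)) 1 else pv
  }, numeric(1))
  de_table(m, grp, p, "wilcoxon", match.arg(adjust))
}

#' Moderated t-test (empirical-Bayes variance shrinkage)
#'
#' Per-feature variances are shrunk toward a common (or, with
#' `trend = TRUE`, mean-dependent) prior by the standard inverse-chi-square
#' empirical-Bayes model, and p values come from a t distribution with
#' augmented degrees of freedom. Fitted with \pkg{limma}.
#'
#' @inheritParams diffexp_ttest
#' @param trend let the prior variance follow a smooth function of mean
#'   expression; requires at least 10 features.
#' @export
diffexp_modt <- function(m, pheno, trend = FALSE, adjust = c("BH", "bonferroni")) {
  grp <- split_groups(m, pheno)
  if (trend && nrow(m) < 10L)
    stop("trend smoothing needs at least 10 features")
  ord <- c(grp$ctrl, grp$case)
  design <- cbind(intercept = 1, case = rep(0:1, c(length(grp$ctrl), length(grp$case))))
  fit <- limma::eBayes(limma::lmFit(m[, ord, drop = FALSE], design), trend = trend)
  de_table(m, grp, fit$p.value[, "case"], "modt", match.arg(adjust))
}

rank_product_stats <- function(x, is_case) {
  # features x (n0*n1) matrix of pairwise case-minus-control differences;
  # comparisons enumerated in an order symmetric in the two groups, so a
  # label swap negates the matrix column-for-column (exact down/up duality)
  ci <- which(is_case); ki <- which(!is_case)
  grid <- expand.grid(k = ki, c = ci)
  grid <- grid[order(pmin(grid$k, grid$c), pmax(grid$k, grid$c)), ]
  d <- x[, grid$c, drop = FALSE] - x[, grid$k, drop = FALSE]
  lr_down <- 0; lr_up <- 0
  nf1 <- nrow(x) + 1L
  for (j in seq_len(ncol(d))) {
    r <- rank(d[, j])          # rank 1 = most down-regulated
    lr_down <- lr_down + log(r)
    lr_up <- lr_up + log(nf1 - r)
  }
  list(down = lr_down / ncol(d), up = lr_up / ncol(d))
}

#' Rank-product test per feature
#'
#' The rank product of a feature is the geometric mean of its ranks across
#' all pairwise case-vs-control fold-change comparisons; consistently
#' extreme features get extreme rank products. Significance is estimated by
#' permuting the sample labels (`n_perm` permutations); down- and
#' up-regulation tails are combined two-sidedly. Adjustment is always
#' Benjamini-Hochberg.
#'
#' @inheritParams diffexp_ttest
#' @param n_perm number of label permutations (at least 100).
#' @param seed seed for the permutation draws, so results are reproducible.
#' @export
diffexp_rankprod <- function(m, pheno, n_perm = 500L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  grp <- split_groups(m, pheno)
  # full name-sorted column order with a fixed group mask: keeps results
  # invariant to input column order and exactly symmetric under label swap
  ord <- sort(colnames(m))
  x <- m[, ord, drop = FALSE]
  is_case <- ord %in% grp$case
  obs <- rank_product_stats(x, is_case)
  cnt_down <- numeric(nrow(m)); cnt_up <- numeric(nrow(m))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    nullstat <- rank_product_stats(x[, sample.int(ncol(x)), drop = FALSE], is_case)
    cnt_down <- cnt_down + (nullstat$down <= obs$down)
    cnt_up <- cnt_up + (nullstat$up <= obs$up)
  }
  p_down <- (cnt_down + 1) / (n_perm + 1)
  p_up <- (cnt_up + 1) / (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_down, p_up))
  out <- de_table(m, grp, p, "rankprod", "BH")
  attr(out, "rank_product") <- exp(obs$down)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with cumulative-minimum enforcement) or
#' Bonferroni, in input order.
#'
#' @param p vector of p values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = method)
}

#' Import an externally computed differential-expression table
#'
#' Expects a delimited table with at least the columns `feature`,
#' `logratio`, `meanExp`, `pval`, `adj.pval`; extra columns are kept but
#' ignored downstream.
#'
#' @param path file path (tab- or comma-delimited, auto-detected).
#' @export
import_diffexp <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("feature", "logratio", "meanExp", "pval", "adj.pval")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$feature)) stop("duplicate feature ids in DE table")
  for (col in c("pval", "adj.pval"))
    if (any(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1))
      stop("column ", col, " must lie in [0, 1]")
  attr(df, "method") <- "imported"
  df
}

#' Write a differential-expression table
#'
#' @param de table from one of the `diffexp_*` functions.
#' @param path output path (TSV).
#' @export
write_diffexp <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
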