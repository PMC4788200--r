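# All-pairs miRNA x mRNA correlation with a one-sided test of negative
# association -- the computational core. Since canonical miRNA action is
# target degradation, the alternative of interest is rho < 0; the composite
# null rho >= 0 is handled as the boundary test at rho = 0 (the supremum
# over the null), i.e. the lower tail of the usual test statistic.

#' All-pairs correlation between miRNAs and mRNAs
#'
#' Computes the chosen correlation coefficient for every (miRNA, mRNA)
#' pair of an aligned dataset, with a one-sided p value for the alternative
#' of negative association, and Benjamini-Hochberg (or Bonferroni)
#' adjustment over the full family of computed pairs. Pearson p values use
#' the exact t reference `t = r * sqrt(n-2) / sqrt(1-r^2)` (lower tail);
#' Spearman runs the same machinery on within-feature ranks (ties averaged);
#' Kendall uses tau with a normal-approximation lower-tail p and is refused
#' above `kendall_max_pairs` pairs.
#'
#' The pair table is assembled in blocks of `block_rows` miRNAs so peak
#' intermediate memory stays proportional to `block_rows * n_mRNA`; each
#' pair's coefficient is computed identically for any block size.
#'
#' Constant (zero-variance) features cannot be tested: their pairs are
#' recorded with `cor = 0`, `pval = 1` and `constant = TRUE` so the
#' row-count contract (exactly `n_miRNA * n_mRNA` rows) still holds.
#'
#' @param ds aligned dataset from [align_dataset()] (at least 4 samples).
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param block_rows number of miRNA rows materialised per block.
#' @param adjust multiple-testing method applied across all pairs.
#' @param kendall_max_pairs refuse Kendall above this many pairs.
#' @return data.frame with one row per pair: `miRNA`, `mRNA`, `cor`,
#'   `pval`, `adj.pval`, `constant`; attribute `n_samples`.
#' @export
correlate_all <- function(ds, method = c("pearson", "spearman", "kendall"),
                          block_rows = 512L, adjust = c("BH", "bonferroni"),
                          kendall_max_pairs = 2e6) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!inherits(ds, "mir_dataset")) stop("'ds' must be a mir_dataset")
  X <- unclass(ds$mirna); Y <- unclass(ds$mrna)
  if (!identical(colnames(X), colnames(Y))) stop("sample mismatch between matrices")
  n <- ncol(X)
  if (n < 4L) stop("need at least 4 shared samples for the correlation test")
  if (block_rows < 1L) stop("block_rows must be positive")
  n_mi <- nrow(X); n_mr <- nrow(Y)
  n_pairs <- as.double(n_mi) * n_mr

  if (method == "kendall") {
    if (n_pairs > kendall_max_pairs)
      stop("Kendall correlation is limited to ", format(kendall_max_pairs),
           " pairs (requested ", format(n_pairs), "); use pearson/spearman")
    res <- kendall_all(X, Y, n)
  } else {
    if (method == "spearman") {
      X <- t(apply(X, 1L, rank)); Y <- t(apply(Y, 1L, rank))
    }
    res <- pearson_all(X, Y, n, block_rows)
  }

  out <- data.frame(
    miRNA = rep(rownames(ds$mirna), each = n_mr),
    mRNA = rep(rownames(ds$mrna), times = n_mi),
    cor = res$cor,
    pval = pmin(pmax(res$pval, .Machine$double.xmin), 1),
    stringsAsFactors = FALSE
  )
  out$adj.pval <- adjust_pvalues(out$pval, adjust)
  out$constant <- res$constant
  out$pval[out$constant] <- 1
  out$adj.pval[out$constant] <- 1
  attr(out, "method") <- method
  attr(out, "n_samples") <- n
  out
}

pearson_all <- function(X, Y, n, block_rows) {
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  nx <- sqrt(rowSums(cx^2))
  ny <- sqrt(rowSums(cy^2))
  zx <- nx == 0; zy <- ny == 0
  xs <- cx / ifelse(zx, 1, nx); xs[zx, ] <- 0
  ys <- cy / ifelse(zy, 1, ny); ys[zy, ] <- 0
  n_mi <- nrow(X); n_mr <- nrow(Y)
  r <- numeric(n_mi * n_mr)
  # per-row products keep each pair's accumulation order independent of the
  # blocking, so results are bitwise identical for any block_rows
  for (start in seq(1L, n_mi, by = block_rows)) {
    end <- min(start + block_rows - 1L, n_mi)
    for (i in start:end)
      r[((i - 1L) * n_mr + 1L):(i * n_mr)] <- ys %*% xs[i, ]
  }
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  tstat[r >= 1] <- Inf
  tstat[r <= -1] <- -Inf
  p <- stats::pt(tstat, df = n - 2)
  constant <- rep(zx, each = n_mr) | rep(zy, times = n_mi)
  r[constant] <- 0
  list(cor = r, pval = p, constant = constant)
}

kendall_all <- function(X, Y, n, ...) {
  n_mi <- nrow(X); n_mr <- nrow(Y)
  tau <- numeric(n_mi * n_mr)
  constant <- logical(n_mi * n_mr)
  sdx <- apply(X, 1L, stats::sd); sdy <- apply(Y, 1L, stats::sd)
  k <- 0L
  for (i in seq_len(n_mi)) {
    for (j in seq_len(n_mr)) {
      k <- k + 1L
      if (sdx[i] == 0 || sdy[j] == 0) {
        constant[k] <- TRUE
      } else {
        tau[k] <- stats::cor(X[i, ], Y[j, ], method = "kendall")
      }
    }
  }
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  list(cor = tau, pval = stats::pnorm(z), constant = constant)
}

#' Select significantly negative pairs
#'
#' Rows with the chosen p-value column below `alpha` and `cor < 0`; all
#' columns are preserved.
#'
#' @param tab pair table from [correlate_all()].
#' @param alpha threshold in (0, 1\].
#' @param on `"adj.pval"` (FDR control, default) or `"pval"`.
#' @export
significant_pairs <- function(tab, alpha = 0.05, on = c("adj.pval", "pval")) {
  on <- match.arg(on)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  tab[tab[[on]] < alpha & tab$cor < 0, , drop = FALSE]
}

#' Summarise the correlation coefficient distribution
#'
#' Histogram over 101 fixed bins on \[-1, 1\] plus the pair counts at the
#' four standard cutoffs (p < 0.05, p < 0.01, FDR < 0.05, FDR < 0.01).
#'
#' @param tab pair table from [correlate_all()].
#' @export
correlation_density_summary <- function(tab) {
  if (nrow(tab) == 0L) stop("empty pair table")
  breaks <- seq(-1, 1, length.out = 102L)
  counts <- graphics::hist(tab$cor, breaks = breaks, plot = FALSE)$counts
  cutoffs <- c(
    "p<0.05" = sum(tab$pval < 0.05),
    "p<0.01" = sum(tab$pval < 0.01),
    "FDR<0.05" = sum(tab$adj.pval < 0.05),
    "FDR<0.01" = sum(tab$adj.pval < 0.01)
  )
  out <- list(n = nrow(tab), mean_cor = mean(tab$cor),
              breaks = breaks, counts = counts, cutoff_counts = cutoffs)
  class(out) <- "corr_density_summary"
  out
}

#' @export
print.corr_density_summary <- function(x, ...) {
  cat("Correlation summary over", format(x$n, big.mark = ","), "pairs\n")
  cat("  mean coefficient:", signif(x$mean_cor, 4), "\n")
  for (nm in names(x$cutoff_counts))
    cat(sprintf("  %-9s %s (%s%%)\n", nm,
                format(x$cutoff_counts[[nm]], big.mark = ","),
                formatC(100 * x$cutoff_counts[[nm]] / x$n, format = "f", digits = 2)))
  invisible(x)
}

#' Write a correlation pair table
#'
#' Columns `miRNA`, `mRNA`, `cor`, `pval`, `adj.pval` as TSV.
#' @param tab pair table.
#' @param path output path.
#' @export
write_pair_table <- function(tab, path) {
  keep <- intersect(c("miRNA", "mRNA", "cor", "pval", "adj.pval"), names(tab))
  extra <- setdiff(names(tab), c(keep, "constant"))
  data.table::fwrite(tab[, c(keep, extra), drop = FALSE], path, sep = "\t")
  invisible(path)
}
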