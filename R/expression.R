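#' Construct an expression matrix
#'
#' Validates and tags a feature-by-sample numeric matrix. Values must be
#' finite with no missing cells: the correlation tests downstream assume a
#' complete common sample set, so missing data are rejected at ingestion
#' rather than silently changing per-pair sample sizes.
#'
#' @param values numeric matrix, features in rows (unique non-empty
#'   rownames), samples in columns (unique colnames).
#' @param scale `"log2"` for normalized log2 expression units, or
#'   `"raw_counts"` for untransformed counts (the only scale on which
#'   [filter_low_expression()] is defined).
#' @return the matrix with a `scale` attribute attached.
#' @export
expression_matrix <- function(values, scale = c("log2", "raw_counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix (", nrow(values), " features, ",
         ncol(values), " samples)")
  ids <- rownames(values)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("feature ids (rownames) must be present and non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(utils::head(dup, 10), collapse = ", "))
  if (is.null(colnames(values)))
    stop("sample ids (colnames) must be present")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- paste0(ids[bad[, 1]], "/", colnames(values)[bad[, 2]])
    stop("missing or non-finite values in ", nrow(bad), " cell(s): ",
         paste(utils::head(cells, 10), collapse = ", "))
  }
  attr(values, "scale") <- scale
  values
}

expr_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) stop("matrix has no 'scale' attribute; use expression_matrix()")
  s
}

#' Read an expression matrix from delimited text
#'
#' First column (or row names) holds feature ids, header row holds sample
#' ids. Delimiter is auto-detected between tab and comma unless `sep` is
#' given.
#'
#' @param path file path.
#' @param scale declared scale of the values, see [expression_matrix()].
#' @param sep field separator; `NULL` auto-detects tab vs comma.
#' @return validated matrix with a `scale` attribute.
#' @export
read_expression <- function(path, scale = c("log2", "raw_counts"), sep = NULL) {
  scale <- match.arg(scale)
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) stop("malformed expression file (need header plus data): ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[1L])) "\t" else ","
  nh <- length(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])
  nd <- length(strsplit(lines[2L], sep, fixed = TRUE)[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (nh == nd - 1L) {
    # header one field short: read.table used column 1 as row names
    ids <- rownames(df)
    vals <- df
  } else {
    if (ncol(df) < 2L)
      stop("malformed header: need a feature-id column plus at least one sample")
    ids <- as.character(df[[1L]])
    vals <- df[-1L]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in ", path, ": ",
         paste(utils::head(dup, 10), collapse = ", "))
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric cells in column(s): ", paste(nonnum, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, scale)
}

#' Write an expression matrix as delimited text
#'
#' @param m matrix from [expression_matrix()] / [read_expression()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(m, path, sep = "\t") {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove features with low median raw counts
#'
#' Keeps exactly the features whose median count across all samples is at
#' least `min_median`; features strictly below the threshold are removed, so
#' a median exactly equal to `min_median` is retained. Defined on raw counts
#' only (thresholding log2 values would silently change its meaning).
#'
#' @param m raw-count matrix (`scale == "raw_counts"`).
#' @param min_median removal threshold, default 10 counts.
#' @export
filter_low_expression <- function(m, min_median = 10) {
  if (expr_scale(m) != "raw_counts")
    stop("filter_low_expression is defined on raw counts, not log2 values")
  med <- apply(m, 1L, stats::median)
  out <- m[med >= min_median, , drop = FALSE]
  if (nrow(out) == 0L) stop("no features pass the median filter")
  expression_matrix(out, "raw_counts")
}

#' Log2-transform raw counts
#'
#' @param m raw-count matrix with non-negative values.
#' @param pseudocount added before taking log2 (default 1, so a count of 0
#'   maps to 0).
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (expr_scale(m) != "raw_counts")
    stop("log2_transform expects a raw-count matrix")
  if (any(m < 0)) stop("negative values in raw-count matrix")
  out <- log2(m + pseudocount)
  attr(out, "scale") <- NULL
  expression_matrix(out, "log2")
}

#' Build a two-group phenotype assignment
#'
#' @param samples character vector of sample ids.
#' @param groups group label per sample; exactly two distinct labels.
#' @param control,case which label is the control / case group. If omitted,
#'   the first label in order of appearance is taken as control.
#' @return named factor with levels `c(control, case)`.
#' @export
phenotype_table <- function(samples, groups, control = NULL, case = NULL) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (length(samples) != length(groups))
    stop("'samples' and 'groups' must have the same length")
  if (anyDuplicated(samples))
    stop("duplicate sample ids in phenotype table")
  labs <- unique(groups)
  if (length(labs) != 2L)
    stop("phenotype must use exactly two group labels, got: ",
         paste(labs, collapse = ", "))
  if (is.null(control)) control <- labs[1L]
  if (is.null(case)) case <- setdiff(labs, control)
  if (!all(c(control, case) %in% labs) || control == case)
    stop("control/case labels must be the two labels present")
  ph <- factor(groups, levels = c(control, case))
  names(ph) <- samples
  ph
}

#' Read a two-column sample/group phenotype file
#'
#' @inheritParams phenotype_table
#' @param path TSV (or CSV) with sample id in column 1, group in column 2;
#'   a header row is expected.
#' @param sep field separator; `NULL` auto-detects tab vs comma.
#' @export
read_phenotype <- function(path, control = NULL, case = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs at least two columns")
  phenotype_table(df[[1L]], df[[2L]], control = control, case = case)
}

#' Align paired miRNA and mRNA matrices on their shared samples
#'
#' Intersects the sample sets of both matrices and the phenotype table,
#' drops samples without a phenotype assignment (with a warning), and
#' reorders the survivors into a canonical (sorted) order so the result does
#' not depend on input column order.
#'
#' @param mirna,mrna log2-scale matrices from [expression_matrix()].
#' @param pheno named factor from [phenotype_table()].
#' @return object of class `mir_dataset`: list with elements `mirna`,
#'   `mrna` (aligned matrices) and `pheno` (aligned factor).
#' @export
align_dataset <- function(mirna, mrna, pheno) {
  if (expr_scale(mirna) != "log2" || expr_scale(mrna) != "log2")
    stop("both matrices must be on the log2 scale before alignment")
  shared <- intersect(colnames(mirna), colnames(mrna))
  if (length(shared) == 0L)
    stop("no shared samples between miRNA and mRNA matrices")
  no_ph <- setdiff(shared, names(pheno))
  if (length(no_ph)) {
    warning("dropping ", length(no_ph), " sample(s) without phenotype: ",
            paste(utils::head(no_ph, 5), collapse = ", "))
    shared <- setdiff(shared, no_ph)
  }
  if (length(shared) == 0L) stop("no shared samples with phenotype assignment")
  shared <- sort(shared)
  ph <- pheno[shared]
  tab <- table(ph)
  if (length(tab) != 2L || any(tab < 2L))
    stop("need at least 2 samples per group after alignment; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  out <- list(
    mirna = expression_matrix(mirna[, shared, drop = FALSE], "log2"),
    mrna  = expression_matrix(mrna[, shared, drop = FALSE], "log2"),
    pheno = ph
  )
  class(out) <- "mir_dataset"
  out
}

#' @export
print.mir_dataset <- function(x, ...) {
  tab <- table(x$pheno)
  cat("Paired expression dataset\n")
  cat("  miRNAs:  ", nrow(x$mirna), "\n")
  cat("  mRNAs:   ", nrow(x$mrna), "\n")
  cat("  samples: ", ncol(x$mirna), " (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
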