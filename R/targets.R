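# Intersection of significant negative correlations with sequence-based
# target prediction databases, combined-table assembly (S1-style schema),
# interaction score, and the per-miRNA false-positive ratio of predicted
# targets.

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Load a target-prediction database from a two-column pair list
#'
#' @param path delimited file, miRNA id in column 1, mRNA id in column 2
#'   (microCosm/TargetScan-style dumps reduced to pair lists, or custom).
#' @param name database name; defaults to the file name without extension.
#' @param sep field separator; `NULL` auto-detects tab vs comma.
#' @param header whether the file has a header row (default `FALSE`).
#' @return object of class `target_db`: list with `name` and a unique
#'   `pairs` data.frame (`miRNA`, `mRNA`). Duplicate pairs are collapsed
#'   with a message.
#' @export
load_target_db <- function(path, name = NULL, sep = NULL, header = FALSE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty target database file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("target database needs at least 2 columns: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  target_db(df[[1L]], df[[2L]], name)
}

#' Construct a target database from pair vectors
#'
#' @param mirna,mrna equal-length id vectors, one element per predicted pair.
#' @param name database name.
#' @export
target_db <- function(mirna, mrna, name) {
  if (!nzchar(name)) stop("database name must be non-empty")
  pairs <- data.frame(miRNA = as.character(mirna), mRNA = as.character(mrna),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) stop("target database '", name, "' has no pairs")
  ndup <- sum(duplicated(pair_key(pairs$miRNA, pairs$mRNA)))
  if (ndup > 0L) {
    message("collapsed ", ndup, " duplicate pair(s) in database '", name, "'")
    pairs <- pairs[!duplicated(pair_key(pairs$miRNA, pairs$mRNA)), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(name = name, pairs = pairs), class = "target_db")
}

#' @export
print.target_db <- function(x, ...) {
  cat("Target database '", x$name, "': ", nrow(x$pairs), " pairs, ",
      length(unique(x$pairs$miRNA)), " miRNAs, ",
      length(unique(x$pairs$mRNA)), " mRNAs\n", sep = "")
  invisible(x)
}

#' Write a target database as a two-column TSV
#' @param db `target_db` object.
#' @param path output path.
#' @export
write_target_db <- function(db, path) {
  utils::write.table(db$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intersect significant pairs with target databases and annotate
#'
#' The final decision rule: a pair is an interaction when it is
#' significantly negatively correlated *and* predicted in at least
#' `min_dat_sum` databases. The output follows the combined-table schema:
#' correlation columns, per-feature differential-expression annotation,
#' one 0/1 flag column per database (`dat.<name>`, in database order),
#' their sum `dat.sum`, and the interaction `score`.
#'
#' @param sig significant pair table from [significant_pairs()] (already
#'   restricted to negative correlations at the chosen threshold).
#' @param de_mir,de_mrna differential-expression tables covering every
#'   feature appearing in `sig` (required for the score).
#' @param dbs list of [target_db()] objects with unique names.
#' @param min_dat_sum minimum number of databases supporting a pair.
#' @return data.frame with columns `miRNA`, `mRNA`, `cor`, `pval`,
#'   `adj.pval`, `logratio.miRNA`, `logratio.mRNA`, `meanExp.miRNA`,
#'   `meanExp.mRNA`, `dat.<name>`..., `dat.sum`, `score`.
#' @export
intersect_with_targets <- function(sig, de_mir, de_mrna, dbs, min_dat_sum = 1L) {
  if (min_dat_sum < 1L) stop("min_dat_sum must be at least 1")
  nms <- vapply(dbs, function(d) d$name, character(1))
  if (anyDuplicated(nms)) stop("database names must be unique")
  keys <- pair_key(sig$miRNA, sig$mRNA)
  flags <- if (length(dbs)) {
    vapply(dbs, function(d)
      as.integer(keys %in% pair_key(d$pairs$miRNA, d$pairs$mRNA)),
      integer(length(keys)))
  } else {
    matrix(0L, nrow = length(keys), ncol = 0L)
  }
  if (length(keys) == 1L) flags <- matrix(flags, nrow = 1L)
  dat_sum <- if (ncol(flags)) as.integer(rowSums(flags)) else integer(length(keys))
  keep <- dat_sum >= min_dat_sum
  sig <- sig[keep, , drop = FALSE]
  flags <- flags[keep, , drop = FALSE]
  dat_sum <- dat_sum[keep]
  i_mir <- match(sig$miRNA, de_mir$feature)
  i_mrn <- match(sig$mRNA, de_mrna$feature)
  miss <- c(unique(sig$miRNA[is.na(i_mir)]), unique(sig$mRNA[is.na(i_mrn)]))
  if (length(miss))
    stop("feature(s) missing from DE tables: ",
         paste(utils::head(miss, 10), collapse = ", "))
  out <- data.frame(
    miRNA = sig$miRNA, mRNA = sig$mRNA,
    cor = sig$cor, pval = sig$pval, adj.pval = sig$adj.pval,
    logratio.miRNA = de_mir$logratio[i_mir],
    logratio.mRNA = de_mrna$logratio[i_mrn],
    meanExp.miRNA = de_mir$meanExp[i_mir],
    meanExp.mRNA = de_mrna$meanExp[i_mrn],
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (length(dbs))
    for (j in seq_along(dbs)) out[[paste0("dat.", nms[j])]] <- flags[, j]
  out$dat.sum <- dat_sum
  out$score <- compute_score(out$logratio.miRNA, out$logratio.mRNA)
  rownames(out) <- NULL
  out
}

#' Interaction deregulation score
#'
#' `score = -2 * (logratio_miRNA * logratio_mRNA)`: positive when the two
#' fold-changes oppose each other (consistent with repression), negative
#' when they agree, with magnitude reflecting how jointly deregulated the
#' pair is.
#'
#' @param logratio_mirna,logratio_mrna log2 fold-changes (case minus
#'   control); vectorised.
#' @export
compute_score <- function(logratio_mirna, logratio_mrna) {
  -2 * (logratio_mirna * logratio_mrna)
}

#' Per-miRNA false-positive ratio of predicted targets
#'
#' For each miRNA, the percentage of its database-predicted targets (among
#' expressed features) that fail the negative-correlation criterion:
#' `100 * (1 - n_confirmed / n_predicted)`. miRNAs with no predicted
#' expressed target are omitted.
#'
#' @param dbs list of [target_db()] objects (their union is the prediction
#'   universe).
#' @param combined combined interaction table from
#'   [intersect_with_targets()] (the confirmed pairs).
#' @param mirna_ids,mrna_ids expressed feature ids; predictions outside
#'   them are excluded from the denominator.
#' @export
mirna_fp_ratio <- function(dbs, combined, mirna_ids, mrna_ids) {
  allp <- unique(do.call(rbind, lapply(dbs, function(d) d$pairs)))
  allp <- allp[allp$miRNA %in% mirna_ids & allp$mRNA %in% mrna_ids, , drop = FALSE]
  if (nrow(allp) == 0L)
    return(data.frame(miRNA = character(), n_predicted = integer(),
                      n_confirmed = integer(), fp_percent = numeric(),
                      stringsAsFactors = FALSE))
  n_pred <- table(allp$miRNA)
  conf <- unique(combined[, c("miRNA", "mRNA")])
  n_conf <- table(factor(conf$miRNA, levels = names(n_pred)))
  out <- data.frame(
    miRNA = names(n_pred),
    n_predicted = as.integer(n_pred),
    n_confirmed = as.integer(n_conf),
    stringsAsFactors = FALSE
  )
  out$fp_percent <- 100 * (1 - out$n_confirmed / out$n_predicted)
  out <- out[order(out$fp_percent, out$miRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-count summaries of a combined interaction table
#'
#' Produces (a) the targets-per-miRNA table sorted by descending target
#' count, (b) the miRNAs-per-mRNA category counts (0, 1, ..., 5, >5 miRNAs
#' per mRNA; a partition of all expressed mRNAs), and (c) the cumulative
#' coverage curve: with miRNAs ordered by target count, the fraction of
#' expressed mRNAs in the union of the first k miRNAs' target sets.
#'
#' @param combined combined interaction table.
#' @param expressed_mrnas total number of expressed mRNAs (category-0
#'   denominator).
#' @return list with `targets_per_mirna`, `mirnas_per_mrna`,
#'   `cumulative_coverage`.
#' @export
count_summaries <- function(combined, expressed_mrnas) {
  pairs <- unique(combined[, c("miRNA", "mRNA"), drop = FALSE])
  n_targeted <- length(unique(pairs$mRNA))
  if (expressed_mrnas < n_targeted)
    stop("expressed_mrnas (", expressed_mrnas, ") smaller than the number of ",
         "distinct targeted mRNAs (", n_targeted, ")")
  cats <- c(as.character(0:5), ">5")
  if (nrow(pairs) == 0L) {
    pie <- stats::setNames(c(expressed_mrnas, rep(0L, 6L)), cats)
    return(list(
      targets_per_mirna = data.frame(miRNA = character(), n_targets = integer(),
                                     stringsAsFactors = FALSE),
      mirnas_per_mrna = pie,
      cumulative_coverage = data.frame(k = integer(), miRNA = character(),
                                       covered = integer(), fraction = numeric(),
                                       stringsAsFactors = FALSE)))
  }
  cnt <- table(pairs$miRNA)
  tpm <- data.frame(miRNA = names(cnt), n_targets = as.integer(cnt),
                    stringsAsFactors = FALSE)
  tpm <- tpm[order(-tpm$n_targets, tpm$miRNA), , drop = FALSE]
  rownames(tpm) <- NULL

  per_mrna <- table(pairs$mRNA)
  cat_lab <- ifelse(per_mrna > 5, ">5", as.character(per_mrna))
  pie <- stats::setNames(integer(7L), cats)
  tt <- table(cat_lab)
  pie[names(tt)] <- as.integer(tt)
  pie["0"] <- expressed_mrnas - n_targeted

  targets_by_mirna <- split(pairs$mRNA, pairs$miRNA)[tpm$miRNA]
  seqall <- unlist(targets_by_mirna, use.names = FALSE)
  cum_unique <- cumsum(!duplicated(seqall))
  ends <- cumsum(lengths(targets_by_mirna))
  cov <- data.frame(
    k = seq_along(ends),
    miRNA = tpm$miRNA,
    covered = cum_unique[ends],
    stringsAsFactors = FALSE
  )
  cov$fraction <- cov$covered / expressed_mrnas
  list(targets_per_mirna = tpm, mirnas_per_mrna = pie,
       cumulative_coverage = cov)
}

#' Top interactions by adjusted p value
#'
#' Stable sort by the sort key ascending with ties broken by
#' (`pval`, `miRNA`, `mRNA`) lexicographically, so the output is
#' deterministic regardless of input row order.
#'
#' @param combined combined interaction table.
#' @param n number of rows to return (whole table if larger).
#' @param sort_key primary sort column, default `"adj.pval"`.
#' @param decreasing sort the key descending instead (e.g. for `score`).
#' @export
top_interactions <- function(combined, n = 15L, sort_key = "adj.pval",
                             decreasing = FALSE) {
  if (n < 1L) stop("n must be at least 1")
  if (!sort_key %in% names(combined)) stop("unknown sort key: ", sort_key)
  key <- combined[[sort_key]]
  if (decreasing) key <- -xtfrm(key)
  ord <- order(key, combined$pval, combined$miRNA, combined$mRNA)
  out <- combined[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a combined interaction table
#' @param combined combined table.
#' @param path output path (TSV; use a `.csv` extension with `sep=","` for
#'   spreadsheet import).
#' @param sep field separator.
#' @export
write_combined <- function(combined, path, sep = "\t") {
  data.table::fwrite(combined, path, sep = sep)
  invisible(path)
}
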