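# Hypergeometric over-representation of target sets against GO/KEGG-style
# gene-set collections. Flat one-sided test only: the question is whether a
# miRNA's confirmed targets are enriched in a category relative to the
# expressed background, and depletion is not of interest here.

#' Read a gene-set collection in GMT format
#'
#' Tab-separated lines: set id, description (may be empty), then member
#' gene ids. Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of member vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(bad, 5), collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- ids
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct genes\n")
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each set S (restricted to the universe), with N = |universe|,
#' K = |S|, n = |targets| and k = |targets intersect S|, the upper-tail
#' p value P(X >= k) of the hypergeometric distribution, then
#' Benjamini-Hochberg adjustment across tested sets. Sets smaller than
#' `min_set` after restriction are skipped. Targets outside the universe
#' are dropped with a warning.
#'
#' @param targets gene ids of interest (e.g. confirmed targets of a miRNA).
#' @param gsc collection from [read_gmt()].
#' @param universe background gene ids; by convention the expressed mRNAs
#'   of the analysed dataset.
#' @param min_set minimum restricted set size to test (default 5).
#' @return data.frame sorted by adjusted p: `set_id`, `description`,
#'   `overlap`, `set_size`, `pval`, `adj.pval`, `genes` (overlapping ids,
#'   comma-separated, sorted).
#' @export
enrich <- function(targets, gsc, universe, min_set = 5L) {
  targets <- unique(as.character(targets))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " target(s) outside the universe")
    targets <- intersect(targets, universe)
  }
  if (length(targets) == 0L) stop("no targets left after universe restriction")
  N <- length(universe); n <- length(targets)
  rows <- lapply(names(gsc$sets), function(id) {
    s <- intersect(gsc$sets[[id]], universe)
    K <- length(s)
    if (K < min_set) return(NULL)
    hit <- intersect(targets, s)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, description = unname(gsc$descriptions[id]),
               overlap = k, set_size = K, pval = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(set_id = character(), description = character(),
                      overlap = integer(), set_size = integer(),
                      pval = numeric(), adj.pval = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adj.pval <- adjust_pvalues(out$pval, "BH")
  out <- out[order(out$adj.pval, out$pval, out$set_id),
             c("set_id", "description", "overlap", "set_size",
               "pval", "adj.pval", "genes")]
  rownames(out) <- NULL
  out
}
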