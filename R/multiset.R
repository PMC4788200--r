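# Integrative layer across several interactomes: shared and
# dataset-specific interactions, k-means on pair correlation profiles, and
# hierarchical clustering / PCA of datasets.

tab_keys <- function(tab) unique(pair_key(tab$miRNA, tab$mRNA))

check_labelled <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))) ||
      anyDuplicated(names(tables)))
    stop("'tables' must be a named list with unique, non-empty dataset labels")
  names(tables)
}

#' Shared interactions across datasets (Venn cells)
#'
#' For every non-empty subset of datasets, the number of interaction pairs
#' found (significant + predicted) in exactly that subset. The cells
#' partition the union of all pairs.
#'
#' @param tables named list (>= 2) of combined interaction tables, one per
#'   dataset.
#' @return list with `cells` (data.frame `subset`, `n_datasets`, `count`),
#'   `pairs` (list of `miRNA`/`mRNA` data.frames per cell) and
#'   `union_size`.
#' @export
shared_interactions <- function(tables) {
  labels <- check_labelled(tables)
  if (length(tables) < 2L) stop("need at least 2 datasets")
  keysets <- lapply(tables, tab_keys)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(labels[row], collapse = "&"))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(labels)))[-1L, , drop = FALSE]
  subsets <- apply(grid, 1L, function(row) paste(labels[as.logical(row)], collapse = "&"))
  counts <- vapply(subsets, function(s) sum(sig == s), integer(1))
  key_to_df <- function(keys) {
    sp <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(miRNA = vapply(sp, `[[`, "", 1L),
               mRNA = vapply(sp, `[[`, "", 2L), stringsAsFactors = FALSE)
  }
  pairs <- lapply(subsets, function(s) key_to_df(all_keys[sig == s]))
  names(pairs) <- subsets
  cells <- data.frame(subset = subsets,
                      n_datasets = rowSums(grid),
                      count = counts,
                      stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  list(cells = cells, pairs = pairs, union_size = length(all_keys))
}

#' Dataset-specific interactions
#'
#' Pairs found (significant + predicted) in the focal dataset and in no
#' other, restricted to pairs whose both features are measurable
#' (expressed) in every other dataset -- otherwise "specific" could merely
#' mean "not measured elsewhere". Pairs excluded for non-measurability are
#' counted in a message.
#'
#' @param tables named list of combined interaction tables.
#' @param focal label of the focal dataset.
#' @param universes named list (same labels) of
#'   `list(mirna = ids, mrna = ids)` giving each dataset's expressed
#'   features; `NULL` skips the measurability restriction.
#' @return the focal table's specific rows.
#' @export
specific_interactions <- function(tables, focal, universes = NULL) {
  labels <- check_labelled(tables)
  if (!focal %in% labels) stop("focal dataset '", focal, "' not among tables")
  others <- setdiff(labels, focal)
  foc <- tables[[focal]]
  other_keys <- unique(unlist(lapply(tables[others], tab_keys), use.names = FALSE))
  keep <- !(pair_key(foc$miRNA, foc$mRNA) %in% other_keys)
  out <- foc[keep, , drop = FALSE]
  if (!is.null(universes)) {
    measurable <- rep(TRUE, nrow(out))
    for (d in others) {
      u <- universes[[d]]
      if (is.null(u)) stop("no universe given for dataset '", d, "'")
      measurable <- measurable &
        out$miRNA %in% u$mirna & out$mRNA %in% u$mrna
    }
    if (any(!measurable))
      message("excluded ", sum(!measurable),
              " pair(s) not measurable in every other dataset")
    out <- out[measurable, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-miRNA specificity summary
#'
#' For the focal dataset: each miRNA's total number of targets, its number
#' of focal-specific targets (see [specific_interactions()]) and its mean
#' expression. miRNAs with ratio 1 have only focal-specific interactions.
#'
#' @inheritParams specific_interactions
#' @export
specificity_scatter <- function(tables, focal, universes = NULL) {
  foc <- tables[[check_labelled(tables)[match(focal, names(tables))]]]
  if (is.null(foc)) stop("focal dataset '", focal, "' not among tables")
  spec <- specific_interactions(tables, focal, universes)
  tot_pairs <- unique(foc[, c("miRNA", "mRNA")])
  n_total <- table(tot_pairs$miRNA)
  spec_pairs <- unique(spec[, c("miRNA", "mRNA")])
  n_spec <- table(factor(spec_pairs$miRNA, levels = names(n_total)))
  mexp <- tapply(foc$meanExp.miRNA, foc$miRNA, `[`, 1L)
  out <- data.frame(
    miRNA = names(n_total),
    n_total = as.integer(n_total),
    n_specific = as.integer(n_spec),
    mean_expression = as.numeric(mexp[names(n_total)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_total, out$miRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the multi-dataset pair-correlation matrix
#'
#' Rows are the miRNA-mRNA pairs measured in *all* datasets (i.e. present
#' in every full correlation table) that are significant + predicted in at
#' least one dataset; columns are datasets; cells are the correlation
#' coefficients. Per-dataset significance flags are carried along.
#'
#' @param corr_tables named list of full pair tables from
#'   [correlate_all()] (all measured pairs of each dataset).
#' @param combined_tables named list (same labels) of combined interaction
#'   tables (the significant + predicted pairs).
#' @return object of class `pair_matrix`: list with `cor` (pairs x
#'   datasets matrix), `flags` (logical matrix) and `pairs` (data.frame).
#' @export
build_pair_matrix <- function(corr_tables, combined_tables) {
  labels <- check_labelled(corr_tables)
  if (!identical(sort(labels), sort(check_labelled(combined_tables))))
    stop("corr_tables and combined_tables must carry the same labels")
  keysets <- lapply(corr_tables, function(t) pair_key(t$miRNA, t$mRNA))
  common <- Reduce(intersect, keysets)
  flagsets <- lapply(combined_tables[labels], tab_keys)
  flags <- vapply(flagsets, function(k) common %in% k, logical(length(common)))
  if (length(common) == 1L) flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, labels))
  keep <- rowSums(flags) >= 1L
  common <- common[keep]
  flags <- flags[keep, , drop = FALSE]
  cors <- vapply(labels, function(d) {
    t <- corr_tables[[d]]
    t$cor[match(common, keysets[[d]])]
  }, numeric(length(common)))
  if (length(common) == 1L) cors <- matrix(cors, nrow = 1L, dimnames = list(NULL, labels))
  sp <- strsplit(common, "\r", fixed = TRUE)
  pairs <- data.frame(miRNA = vapply(sp, `[[`, "", 1L),
                      mRNA = vapply(sp, `[[`, "", 2L), stringsAsFactors = FALSE)
  rownames(cors) <- common
  structure(list(cor = cors, flags = flags, pairs = pairs),
            class = "pair_matrix")
}

#' k-means clustering of pair correlation profiles
#'
#' Lloyd's algorithm with `n_init` random restarts under a fixed seed, on
#' the rows (pairs) of the correlation matrix. Cluster centers are mean
#' correlation profiles across datasets.
#'
#' @param m `pair_matrix` from [build_pair_matrix()], or a plain numeric
#'   matrix (rows = pairs, columns = datasets).
#' @param k number of clusters (default 4).
#' @param n_init number of random restarts.
#' @param seed RNG seed for the restarts.
#' @param iter_max maximum Lloyd iterations.
#' @return a `stats::kmeans` object (`cluster`, `centers`, `tot.withinss`,
#'   ...).
#' @export
cluster_pairs <- function(m, k = 4L, n_init = 10L, seed = 1L, iter_max = 100L) {
  x <- if (inherits(m, "pair_matrix")) m$cor else as.matrix(m)
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of pairs (", nrow(x), ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  suppressWarnings(stats::kmeans(x, centers = k, nstart = n_init,
                                 iter.max = iter_max, algorithm = "Lloyd"))
}

#' Hierarchical clustering and PCA of datasets from cluster centers
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' the dataset columns of the center matrix, and PCA of the datasets on
#' standardized center profiles (i.e. computed from the correlation
#' matrix of the variables).
#'
#' @param centers clusters x datasets matrix (e.g. `$centers` from
#'   [cluster_pairs()]).
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `hclust` and `pca` (a `prcomp` object; datasets are
#'   the observations).
#' @export
cluster_datasets <- function(centers, linkage = "average") {
  centers <- as.matrix(centers)
  if (ncol(centers) < 3L) stop("need at least 3 datasets for a meaningful tree")
  hc <- stats::hclust(stats::dist(t(centers)), method = linkage)
  prof <- t(centers)                       # datasets x clusters
  sds <- apply(prof, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant profile(s) before PCA")
    prof <- prof[, sds > 0, drop = FALSE]
  }
  pca <- stats::prcomp(prof, center = TRUE, scale. = TRUE)
  list(hclust = hc, pca = pca)
}
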