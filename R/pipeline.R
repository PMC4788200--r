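# File-to-file orchestration: reads the standard input files, runs the
# fitting function stage by stage, writes every intermediate as TSV plus a
# manifest with row counts and checksums, and renders an HTML report whose
# every number is re-derivable from those TSVs. A failing stage aborts
# with the stage name; outputs of the failed stage are left with a
# .partial suffix.

pipeline_defaults <- function() {
  list(scale = "log2", min_median = 10, control = NULL, case = NULL,
       de_method = "modt", cor_method = "pearson", alpha = 0.05,
       sig_on = "adj.pval", adjust = "BH", min_dat_sum = 1L,
       trend = FALSE, gmt = NULL, enrich_min_set = 5L, seed = 1L,
       report = TRUE)
}

#' Run the full analysis pipeline from files
#'
#' @param config a named list, or the path of a YAML file, with fields:
#'   `mirna`, `mrna`, `pheno` (input paths), `control`, `case` (group
#'   labels), `outdir`, `databases` (named list of pair-list paths), and
#'   optionally `scale` (`"log2"`, or `"raw_counts"` to median-filter and
#'   log2-transform first), `min_median`, `de_method`, `cor_method`,
#'   `alpha`, `sig_on`, `adjust`, `min_dat_sum`, `trend`, `gmt`
#'   (gene-set collection for enrichment), `enrich_min_set`, `seed`,
#'   `report`.
#' @return the output directory, invisibly. All stage outputs are TSVs;
#'   `manifest.tsv` lists each with its row count and MD5 checksum.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  for (f in c("mirna", "mrna", "pheno", "outdir"))
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
  for (p in c(cfg$mirna, cfg$mrna, cfg$pheno, unlist(cfg$databases), cfg$gmt))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$outdir, name)
    tmp <- paste0(path, ".partial")
    writer(tmp)
    file.rename(tmp, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ds <- stage("core_data", {
    mir <- read_expression(cfg$mirna, scale = cfg$scale)
    mrn <- read_expression(cfg$mrna, scale = cfg$scale)
    if (cfg$scale == "raw_counts") {
      mir <- log2_transform(filter_low_expression(mir, cfg$min_median))
      mrn <- log2_transform(filter_low_expression(mrn, cfg$min_median))
    }
    ph <- read_phenotype(cfg$pheno, control = cfg$control, case = cfg$case)
    d <- align_dataset(mir, mrn, ph)
    emit("mirna_aligned.tsv", function(p) write_expression(d$mirna, p))
    emit("mrna_aligned.tsv", function(p) write_expression(d$mrna, p))
    emit("phenotype.tsv", function(p)
      utils::write.table(data.frame(sample = names(d$pheno),
                                    group = as.character(d$pheno)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    d
  })

  dbs <- stage("target_db", lapply(names(cfg$databases), function(nm)
    load_target_db(cfg$databases[[nm]], name = nm)))

  fit <- stage("fit", mirlink(
    ds, databases = dbs, de_method = cfg$de_method,
    cor_method = cfg$cor_method, alpha = cfg$alpha, sig_on = cfg$sig_on,
    adjust = cfg$adjust, min_dat_sum = cfg$min_dat_sum, trend = cfg$trend,
    n_perm = if (is.null(cfg$n_perm)) 500L else cfg$n_perm))

  stage("diffexp", {
    emit("de_mirna.tsv", function(p) write_diffexp(fit$de_mirna, p))
    emit("de_mrna.tsv", function(p) write_diffexp(fit$de_mrna, p))
  })
  stage("pairwise_corr", {
    emit("correlation_pairs.tsv", function(p) write_pair_table(fit$pairs, p))
    emit("significant_pairs.tsv", function(p) write_pair_table(fit$significant, p))
  })

  if (length(dbs) == 0L) {
    message("pipeline stopped after the correlation stage: ",
            "no target databases configured")
    write_manifest(cfg$outdir, outputs)
    return(invisible(cfg$outdir))
  }

  stage("target_integration", {
    emit("combined_interactions.tsv", function(p) write_combined(fit$combined, p))
    pred <- intersect_with_targets(fit$pairs, fit$de_mirna, fit$de_mrna,
                                   dbs, min_dat_sum = 1L)
    venn <- data.frame(
      quantity = c("significant_negative", "predicted_any_db", "intersection"),
      count = c(nrow(fit$significant), nrow(pred), nrow(fit$combined)))
    emit("intersection_summary.tsv", function(p)
      utils::write.table(venn, p, sep = "\t", quote = FALSE, row.names = FALSE))
    cs <- count_summaries(fit$combined, expressed_mrnas = nrow(ds$mrna))
    emit("targets_per_mirna.tsv", function(p)
      utils::write.table(cs$targets_per_mirna, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("mirnas_per_mrna.tsv", function(p)
      utils::write.table(data.frame(category = names(cs$mirnas_per_mrna),
                                    count = as.integer(cs$mirnas_per_mrna)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("cumulative_coverage.tsv", function(p)
      utils::write.table(cs$cumulative_coverage, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  stage("network_export", {
    if (nrow(fit$combined)) {
      net <- build_network(fit$combined)
      export_sif(net, file.path(cfg$outdir, "network"))
      outputs <- c(outputs, file.path(cfg$outdir,
        c("network.sif", "network.node_attrs.tsv", "network.edge_attrs.tsv")))
    }
  })

  if (!is.null(cfg$gmt)) stage("enrichment", {
    gsc <- read_gmt(cfg$gmt)
    res <- enrich(unique(fit$combined$mRNA), gsc,
                  universe = rownames(ds$mrna), min_set = cfg$enrich_min_set)
    emit("enrichment.tsv", function(p)
      utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE))
  })

  write_manifest(cfg$outdir, outputs)
  if (isTRUE(cfg$report))
    stage("report", make_report(cfg$outdir))
  invisible(cfg$outdir)
}

count_rows <- function(path) {
  n <- length(readLines(path))
  if (grepl("\\.sif$", path)) n else max(n - 1L, 0L)  # header line
}

write_manifest <- function(outdir, outputs) {
  man <- data.frame(
    file = basename(outputs),
    rows = vapply(outputs, count_rows, numeric(1)),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  utils::write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' PCA of samples from an expression matrix
#'
#' Principal components of the samples computed from the correlation
#' matrix of the features (standardized variables); constant features are
#' dropped.
#'
#' @param m feature-by-sample matrix.
#' @param k number of components to return.
#' @return list with `coords` (sample coordinates) and `var_explained`.
#' @export
sample_pca <- function(m, k = 2L) {
  keep <- apply(m, 1L, stats::sd) > 0
  pr <- stats::prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  k <- min(k, ncol(pr$x))
  list(coords = data.frame(sample = rownames(pr$x), pr$x[, seq_len(k), drop = FALSE],
                           row.names = NULL),
       var_explained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)])
}
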