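# Standardised HTML report over a pipeline output directory. Section order
# mirrors the classic analysis report: data summary & sample PCA,
# differential expression, correlation summary, database intersection, top
# interactions, network, per-feature target tables, coverage, enrichment.
# Every printed number is read back from the stage TSVs, never recomputed
# from memory, so the report and the files cannot disagree.

h_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

h_table <- function(df, max_rows = 50L, digits = 4) {
  df <- utils::head(df, max_rows)
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else h_esc(as.character(v))
  cells <- vapply(df, function(v) as.character(fmt(v)), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  rows <- apply(cells, 1L, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>"))
  paste0("<table><tr><th>", paste(h_esc(names(df)), collapse = "</th><th>"),
         "</th></tr>", paste(rows, collapse = ""), "</table>")
}

read_out <- function(outdir, name) {
  p <- file.path(outdir, name)
  if (!file.exists(p)) return(NULL)
  as.data.frame(data.table::fread(p, sep = "\t", header = TRUE))
}

not_computed <- "<p class=\"missing\">not computed</p>"

#' Render the standard HTML report for a pipeline output directory
#'
#' @param outdir directory written by [run_pipeline()].
#' @param file output HTML path (default `report.html` inside `outdir`).
#' @return invisibly, a list with the HTML path and the numeric tables
#'   each section was rendered from.
#' @export
make_report <- function(outdir, file = file.path(outdir, "report.html")) {
  data <- list()
  secs <- character(0)
  add <- function(title, body) {
    secs <<- c(secs, paste0("<h2>", h_esc(title), "</h2>\n", body))
  }

  # 1. data summary and sample PCA
  mir <- read_out(outdir, "mirna_aligned.tsv")
  mrn <- read_out(outdir, "mrna_aligned.tsv")
  ph <- read_out(outdir, "phenotype.tsv")
  if (!is.null(mir) && !is.null(mrn) && !is.null(ph)) {
    mm <- as.matrix(mir[-1L]); rownames(mm) <- mir[[1L]]
    pca <- sample_pca(mm)
    data$dims <- c(n_mirna = nrow(mir), n_mrna = nrow(mrn), n_samples = ncol(mir) - 1L)
    body <- paste0(
      "<p>", nrow(mir), " miRNAs, ", nrow(mrn), " mRNAs, ", ncol(mir) - 1L,
      " samples (", paste(names(table(ph$group)), table(ph$group),
                          sep = "=", collapse = ", "), ").</p>",
      "<p>miRNA sample PCA (correlation matrix), variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_along(pca$var_explained),
                    100 * pca$var_explained), collapse = ", "), "</p>",
      h_table(pca$coords, max_rows = 20L))
    data$sample_pca <- pca
    add("Data summary and sample PCA", body)
  } else add("Data summary and sample PCA", not_computed)

  # 2. differential expression (top 50 by FDR)
  de1 <- read_out(outdir, "de_mirna.tsv"); de2 <- read_out(outdir, "de_mrna.tsv")
  if (!is.null(de1) && !is.null(de2)) {
    top_de <- function(d) utils::head(d[order(d$adj.pval, d$pval, d$feature), ], 50L)
    data$de_top_mirna <- top_de(de1); data$de_top_mrna <- top_de(de2)
    add("Differential expression",
        paste0("<h3>Top miRNAs by FDR</h3>", h_table(data$de_top_mirna),
               "<h3>Top mRNAs by FDR</h3>", h_table(data$de_top_mrna)))
  } else add("Differential expression", not_computed)

  # 3. correlation summary
  corr <- read_out(outdir, "correlation_pairs.tsv")
  if (!is.null(corr)) {
    cut_tab <- data.frame(
      cutoff = c("p<0.05", "p<0.01", "FDR<0.05", "FDR<0.01"),
      count = c(sum(corr$pval < 0.05), sum(corr$pval < 0.01),
                sum(corr$adj.pval < 0.05), sum(corr$adj.pval < 0.01)))
    cut_tab$percent <- round(100 * cut_tab$count / nrow(corr), 2)
    data$correlation <- list(total = nrow(corr), cutoffs = cut_tab)
    add("Correlation analysis",
        paste0("<p>Total correlations computed: ", nrow(corr), "</p>",
               h_table(cut_tab)))
  } else add("Correlation analysis", not_computed)

  # 4. intersection with target predictions
  venn <- read_out(outdir, "intersection_summary.tsv")
  if (!is.null(venn)) {
    data$intersection <- venn
    add("Intersection with target predictions", h_table(venn))
  } else add("Intersection with target predictions", not_computed)

  # 5. top interactions
  comb <- read_out(outdir, "combined_interactions.tsv")
  if (!is.null(comb)) {
    data$top_interactions <- top_interactions(comb, n = 15L)
    add("Top interactions", h_table(data$top_interactions, max_rows = 15L))
  } else add("Top interactions", not_computed)

  # 6. network
  nodes <- read_out(outdir, "network.node_attrs.tsv")
  edges <- read_out(outdir, "network.edge_attrs.tsv")
  if (!is.null(nodes) && !is.null(edges)) {
    data$network <- c(n_nodes = nrow(nodes), n_edges = nrow(edges))
    add("Network", paste0(
      "<p>", nrow(nodes), " nodes (", sum(nodes$kind == "miRNA"), " miRNA / ",
      sum(nodes$kind == "mRNA"), " mRNA), ", nrow(edges), " edges.</p>"))
  } else add("Network", not_computed)

  # 7. per-feature target tables
  tpm <- read_out(outdir, "targets_per_mirna.tsv")
  if (!is.null(tpm) && !is.null(comb)) {
    per_mrna <- as.data.frame(table(comb$mRNA), stringsAsFactors = FALSE)
    names(per_mrna) <- c("mRNA", "n_miRNAs")
    per_mrna <- per_mrna[order(-per_mrna$n_miRNAs, per_mrna$mRNA), ]
    data$targets_per_mirna <- tpm
    add("Targets per miRNA and miRNAs per mRNA",
        paste0("<h3>miRNAs by number of targets</h3>", h_table(tpm, 20L),
               "<h3>mRNAs by number of regulating miRNAs</h3>",
               h_table(per_mrna, 20L)))
  } else add("Targets per miRNA and miRNAs per mRNA", not_computed)

  # 8. coverage
  pie <- read_out(outdir, "mirnas_per_mrna.tsv")
  cov <- read_out(outdir, "cumulative_coverage.tsv")
  if (!is.null(pie) && !is.null(cov)) {
    data$pie <- pie; data$coverage <- cov
    add("Target coverage", paste0(
      "<h3>mRNAs regulated by 0,1,...,5,&gt;5 miRNAs</h3>", h_table(pie, 7L),
      "<h3>Cumulative coverage (first 20 miRNAs)</h3>", h_table(cov, 20L)))
  } else add("Target coverage", not_computed)

  # 9. enrichment
  enr <- read_out(outdir, "enrichment.tsv")
  if (!is.null(enr)) {
    data$enrichment <- enr
    add("Functional enrichment", h_table(enr, 25L))
  } else add("Functional enrichment", not_computed)

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>miRNA-mRNA interactome report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px}.missing{color:#a00}</style>",
    "</head><body><h1>miRNA-mRNA interactome report</h1>\n",
    paste(secs, collapse = "\n"), "</body></html>")
  writeLines(html, file)
  invisible(list(file = file, data = data))
}
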