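# Interaction network construction and Cytoscape export. Nodes carry kind
# (miRNA/mRNA) and deregulation direction; edges carry score, database
# support and adjusted p. Shapes and colours are left to a Cytoscape style
# file -- the attributes are the testable contract (a reasonable default
# style: miRNA = square, up-regulated = red, down-regulated = green).

#' Build an interaction network from a combined table
#'
#' Edges are the top `max_edges` rows under the selector (default:
#' ascending adjusted p with the [top_interactions()] tie-break). Node
#' direction is the sign of the feature's log ratio: `up`, `down` or
#' `flat`.
#'
#' @param combined combined table from [intersect_with_targets()].
#' @param max_edges maximum number of edges to keep.
#' @param sort_key,decreasing edge selector, see [top_interactions()].
#' @return object of class `interaction_network`: list with `nodes`
#'   (`id`, `kind`, `logratio`, `direction`) and `edges` (`miRNA`, `mRNA`,
#'   `score`, `dat.sum`, `adj.pval`).
#' @export
build_network <- function(combined, max_edges = nrow(combined),
                          sort_key = "adj.pval", decreasing = FALSE) {
  if (max_edges < 1L) stop("max_edges must be at least 1")
  top <- top_interactions(combined, n = max_edges, sort_key = sort_key,
                          decreasing = decreasing)
  top <- top[!duplicated(pair_key(top$miRNA, top$mRNA)), , drop = FALSE]
  edges <- data.frame(
    miRNA = top$miRNA, mRNA = top$mRNA,
    score = top$score, dat.sum = top$dat.sum, adj.pval = top$adj.pval,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  node_part <- function(ids, kind, lr) {
    keep <- !duplicated(ids)
    data.frame(id = ids[keep], kind = kind, logratio = lr[keep],
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_part(top$miRNA, "miRNA", top$logratio.miRNA),
                 node_part(top$mRNA, "mRNA", top$logratio.mRNA))
  nodes$direction <- ifelse(nodes$logratio > 0, "up",
                            ifelse(nodes$logratio < 0, "down", "flat"))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", nrow(x$edges), "edges,", nrow(x$nodes),
      "nodes (", sum(x$nodes$kind == "miRNA"), "miRNA /",
      sum(x$nodes$kind == "mRNA"), "mRNA )\n")
  invisible(x)
}

#' Export a network in Cytoscape SIF format with attribute tables
#'
#' Writes `<prefix>.sif` (tab-delimited `miRNA regulates mRNA` triples),
#' `<prefix>.node_attrs.tsv` (id, kind, logratio, direction) and
#' `<prefix>.edge_attrs.tsv` (edge key `"mirna (regulates) mrna"`, score,
#' dat.sum, adj.pval). Line order is sorted, so re-export is byte-identical.
#'
#' @param net network from [build_network()].
#' @param path_prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
export_sif <- function(net, path_prefix) {
  if (nrow(net$edges) == 0L) stop("cannot export an empty network")
  e <- net$edges[order(net$edges$miRNA, net$edges$mRNA), , drop = FALSE]
  nd <- net$nodes[order(net$nodes$kind, net$nodes$id), , drop = FALSE]
  sif <- paste0(path_prefix, ".sif")
  nodef <- paste0(path_prefix, ".node_attrs.tsv")
  edgef <- paste0(path_prefix, ".edge_attrs.tsv")
  writeLines(paste(e$miRNA, "regulates", e$mRNA, sep = "\t"), sif)
  utils::write.table(nd, nodef, sep = "\t", quote = FALSE, row.names = FALSE)
  ea <- data.frame(edge = sprintf("%s (regulates) %s", e$miRNA, e$mRNA),
                   score = e$score, dat.sum = e$dat.sum, adj.pval = e$adj.pval,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(ea, edgef, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif = sif, nodes = nodef, edges = edgef))
}

#' Read a SIF file back as an edge table
#'
#' Minimal parser for round-tripping: returns the source/relation/target
#' triples of a `.sif` file.
#'
#' @param path SIF file path.
#' @export
read_sif <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed SIF line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  data.frame(source = vapply(parts, `[[`, "", 1L),
             relation = vapply(parts, `[[`, "", 2L),
             target = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
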