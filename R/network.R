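#' Build the gene-pair association network of a signature
#'
#' Genes become nodes, signature pairs become directed edges. Each edge
#' points from the gene with the higher mean expression in the designated
#' positive class to the lower one, and carries the pair's random-forest
#' importance as weight. Nodes carry their degree (number of incident
#' signature pairs) and the per-class mean expression; vertices are ordered
#' by descending degree so the hub gene is listed first.
#'
#' @param sig An `aigps_signature`.
#' @param X Expression matrix containing every signature gene.
#' @param labels Named factor of class labels for the samples of `X`.
#' @param positive_class Class whose mean expression orients the edges;
#'   defaults to the signature's first class.
#' @return An `igraph` directed graph with vertex attributes `degree` and
#'   `mean_expr_<class>` and edge attributes `importance`, `p_value`.
#' @export
build_network <- function(sig, X, labels, positive_class = NULL) {
  genes <- unique(c(sig$pairs$gene_a, sig$pairs$gene_b))
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0L) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- droplevels(labels[colnames(X)])
  if (is.null(positive_class)) positive_class <- sig$class_order[1L]
  if (!positive_class %in% levels(lab)) {
    stop("positive class '", positive_class, "' absent from labels",
         call. = FALSE)
  }
  class_means <- sapply(levels(lab), function(cl) {
    rowMeans(X[genes, lab == cl, drop = FALSE])
  })
  pos_mean <- class_means[, positive_class]
  from_a <- pos_mean[sig$pairs$gene_a] >= pos_mean[sig$pairs$gene_b]
  edges <- data.frame(
    from = ifelse(from_a, sig$pairs$gene_a, sig$pairs$gene_b),
    to = ifelse(from_a, sig$pairs$gene_b, sig$pairs$gene_a),
    importance = sig$pairs$importance,
    p_value = sig$pairs$p_value,
    stringsAsFactors = FALSE)
  deg <- table(factor(c(sig$pairs$gene_a, sig$pairs$gene_b), levels = genes))
  vorder <- genes[order(-as.integer(deg), genes)]
  vertices <- data.frame(name = vorder,
                         degree = as.integer(deg[vorder]),
                         stringsAsFactors = FALSE)
  for (cl in levels(lab)) {
    vertices[[paste0("mean_expr_", cl)]] <- class_means[vorder, cl]
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export a pair network
#'
#' @param graph Network from [build_network()].
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"` (TSV with columns `gene_a`,
#'   `gene_b`, `importance`, `p_value`).
#' @export
write_network <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(graph, what = "edges")
    names(ed)[1:2] <- c("gene_a", "gene_b")
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
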