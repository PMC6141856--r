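#' Retain the most variant genes
#'
#' Ranks genes by sample variance (denominator n - 1) and keeps the top
#' `floor(fraction * n_genes)`. Ties are broken by gene-identifier
#' lexicographic order so the retained set is deterministic. The default
#' keeps the top half, the conventional pre-filter before network
#' construction (12,413 genes -> 6,206).
#'
#' @param expr genes x samples numeric matrix.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param drop optional character vector of sample identifiers to remove
#'   beforehand (manual outlier list).
#' @return list with `expr` (filtered matrix) and `report` (data.frame of
#'   all input genes with variance, rank and retained flag, plus
#'   attributes `nInput`/`nRetained`).
#' @export
varianceFilter <- function(expr, fraction = 0.5, drop = NULL) {
  if (length(drop)) {
    expr <- expr[, !(colnames(expr) %in% drop), drop = FALSE]
  }
  .checkExpr(expr, minSamples = 2L)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  v <- .rowVars(expr)
  nKeep <- as.integer(floor(fraction * nrow(expr)))
  # order: variance descending, gene id ascending for ties
  ord <- order(-v, rownames(expr), method = "radix")
  keep <- ord[seq_len(nKeep)]
  report <- data.frame(gene_id = rownames(expr), variance = v,
                       rank = match(seq_len(nrow(expr)), ord),
                       retained = seq_len(nrow(expr)) %in% keep,
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "nInput") <- nrow(expr)
  attr(report, "nRetained") <- nKeep
  list(expr = expr[sort(keep), , drop = FALSE], report = report)
}

#' Cluster samples by correlation distance
#'
#' Average-linkage (UPGMA) hierarchical clustering of samples under the
#' distance \eqn{d(s,t) = 1 - r(s,t)}, with r the Pearson correlation over
#' genes — the standard outlier-inspection dendrogram.
#'
#' @param expr genes x samples numeric matrix.
#' @return an [stats::hclust] object over samples.
#' @export
clusterSamples <- function(expr) {
  .checkExpr(expr, minSamples = 2L)
  sv <- apply(expr, 2, stats::sd)
  zero <- colnames(expr)[sv == 0]
  if (length(zero)) {
    stop("zero-variance sample(s), correlation undefined: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(expr))
  stats::hclust(d, method = "average")
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths are the merge-height differences along each edge
#' (via the standard hclust -> phylo conversion).
#'
#' @param hc an [stats::hclust] object.
#' @param path output path; if `NULL`, the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogramToNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
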