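#' Cluster genes on the TOM dissimilarity
#'
#' Average-linkage (UPGMA) hierarchical clustering of genes under
#' `1 - TOM`. Genes with high topological overlap merge at low heights
#' and form the branches that the tree cut turns into modules.
#'
#' @param network a [CoexpressionNetwork-class], or a symmetric TOM matrix.
#' @return an [stats::hclust] object over genes.
#' @export
clusterGenes <- function(network) {
  tom <- if (is(network, "CoexpressionNetwork")) tomMatrix(network) else network
  if (!is.matrix(tom) || nrow(tom) != ncol(tom) || nrow(tom) < 2) {
    stop("need a square TOM matrix over at least 2 genes", call. = FALSE)
  }
  d <- 1 - tom
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Cut the gene dendrogram into modules
#'
#' Static branch cut: the tree is cut at
#' `cutHeightFraction * max(merge height)`; every resulting branch with at
#' least `minModuleSize` leaves becomes a module, all other genes are
#' labelled "grey" (unassigned). Module labels are colour names assigned
#' in decreasing order of size.
#'
#' This is the "tree" (static-cut) variant of dendrogram module
#' detection; the hybrid variant with adaptive break-point detection and
#' eigengene-based reassignment is deliberately not implemented (see the
#' methods vignette for the fidelity implications).
#'
#' @param dend an [stats::hclust] object from [clusterGenes()].
#' @param minModuleSize smallest branch accepted as a module (default 30).
#' @param cutHeightFraction fraction of the maximum merge height at which
#'   the tree is cut (default 0.99).
#' @return a [ModuleAssignment-class].
#' @export
cutModules <- function(dend, minModuleSize = 30L, cutHeightFraction = 0.99) {
  if (!inherits(dend, "hclust")) stop("dend must be an hclust object", call. = FALSE)
  if (minModuleSize < 2) stop("minModuleSize must be >= 2", call. = FALSE)
  if (cutHeightFraction <= 0 || cutHeightFraction > 1) {
    stop("cutHeightFraction must lie in (0,1]", call. = FALSE)
  }
  # UPGMA merge heights are mathematically non-decreasing, but ties can
  # produce sub-epsilon inversions that cutree rejects; clamp them
  if (is.unsorted(dend$height)) {
    fixed <- cummax(dend$height)
    if (max(fixed - dend$height) > 1e-8) {
      stop("dendrogram heights are not non-decreasing", call. = FALSE)
    }
    dend$height <- fixed
  }
  h <- cutHeightFraction * max(dend$height)
  raw <- stats::cutree(dend, h = h)
  genes <- dend$labels
  if (is.null(genes)) genes <- as.character(seq_along(raw))
  sz <- table(raw)
  big <- names(sz)[sz >= minModuleSize]
  labels <- rep("grey", length(raw))
  if (length(big)) {
    ord <- big[order(-sz[big], as.integer(big))]
    for (i in seq_along(ord)) {
      labels[raw == as.integer(ord[i])] <- .moduleColor(i)
    }
  }
  new("ModuleAssignment", genes = genes, labels = labels,
      minModuleSize = as.integer(minModuleSize))
}

#' Write a module assignment as TSV
#'
#' @param assign a [ModuleAssignment-class].
#' @param path output path.
#' @export
writeModuleAssignment <- function(assign, path) {
  utils::write.table(
    data.frame(gene_id = assign@genes, module = assign@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module assignment from TSV
#'
#' @param path path to a two-column (gene_id, module) TSV.
#' @param minModuleSize size floor recorded on the object.
#' @return a [ModuleAssignment-class].
#' @export
readModuleAssignment <- function(path, minModuleSize = 2L) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  new("ModuleAssignment", genes = as.character(d$gene_id),
      labels = as.character(d$module),
      minModuleSize = as.integer(minModuleSize))
}
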