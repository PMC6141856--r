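#' Module membership (kME)
#'
#' Correlation of every gene's expression with every module eigengene,
#' with two-sided t-based p-values. A gene's membership in its own module
#' (|kME|) measures its intramodular connectivity.
#'
#' @param expr genes x samples numeric matrix.
#' @param me samples x modules eigengene matrix from [moduleEigengenes()].
#' @return list of genes x modules matrices `cor` and `pvalue`.
#' @export
moduleMembership <- function(expr, me) {
  shared <- .alignSamples(colnames(expr), rownames(me), "expression",
                          "eigengenes")
  x <- expr[, shared, drop = FALSE]
  .checkGeneVariance(x)
  r <- stats::cor(t(x), me[shared, , drop = FALSE])
  list(cor = r, pvalue = .corPvalue(r, length(shared)))
}

#' Screen hub genes in the clinically significant module
#'
#' A hub gene is a gene of the screened module with both high
#' intramodular connectivity and high trait association:
#' `|MM| > mmThreshold` and `|geneTraitCor| > gsThreshold`, strict
#' inequalities (default 0.8 and 0.2). GS here is on the correlation
#' scale (`cor.geneTraitSignificance`). Rows are ordered by decreasing
#' |MM| with gene-identifier tie-break.
#'
#' @param expr genes x samples numeric matrix.
#' @param assign a [ModuleAssignment-class].
#' @param relation a [ModuleTraitResult-class] from
#'   [relateModulesToTraits()]; supplies the eigengenes, the designated
#'   trait's per-gene correlation, and the default module.
#' @param module module to screen; default the clinically significant one.
#' @param mmThreshold module-membership cut-off in \[0,1\].
#' @param gsThreshold gene-trait-correlation cut-off in \[0,1\].
#' @return data.frame (one row per gene of the screened module) with
#'   `gene_id`, `module`, `MM`, `MM_pvalue`, `geneTraitCor`,
#'   `geneTraitPvalue`, `isHub`; hub count in `attr(, "nHubs")`.
#' @export
screenHubGenes <- function(expr, assign, relation,
                           module = significantModule(relation),
                           mmThreshold = 0.8, gsThreshold = 0.2) {
  if (any(c(mmThreshold, gsThreshold) < 0) ||
      any(c(mmThreshold, gsThreshold) > 1)) {
    stop("thresholds must lie in [0,1]", call. = FALSE)
  }
  lab <- moduleLabels(assign)
  if (!module %in% lab) stop("unknown module label: ", module, call. = FALSE)
  genes <- names(lab)[lab == module]
  genes <- genes[genes %in% rownames(expr)]
  me <- eigengenes(relation)
  col <- paste0("ME", module)
  if (!col %in% colnames(me)) {
    stop("no eigengene for module: ", module, call. = FALSE)
  }
  mm <- moduleMembership(expr[genes, , drop = FALSE],
                         me[, col, drop = FALSE])
  gs <- relation@geneSignificance
  gs <- gs[match(genes, gs$gene_id), ]
  out <- data.frame(gene_id = genes, module = module,
                    MM = as.numeric(mm$cor),
                    MM_pvalue = as.numeric(mm$pvalue),
                    geneTraitCor = gs$cor,
                    geneTraitPvalue = gs$pvalue,
                    stringsAsFactors = FALSE)
  out$isHub <- abs(out$MM) > mmThreshold & abs(out$geneTraitCor) > gsThreshold
  out <- out[order(-abs(out$MM), out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "nHubs") <- sum(out$isHub)
  attr(out, "thresholds") <- c(MM = mmThreshold, GS = gsThreshold)
  out
}
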