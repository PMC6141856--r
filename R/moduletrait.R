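#' Module eigengene
#'
#' The module eigengene (ME) is the first principal component of the
#' module's standardized expression: genes are scaled to mean 0, sd 1
#' across samples, and the ME is the leading right singular vector of the
#' resulting genes x samples matrix (unit-normalized, one value per
#' sample). Its sign is fixed so that the ME correlates positively with
#' the mean standardized module expression.
#'
#' @param expr genes x samples numeric matrix.
#' @param assign a [ModuleAssignment-class] covering `expr`'s genes, or a
#'   named gene -> label vector.
#' @param module module label to summarise.
#' @return named numeric vector, one ME value per sample.
#' @export
moduleEigengene <- function(expr, assign, module) {
  lab <- if (is(assign, "ModuleAssignment")) moduleLabels(assign) else assign
  genes <- names(lab)[lab == module]
  genes <- genes[genes %in% rownames(expr)]
  if (length(genes) < 2) {
    stop("module '", module, "' has fewer than 2 genes in the matrix",
         call. = FALSE)
  }
  x <- expr[genes, , drop = FALSE]
  .checkGeneVariance(x)
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  me <- sv$v[, 1]
  if (stats::cor(me, colMeans(xs)) < 0) me <- -me
  stats::setNames(me, colnames(expr))
}

#' All module eigengenes
#'
#' @inheritParams moduleEigengene
#' @param includeGrey also compute an eigengene for the unassigned genes.
#' @return samples x modules matrix; columns named `ME<label>`, ordered by
#'   decreasing module size.
#' @export
moduleEigengenes <- function(expr, assign, includeGrey = FALSE) {
  sz <- moduleSizes(assign, countGrey = FALSE)
  mods <- sz$module
  if (includeGrey && sum(moduleLabels(assign) == "grey") >= 2) {
    mods <- c(mods, "grey")
  }
  if (!length(mods)) stop("no modules to summarise", call. = FALSE)
  me <- vapply(mods, function(m) moduleEigengene(expr, assign, m),
               numeric(ncol(expr)))
  colnames(me) <- paste0("ME", mods)
  rownames(me) <- colnames(expr)
  me
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation of each ME with each trait, with two-sided
#' p-values from the t distribution
#' (\eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}, n - 2 df). The module with the
#' largest absolute correlation against `trait` is flagged as the
#' clinically significant module.
#'
#' @param me samples x modules eigengene matrix from [moduleEigengenes()].
#' @param traits samples x traits numeric matrix; samples aligned with the
#'   eigengenes by identifier (intersection).
#' @param trait name of the designated trait (default: first column).
#' @return list with `correlation`, `pvalue` (modules x traits matrices)
#'   and `significantModule` (label, "ME" prefix stripped).
#' @export
moduleTraitCorrelation <- function(me, traits, trait = colnames(traits)[1]) {
  if (is.null(rownames(me)) || is.null(rownames(traits))) {
    stop("eigengene and trait matrices must have sample rownames", call. = FALSE)
  }
  if (!trait %in% colnames(traits)) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  shared <- .alignSamples(rownames(me), rownames(traits),
                          "eigengenes", "traits")
  me <- me[shared, , drop = FALSE]
  traits <- traits[shared, , drop = FALSE]
  const <- colnames(traits)[apply(traits, 2, stats::sd) == 0]
  if (length(const)) {
    stop("constant trait(s): ", paste(const, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(me, traits)
  p <- .corPvalue(r, length(shared))
  sig <- rownames(r)[which.max(abs(r[, trait]))]
  list(correlation = r, pvalue = p,
       significantModule = sub("^ME", "", sig))
}

#' Gene significance for a clinical trait
#'
#' Association of each gene's expression with a trait vector. In
#' `"correlation"` mode GS is the absolute Pearson correlation; in
#' `"neglogp"` mode GS is \eqn{-\log_{10}(p)} of the same correlation
#' test. The signed correlation and p-value are always returned alongside.
#'
#' @param expr genes x samples numeric matrix.
#' @param trait named numeric vector (one value per sample) or one-column
#'   matrix.
#' @param mode `"correlation"` (default) or `"neglogp"`.
#' @return data.frame with `gene_id`, `cor`, `pvalue`, `GS`.
#' @export
geneSignificance <- function(expr, trait, mode = c("correlation", "neglogp")) {
  mode <- match.arg(mode)
  if (is.matrix(trait)) trait <- stats::setNames(trait[, 1], rownames(trait))
  if (is.null(names(trait))) {
    stop("trait vector must carry sample names", call. = FALSE)
  }
  shared <- .alignSamples(colnames(expr), names(trait), "expression", "trait")
  x <- expr[, shared, drop = FALSE]
  .checkGeneVariance(x)
  tv <- trait[shared]
  if (stats::sd(tv) == 0) stop("trait is constant", call. = FALSE)
  r <- as.numeric(stats::cor(t(x), tv))
  p <- .corPvalue(r, length(shared))
  gs <- switch(mode, correlation = abs(r), neglogp = -log10(p))
  data.frame(gene_id = rownames(expr), cor = r, pvalue = as.numeric(p),
             GS = gs, stringsAsFactors = FALSE)
}

#' Module significance
#'
#' MS of a module is the mean absolute gene significance over its genes.
#' The grey (unassigned) pool is reported too, flagged as not a module.
#'
#' @param gs data.frame from [geneSignificance()].
#' @param assign a [ModuleAssignment-class].
#' @return data.frame with `module`, `size`, `MS`, `isModule`.
#' @export
moduleSignificance <- function(gs, assign) {
  lab <- moduleLabels(assign)
  missing <- setdiff(gs$gene_id, names(lab))
  if (length(missing)) {
    stop("assignment does not cover gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  g <- lab[gs$gene_id]
  out <- do.call(rbind, lapply(split(seq_len(nrow(gs)), g), function(idx) {
    data.frame(module = g[idx[1]], size = length(idx),
               MS = mean(abs(gs$GS[idx])), stringsAsFactors = FALSE)
  }))
  out$isModule <- out$module != "grey"
  out <- out[order(-out$isModule, -out$MS), ]
  rownames(out) <- NULL
  out
}

#' Relate modules to traits
#'
#' Orchestrates the module-trait stage: eigengenes, ME-trait correlation
#' with p-values, gene significance in both modes, and module
#' significance, bundled as a [ModuleTraitResult-class].
#'
#' @inheritParams moduleEigengenes
#' @inheritParams moduleTraitCorrelation
#' @param msMode GS flavour feeding the MS summary (default `"neglogp"`,
#'   the -log10 p scale; screening elsewhere uses the correlation scale).
#' @return a [ModuleTraitResult-class].
#' @export
relateModulesToTraits <- function(expr, assign, traits,
                                  trait = colnames(traits)[1],
                                  msMode = c("neglogp", "correlation")) {
  msMode <- match.arg(msMode)
  me <- moduleEigengenes(expr, assign)
  mt <- moduleTraitCorrelation(me, traits, trait)
  tv <- stats::setNames(traits[, trait], rownames(traits))
  gsCor <- geneSignificance(expr, tv, "correlation")
  gsLog <- geneSignificance(expr, tv, "neglogp")
  gs <- data.frame(gene_id = gsCor$gene_id, cor = gsCor$cor,
                   pvalue = gsCor$pvalue, GS_cor = gsCor$GS,
                   GS_neglogp = gsLog$GS, stringsAsFactors = FALSE)
  gsForMs <- if (msMode == "neglogp") gsLog else gsCor
  ms <- moduleSignificance(gsForMs, assign)
  new("ModuleTraitResult", eigengenes = me, correlation = mt$correlation,
      pvalue = mt$pvalue, geneSignificance = gs, moduleSignificance = ms,
      significantModule = mt$significantModule, trait = trait)
}
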