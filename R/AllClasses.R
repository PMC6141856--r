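#' @import methods
NULL

#' Weighted co-expression network
#'
#' Holds the soft-thresholded adjacency matrix, the topological overlap
#' matrix (TOM) derived from it, and the soft-thresholding power used.
#' The adjacency diagonal is stored as 0 so that row sums are the
#' connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}}; the TOM diagonal is 1.
#'
#' @slot genes character vector of gene identifiers (unique, ordered).
#' @slot adjacency symmetric numeric matrix in \[0,1\], zero diagonal.
#' @slot tom symmetric numeric matrix in \[0,1\], unit diagonal.
#' @slot power the soft-thresholding exponent beta.
#'
#' @seealso [softAdjacency()], [tomSimilarity()], [buildNetwork()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(
    genes = "character",
    adjacency = "matrix",
    tom = "matrix",
    power = "numeric"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  msgs <- character()
  n <- length(object@genes)
  if (anyDuplicated(object@genes)) {
    msgs <- c(msgs, "duplicate gene identifiers")
  }
  for (nm in c("adjacency", "tom")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) {
      msgs <- c(msgs, sprintf("%s must be %d x %d", nm, n, n))
      next
    }
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      msgs <- c(msgs, sprintf("%s must be symmetric", nm))
    }
    if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
      msgs <- c(msgs, sprintf("%s entries must lie in [0,1]", nm))
    }
  }
  if (length(object@power) != 1L || object@power < 1) {
    msgs <- c(msgs, "power must be a single value >= 1")
  }
  if (n > 0 && nrow(object@adjacency) == n && any(diag(object@adjacency) != 0)) {
    msgs <- c(msgs, "adjacency diagonal must be 0")
  }
  if (n > 0 && nrow(object@tom) == n && any(abs(diag(object@tom) - 1) > 1e-12)) {
    msgs <- c(msgs, "TOM diagonal must be 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene-to-module assignment
#'
#' Maps each gene to a module label. Labels are colour names assigned in
#' decreasing order of module size (largest module is "turquoise", then
#' "blue", ...); the reserved label "grey" marks unassigned genes and is
#' exempt from the minimum-size floor.
#'
#' @slot genes character vector of gene identifiers.
#' @slot labels character vector of module labels, parallel to `genes`.
#' @slot minModuleSize the size floor used during detection.
#'
#' @seealso [cutModules()], [moduleSizes()]
#' @exportClass ModuleAssignment
setClass("ModuleAssignment",
  representation(
    genes = "character",
    labels = "character",
    minModuleSize = "integer"
  )
)

setValidity("ModuleAssignment", function(object) {
  msgs <- character()
  if (length(object@genes) != length(object@labels)) {
    msgs <- c(msgs, "genes and labels must have equal length")
  }
  if (anyDuplicated(object@genes)) {
    msgs <- c(msgs, "duplicate gene identifiers")
  }
  sz <- table(object@labels[object@labels != "grey"])
  if (length(sz) && length(object@minModuleSize) == 1L &&
      any(sz < object@minModuleSize)) {
    msgs <- c(msgs, "a non-grey module is smaller than minModuleSize")
  }
  if (length(msgs)) msgs else TRUE
})

#' Module-trait relationship results
#'
#' Module eigengenes, their correlations with clinical traits, per-gene
#' trait significance (GS) and per-module significance (MS).
#'
#' @slot eigengenes samples x modules matrix of module eigengene values.
#' @slot correlation modules x traits matrix of Pearson correlations.
#' @slot pvalue modules x traits matrix of two-sided p-values.
#' @slot geneSignificance data.frame with per-gene trait correlation, its
#'   p-value, and GS on both the correlation and -log10(p) scales.
#' @slot moduleSignificance data.frame of per-module MS (mean |GS|).
#' @slot significantModule label of the module with the largest absolute
#'   eigengene-trait correlation against the designated trait.
#' @slot trait name of the designated clinical trait.
#'
#' @exportClass ModuleTraitResult
setClass("ModuleTraitResult",
  representation(
    eigengenes = "matrix",
    correlation = "matrix",
    pvalue = "matrix",
    geneSignificance = "data.frame",
    moduleSignificance = "data.frame",
    significantModule = "character",
    trait = "character"
  )
)

setValidity("ModuleTraitResult", function(object) {
  msgs <- character()
  if (!all(dim(object@correlation) == dim(object@pvalue))) {
    msgs <- c(msgs, "correlation and pvalue must share dimensions")
  }
  if (any(abs(object@correlation) > 1 + 1e-12, na.rm = TRUE)) {
    msgs <- c(msgs, "|correlation| must be <= 1")
  }
  p <- object@pvalue
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "p-values must lie in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth for a simulated dataset
#'
#' Records what the latent-factor simulator planted: the module label of
#' every gene ("grey" for background noise genes), the latent module
#' eigengenes (standardized per module), per-gene factor loadings, the
#' ordinal trait vector, and the generating parameters.
#'
#' @slot moduleLabels named character vector, gene -> planted label.
#' @slot eigengenes modules x samples matrix of latent factors, each row
#'   standardized to mean 0, sd 1.
#' @slot loadings named numeric vector of per-gene loadings (0 for
#'   background genes).
#' @slot trait named numeric vector, the planted ordinal grade per sample.
#' @slot params list of generator parameters (the `simulationConfig()`).
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    moduleLabels = "character",
    eigengenes = "matrix",
    loadings = "numeric",
    trait = "numeric",
    params = "list"
  )
)

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  if (length(object@moduleLabels) != length(object@loadings)) {
    msgs <- c(msgs, "moduleLabels and loadings must have equal length")
  }
  if (nrow(object@eigengenes) > 0) {
    mu <- rowMeans(object@eigengenes)
    sd1 <- apply(object@eigengenes, 1, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sd1 - 1) > 1e-8)) {
      msgs <- c(msgs, "latent eigengenes must be standardized (mean 0, sd 1)")
    }
  }
  if (length(msgs)) msgs else TRUE
})
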