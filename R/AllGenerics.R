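#' Accessors for network and module objects
#'
#' `adjacencyMatrix()`, `tomMatrix()`, `tomDissimilarity()`, `connectivity()`
#' and `softPower()` extract the components of a [CoexpressionNetwork-class];
#' `moduleLabels()` and `moduleSizes()` summarise a
#' [ModuleAssignment-class]; `eigengenes()` returns the sample-by-module
#' eigengene matrix of a [ModuleTraitResult-class].
#'
#' @param object a package S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(object) standardGeneric("tomMatrix"))

#' @rdname accessors
#' @export
setGeneric("tomDissimilarity", function(object) standardGeneric("tomDissimilarity"))

#' @rdname accessors
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' @rdname accessors
#' @export
setGeneric("softPower", function(object) standardGeneric("softPower"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @param countGrey if `TRUE` include the reserved "grey" (unassigned) label.
#' @export
setGeneric("moduleSizes", function(object, countGrey = TRUE) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("significantModule", function(object) standardGeneric("significantModule"))

#' @describeIn accessors adjacency of a network
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(object) object@adjacency)

#' @describeIn accessors TOM of a network
setMethod("tomMatrix", "CoexpressionNetwork", function(object) object@tom)

#' @describeIn accessors 1 - TOM with zero diagonal
setMethod("tomDissimilarity", "CoexpressionNetwork", function(object) {
  d <- 1 - object@tom
  diag(d) <- 0
  d
})

#' @describeIn accessors connectivity vector k (adjacency row sums)
setMethod("connectivity", "CoexpressionNetwork", function(object) {
  k <- rowSums(object@adjacency)
  names(k) <- object@genes
  k
})

#' @describeIn accessors soft-thresholding power beta
setMethod("softPower", "CoexpressionNetwork", function(object) object@power)

#' @describeIn accessors gene identifiers of a network
setMethod("geneIds", "CoexpressionNetwork", function(object) object@genes)

#' @describeIn accessors gene identifiers of an assignment
setMethod("geneIds", "ModuleAssignment", function(object) object@genes)

#' @describeIn accessors named gene -> module label vector
setMethod("moduleLabels", "ModuleAssignment", function(object) {
  stats::setNames(object@labels, object@genes)
})

#' @describeIn accessors module sizes, largest first; grey last if counted
setMethod("moduleSizes", "ModuleAssignment", function(object, countGrey = TRUE) {
  lab <- object@labels
  sz <- table(lab[lab != "grey"])
  sz <- sort(sz, decreasing = TRUE)
  out <- data.frame(
    module = names(sz),
    size = as.integer(sz),
    stringsAsFactors = FALSE
  )
  if (countGrey) {
    out <- rbind(out, data.frame(module = "grey", size = sum(lab == "grey")))
  }
  rownames(out) <- NULL
  out
})

#' @describeIn accessors eigengene matrix (samples x modules)
setMethod("eigengenes", "ModuleTraitResult", function(object) object@eigengenes)

#' @describeIn accessors label of the clinically significant module
setMethod("significantModule", "ModuleTraitResult", function(object) object@significantModule)

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork with", length(object@genes), "genes\n")
  cat("  soft-thresholding power:", object@power, "\n")
  k <- rowSums(object@adjacency)
  cat(sprintf("  connectivity: mean %.3f, median %.3f, max %.3f\n",
              mean(k), stats::median(k), max(k)))
})

setMethod("show", "ModuleAssignment", function(object) {
  sz <- moduleSizes(object, countGrey = FALSE)
  cat("ModuleAssignment:", length(object@genes), "genes,",
      nrow(sz), "modules (min size", object@minModuleSize, "),",
      sum(object@labels == "grey"), "unassigned (grey)\n")
  if (nrow(sz)) {
    hd <- utils::head(sz, 8)
    cat("  ", paste(sprintf("%s(%d)", hd$module, hd$size), collapse = " "),
        if (nrow(sz) > 8) "...\n" else "\n")
  }
})

setMethod("show", "ModuleTraitResult", function(object) {
  cat("ModuleTraitResult:", ncol(object@eigengenes), "module eigengenes x",
      ncol(object@correlation), "trait(s)\n")
  cat("  designated trait:", object@trait, "\n")
  row <- paste0("ME", object@significantModule)
  cat("  clinically significant module:", object@significantModule,
      sprintf("(r = %.3f, p = %.3g)\n",
              object@correlation[row, object@trait],
              object@pvalue[row, object@trait]))
})

setMethod("show", "SyntheticTruth", function(object) {
  lab <- object@moduleLabels
  cat("SyntheticTruth:", length(lab), "genes,",
      nrow(object@eigengenes), "planted modules,",
      sum(lab == "grey"), "background genes\n")
})
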