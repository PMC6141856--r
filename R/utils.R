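# Internal helpers shared across modules.

# Validate a genes x samples expression matrix: numeric, finite, named,
# no duplicate identifiers, at least 2 genes and 3 samples.
.checkExpr <- function(expr, minGenes = 2L, minSamples = 3L) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  dg <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dg)) {
    stop("duplicate gene identifiers: ", paste(unique(dg), collapse = ", "),
         call. = FALSE)
  }
  ds <- colnames(expr)[duplicated(colnames(expr))]
  if (length(ds)) {
    stop("duplicate sample identifiers: ", paste(unique(ds), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(expr))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  if (nrow(expr) < minGenes) {
    stop("need at least ", minGenes, " genes", call. = FALSE)
  }
  if (ncol(expr) < minSamples) {
    stop("need at least ", minSamples, " samples", call. = FALSE)
  }
  invisible(expr)
}

# Stop if any row (gene) has zero variance, naming offenders.
.checkGeneVariance <- function(expr) {
  v <- .rowVars(expr)
  zero <- rownames(expr)[v == 0]
  if (length(zero)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(zero, 5), collapse = ", "),
         if (length(zero) > 5) sprintf(" (and %d more)", length(zero) - 5) else "",
         call. = FALSE)
  }
  invisible(v)
}

# Per-row sample variance with denominator n - 1.
.rowVars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Two-sided p-value for a Pearson correlation from the t distribution:
# t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom.
.corPvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  t <- r[!exact] * sqrt(n - 2) / sqrt(1 - r[!exact]^2)
  p[!exact] <- 2 * stats::pt(-abs(t), df = n - 2)
  dim(p) <- dim(r)
  dimnames(p) <- dimnames(r)
  p
}

# Align two sets of sample identifiers by intersection, preserving the
# order of `ref`; messages the number dropped from each side.
.alignSamples <- function(ref, other, refName = "expression", otherName = "table") {
  shared <- ref[ref %in% other]
  dropRef <- length(ref) - length(shared)
  dropOther <- length(other) - length(shared)
  if (dropRef > 0 || dropOther > 0) {
    message(sprintf("sample alignment: %d dropped from %s, %d from %s; %d shared",
                    dropRef, refName, dropOther, otherName, length(shared)))
  }
  if (length(shared) < 3) {
    stop("fewer than 3 shared samples after identifier alignment", call. = FALSE)
  }
  shared
}

# Ordered module colour vocabulary (largest module first); "grey" is
# reserved for unassigned genes and never appears here.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

# Label i-th largest module; beyond the colour list fall back to module_N.
.moduleColor <- function(i) {
  ifelse(i <= length(MODULE_COLORS),
         MODULE_COLORS[pmin(i, length(MODULE_COLORS))],
         paste0("module_", i))
}
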