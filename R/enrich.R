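#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list
#' against a universe: with a universe of size N containing K set members
#' and a query of size n with x overlapping genes, the p-value is the
#' hypergeometric upper tail \eqn{P(X \ge x)}. P-values are adjusted
#' across all tested sets by Benjamini-Hochberg; the default significance
#' cut-off is adjusted P < 0.001. Sets are intersected with the universe
#' before testing; the conventional universe is the set of genes that
#' survived the variance filter.
#'
#' @param query character vector of genes of interest (e.g. a module's
#'   genes); intersected with the universe.
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of all considered genes.
#' @param alpha adjusted-p significance cut-off (default 0.001).
#' @return data.frame sorted by raw p with `set`, `setSize`, `overlap`,
#'   `querySize`, `universeSize`, `pvalue`, `adjPvalue`, `significant`.
#' @export
oraTest <- function(query, sets, universe, alpha = 0.001) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe intersection", call. = FALSE)
  if (!length(sets)) stop("no gene sets to test", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    x <- length(intersect(s, query))
    p <- if (K == 0) 1 else stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, setSize = K, overlap = x, querySize = n,
               universeSize = N, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjPvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$adjPvalue < alpha
  out <- out[order(out$pvalue, out$set), ]
  rownames(out) <- NULL
  out
}
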