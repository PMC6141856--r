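#' Read a log-scale expression matrix from delimited text
#'
#' Expects one header row of sample (or gene) identifiers and one leading
#' identifier column. The canonical dialect is tab-separated; pass
#' `sep = ","` for CSV. Values must be numeric and complete: missing cells
#' are a hard error unless `impute = TRUE`, in which case they are replaced
#' by the per-gene mean.
#'
#' @param path path to the text file.
#' @param orientation `"genes"` if genes are in rows (default), `"samples"`
#'   if samples are in rows (the matrix is transposed after reading).
#' @param sep field separator.
#' @param impute replace missing values with the per-gene mean instead of
#'   erroring.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path, orientation = c("genes", "samples"),
                                 sep = "\t", impute = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("expected an identifier column plus data columns",
                          call. = FALSE)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate row identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body) & toupper(trimws(body)) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d (%s), column %d (%s)",
                 body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                 bad[1, 2], colnames(body)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(vals) <- list(ids, colnames(body))
  expr <- if (orientation == "samples") t(vals) else vals
  if (anyNA(expr)) {
    if (!impute) {
      miss <- which(is.na(expr), arr.ind = TRUE)
      stop(sprintf("missing value at gene %s, sample %s (use impute = TRUE for per-gene mean imputation)",
                   rownames(expr)[miss[1, 1]], colnames(expr)[miss[1, 2]]),
           call. = FALSE)
    }
    for (i in which(rowSums(is.na(expr)) > 0)) {
      expr[i, is.na(expr[i, ])] <- mean(expr[i, ], na.rm = TRUE)
    }
  }
  .checkExpr(expr)
  expr
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @param sep field separator.
#' @param idColumn name of the leading identifier column.
#' @export
writeExpressionMatrix <- function(expr, path, sep = "\t", idColumn = "gene_id") {
  .writeIdTable(expr, path, sep, idColumn)
}

#' Read a samples x traits table
#'
#' One row per sample, one numeric column per trait; trait encodings
#' (ordinal grade 1-3, binary tumor/normal, continuous) are the caller's.
#'
#' @inheritParams readExpressionMatrix
#' @return numeric matrix, samples in rows, traits in columns.
#' @export
readTraitTable <- function(path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a sample_id column plus trait columns",
                          call. = FALSE)
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("trait values must be numeric", call. = FALSE)
  rownames(vals) <- ids
  vals
}

#' @rdname readTraitTable
#' @param traits samples x traits numeric matrix.
#' @export
writeTraitTable <- function(traits, path, sep = "\t") {
  .writeIdTable(traits, path, sep, "sample_id")
}

#' Read a survival table (sample_id, time, event)
#'
#' @inheritParams readExpressionMatrix
#' @return data.frame with columns `sample_id`, `time` (nonnegative, one
#'   unit throughout) and `event` (1 = event observed, 0 = censored).
#' @export
readSurvivalTable <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(d))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, need]
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(d$time)) || any(d$time < 0)) {
    stop("survival times must be finite and >= 0", call. = FALSE)
  }
  if (!all(d$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  d
}

#' @rdname readSurvivalTable
#' @param surv survival data.frame as returned by [readSurvivalTable()].
#' @export
writeSurvivalTable <- function(surv, path, sep = "\t") {
  utils::write.table(format(surv, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' member...`. Member lists are uniqued (set semantics).
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate gene-set names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(sets) == 0)) {
    stop("GMT contains a set with no members", call. = FALSE)
  }
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description")
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

# Write a numeric matrix with an identifier column at full precision.
.writeIdTable <- function(m, path, sep, idColumn) {
  d <- data.frame(id = rownames(m),
                  format(m, digits = 17, trim = TRUE, scientific = FALSE),
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d)[1] <- idColumn
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
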