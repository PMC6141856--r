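#' Median split of a per-sample score
#'
#' Samples strictly above the median are "high"; ties go to "low", so the
#' high group strictly exceeds the median — the stratification used for
#' survival comparison of a hub gene's expression.
#'
#' @param values named numeric vector (one value per sample).
#' @return factor with levels `low`, `high`, named by sample.
#' @export
medianSplit <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples", call. = FALSE)
  g <- factor(ifelse(values > stats::median(values), "high", "low"),
              levels = c("low", "high"))
  names(g) <- names(values)
  g
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' per group, with censored subjects leaving the risk set after their
#' time (fitted via [survival::survfit()]).
#'
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param groups named group labels per sample; `NULL` for a single group.
#' @return data.frame with `group`, `time`, `nRisk`, `nEvent`, `nCensor`,
#'   `survival`.
#' @export
kaplanMeier <- function(surv, groups = NULL) {
  d <- .alignSurvival(surv, groups)
  fit <- if (is.null(groups)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  } else {
    survival::survfit(survival::Surv(time, event) ~ group, data = d)
  }
  grp <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, nRisk = fit$n.risk,
             nEvent = fit$n.event, nCensor = fit$n.censor,
             survival = fit$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected events per group come from
#' the hypergeometric mean given the risk sets; the chi-square statistic
#' is \eqn{(O-E)^2/V} on 1 df (via [survival::survdiff()]).
#'
#' @inheritParams kaplanMeier
#' @param groups named two-level group labels per sample.
#' @return list with `chisq`, `df`, `pvalue`, `observed`, `expected`
#'   (named per group).
#' @export
logrankTest <- function(surv, groups) {
  d <- .alignSurvival(surv, groups)
  if (nlevels(droplevels(factor(d$group))) != 2) {
    stop("log-rank test needs exactly 2 non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  lev <- sub("^group=", "", names(sd$n))
  list(chisq = unname(sd$chisq), df = 1L,
       pvalue = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = stats::setNames(as.numeric(sd$obs), lev),
       expected = stats::setNames(as.numeric(sd$exp), lev))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability
#' \eqn{P(score_{case} > score_{control}) + \frac12 P(tie)}, computed
#' from midranks; the curve is the (1 - specificity, sensitivity) path
#' over all thresholds (via [pROC::roc()]).
#'
#' @param scores numeric predictor (e.g. a gene's expression).
#' @param labels binary labels, 1/`"tumor"`-like = case; both classes must
#'   be present.
#' @param positive value of `labels` treated as the case class; default
#'   the larger of the two values.
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr` from
#'   (0,0) to (1,1)).
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) stop("labels must contain exactly 2 classes", call. = FALSE)
  if (is.null(positive)) positive <- u[2]
  ctrl <- setdiff(u, as.character(positive))
  r <- pROC::roc(response = as.character(labels), predictor = scores,
                 levels = c(ctrl, as.character(positive)), direction = "<",
                 quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  list(auc = as.numeric(r$auc), curve = curve)
}

#' Welch two-group t-test
#'
#' Two-sided test of a mean difference; the Welch form
#' (Welch-Satterthwaite df) is the default, the pooled-variance form is
#' available via `pooled = TRUE`.
#'
#' @param values numeric vector.
#' @param groups two-level labels parallel to `values`, each level with
#'   >= 2 observations.
#' @param pooled use the pooled-variance (classic Student) form.
#' @return list with `t`, `df`, `pvalue`, `means` (named group means).
#' @export
twoGroupTTest <- function(values, groups, pooled = FALSE) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  ht <- stats::t.test(values ~ g, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       pvalue = ht$p.value,
       means = stats::setNames(as.numeric(tapply(values, g, mean)), levels(g)))
}

#' One-way fixed-effects ANOVA
#'
#' Between/within sum-of-squares decomposition with p from the F
#' distribution. The fully degenerate case (all observations identical)
#' returns F = 0 with a warning instead of 0/0.
#'
#' @param values numeric vector.
#' @param groups factor with >= 2 levels, each with >= 2 observations.
#' @return list with `F`, `df1`, `df2`, `pvalue`.
#' @export
onewayAnova <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  n <- length(values)
  k <- nlevels(g)
  gm <- tapply(values, g, mean)
  ssb <- sum(tapply(values, g, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    warning("all observations identical; returning F = 0")
    return(list(F = 0, df1 = df1, df2 = df2, pvalue = 1))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       pvalue = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pairwise correlation among selected genes
#'
#' Pearson correlation and t-based p-value for every pair in a gene list
#' — the co-expression check applied to validated hub genes. Uses the
#' same correlation kernel as the adjacency step.
#'
#' @param expr genes x samples numeric matrix.
#' @param genes character vector of gene identifiers (>= 2).
#' @return data.frame with `gene1`, `gene2`, `cor`, `pvalue` for each
#'   unordered pair.
#' @export
genePairCorrelation <- function(expr, genes) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  x <- expr[genes, , drop = FALSE]
  .checkGeneVariance(x)
  r <- stats::cor(t(x))
  p <- .corPvalue(r, ncol(x))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(gene1 = genes[pairs[, 1]], gene2 = genes[pairs[, 2]],
             cor = r[pairs], pvalue = p[pairs], stringsAsFactors = FALSE)
}

#' Validate a set of candidate genes
#'
#' Per-gene validation summary: median-split log-rank p against survival,
#' ROC AUC against a binary label, and a two-group test of the expression
#' difference between label groups.
#'
#' @param expr genes x samples numeric matrix.
#' @param genes character vector of genes to validate.
#' @param surv optional survival data.frame.
#' @param labels optional named binary label vector (1 = case).
#' @return data.frame, one row per gene, with whichever of
#'   `logrank_pvalue`, `auc`, `ttest_pvalue` the supplied tables allow.
#' @export
validateGenes <- function(expr, genes, surv = NULL, labels = NULL) {
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  if (!is.null(surv)) {
    out$logrank_chisq <- out$logrank_pvalue <- NA_real_
    for (i in seq_along(genes)) {
      x <- stats::setNames(expr[genes[i], ], colnames(expr))
      grp <- medianSplit(x)
      if (nlevels(droplevels(grp[surv$sample_id[surv$sample_id %in% names(grp)]])) == 2) {
        lr <- logrankTest(surv, grp)
        out$logrank_chisq[i] <- lr$chisq
        out$logrank_pvalue[i] <- lr$pvalue
      }
    }
  }
  if (!is.null(labels)) {
    if (is.matrix(labels)) labels <- stats::setNames(labels[, 1], rownames(labels))
    shared <- intersect(colnames(expr), names(labels))
    out$auc <- out$ttest_pvalue <- NA_real_
    for (i in seq_along(genes)) {
      x <- expr[genes[i], shared]
      lb <- labels[shared]
      out$auc[i] <- rocAuc(x, lb)$auc
      out$ttest_pvalue[i] <- twoGroupTTest(x, lb)$pvalue
    }
  }
  out
}

# Align survival rows with optional group labels by sample identifier.
.alignSurvival <- function(surv, groups) {
  if (any(surv$time < 0)) stop("negative survival time", call. = FALSE)
  d <- surv
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      stop("group labels must be named by sample", call. = FALSE)
    }
    shared <- intersect(d$sample_id, names(groups))
    if (!length(shared)) stop("no shared samples", call. = FALSE)
    d <- d[d$sample_id %in% shared, ]
    d$group <- as.character(groups[d$sample_id])
    if (any(table(d$group) == 0)) stop("empty group", call. = FALSE)
  }
  d
}
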