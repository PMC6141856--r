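# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# Naive O(n^3) average-linkage (UPGMA) agglomeration on a distance matrix.
# Returns the sorted merge heights.
upgmaOracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  active <- rep(TRUE, n + (n - 1))
  allClusters <- clusters
  while (sum(active[seq_along(allClusters)]) > 1) {
    ids <- which(active[seq_along(allClusters)])
    best <- c(NA, NA)
    bestD <- Inf
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        ca <- allClusters[[ids[a]]]
        cb <- allClusters[[ids[b]]]
        d <- mean(D[ca, cb])
        if (d < bestD) {
          bestD <- d
          best <- c(ids[a], ids[b])
        }
      }
    }
    heights <- c(heights, bestD)
    allClusters[[length(allClusters) + 1L]] <-
      c(allClusters[[best[1]]], allClusters[[best[2]]])
    active[best] <- FALSE
    active[length(allClusters)] <- TRUE
  }
  sort(heights)
}

# Triple-nested-loop topological overlap on an adjacency with zero diagonal.
tomOracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (l in seq_len(n)) {
        if (l != i && l != j) s <- s + a[i, l] * a[l, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# Definitional Pearson correlation for one pair of vectors.
pearsonOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs AUC: P(case > control) + 0.5 P(tie).
aucPairOracle <- function(scores, cases) {
  sc <- scores[cases]
  sn <- scores[!cases]
  tot <- 0
  for (a in sc) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sc) * length(sn))
}

# Risk-table product-limit estimator at each distinct event time.
kmOracle <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, nRisk = NA_real_, nEvent = NA_real_,
                    survival = NA_real_)
  for (i in seq_along(et)) {
    atRisk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / atRisk)
    out[i, c("nRisk", "nEvent", "survival")] <- c(atRisk, d, s)
  }
  out
}

# Two-group log-rank by explicit enumeration over distinct event times.
logrankOracle <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, pvalue = pchisq(chisq, 1, lower.tail = FALSE))
}

# Welch t statistic and p from the definitional formulas.
welchOracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, pvalue = 2 * pt(-abs(t), df))
}

# One-way ANOVA from explicit sums of squares.
anovaSSOracle <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, g, function(v) (v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df1 = k - 1, df2 = n - k,
       pvalue = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by hand: p * m / rank, cumulative minimum
# from the largest p down, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small reproducible genes x samples matrix.
randomExpr <- function(nGenes, nSamples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  m
}

# A vector with exact Pearson correlation `rho` to `x` (n > 2).
vectorWithCor <- function(x, rho, seed = 1) {
  set.seed(seed)
  w <- rnorm(length(x))
  zx <- as.numeric(scale(x))
  zw <- residuals(lm(w ~ zx))
  zw <- zw / sqrt(sum(zw^2))
  zx <- zx / sqrt(sum(zx^2))
  rho * zx + sqrt(1 - rho^2) * zw
}

# Block TOM matrix: high overlap within blocks, low between.
blockTom <- function(sizes, within = 0.9, between = 0.05) {
  n <- sum(sizes)
  tom <- matrix(between, n, n)
  at <- 0
  for (s in sizes) {
    idx <- at + seq_len(s)
    tom[idx, idx] <- within
    at <- at + s
  }
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tom
}
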