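test_that("median split sends ties low and the high group above the median", {
  g <- medianSplit(setNames(c(1, 2, 3, 4), paste0("s", 1:4)))
  expect_identical(as.integer(table(g)), c(2L, 2L))
  expect_identical(as.character(g[c("s3", "s4")]), c("high", "high"))

  allSame <- medianSplit(setNames(rep(5, 6), paste0("s", 1:6)))
  expect_true(all(allSame == "low"))

  odd <- medianSplit(setNames(c(10, 20, 30, 40, 50), paste0("s", 1:5)))
  expect_identical(sum(odd == "low"), 3L)  # ceiling(5/2)
})

test_that("Kaplan-Meier closed forms hold", {
  survAll <- data.frame(sample_id = paste0("s", 1:4),
                        time = c(1, 2, 3, 4), event = rep(0L, 4))
  km <- kaplanMeier(survAll)
  expect_true(all(km$survival == 1))

  surv3 <- data.frame(sample_id = paste0("s", 1:3),
                      time = c(1, 2, 3), event = rep(1L, 3))
  km3 <- kaplanMeier(surv3)
  expect_equal(km3$survival[km3$nEvent > 0], c(2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_error(kaplanMeier(data.frame(sample_id = "a", time = -1, event = 1L)),
               "negative")
})

test_that("Kaplan-Meier matches a hand-rolled risk-table oracle", {
  set.seed(61)
  surv <- data.frame(sample_id = paste0("s", 1:20),
                     time = round(rexp(20, 0.2), 1),
                     event = rbinom(20, 1, 0.7))
  km <- kaplanMeier(surv)
  oracle <- kmOracle(surv$time, surv$event)
  got <- km[km$nEvent > 0, ]
  expect_equal(got$time, oracle$time)
  expect_equal(got$nRisk, oracle$nRisk)
  expect_equal(got$survival, oracle$survival, tolerance = 1e-12)
  # monotone, bounded
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("log-rank is zero for identical groups and matches enumeration", {
  base <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1L, 1L, 0L, 1L, 0L, 1L))
  surv <- data.frame(sample_id = paste0("s", 1:12),
                     time = rep(base$time, 2), event = rep(base$event, 2))
  groups <- setNames(rep(c("A", "B"), each = 6), surv$sample_id)
  lr <- logrankTest(surv, groups)
  expect_lt(lr$chisq, 1e-12)
  expect_equal(lr$pvalue, 1, tolerance = 1e-9)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  set.seed(62)
  surv2 <- data.frame(sample_id = paste0("s", 1:12),
                      time = sample(1:20, 12), event = rbinom(12, 1, 0.8))
  g2 <- setNames(rep(c("A", "B"), times = c(5, 7)), surv2$sample_id)
  lr2 <- logrankTest(surv2, g2)
  oracle <- logrankOracle(surv2$time, surv2$event, g2[surv2$sample_id])
  expect_equal(lr2$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(lr2$pvalue, oracle$pvalue, tolerance = 1e-10)

  # relabeling invariance
  g3 <- setNames(ifelse(g2 == "A", "Z", "Y"), names(g2))
  expect_equal(logrankTest(surv2, g3)$chisq, lr2$chisq, tolerance = 1e-12)
  expect_error(logrankTest(surv2, setNames(rep("A", 12), surv2$sample_id)),
               "2 non-empty groups")
})

test_that("a strong survival effect is detected in nearly all replicates", {
  hits <- vapply(1:100, function(i) {
    cfg <- simulationConfig(nSamples = 100L, moduleSizes = c(10L),
                            nBackgroundGenes = 0L, survivalLogHazard = 2,
                            censoringFraction = 0.2, seed = 7000L + i)
    out <- simulateExpression(cfg)
    surv <- simulateSurvival(out$expr, out$truth, cfg)
    g <- medianSplit(setNames(out$expr[1, ], colnames(out$expr)))
    logrankTest(surv, g)$pvalue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(rocAuc(scores, labels)$auc, 1, tolerance = 1e-12)

  tied <- rocAuc(rep(5, 10), rep(c(0, 1), 5))
  expect_equal(tied$auc, 0.5, tolerance = 1e-12)

  set.seed(63)
  sc <- rnorm(30)
  lb <- rbinom(30, 1, 0.5)
  got <- rocAuc(sc, lb)
  expect_equal(got$auc, aucPairOracle(sc, lb == 1), tolerance = 1e-12)
  # curve endpoints and symmetry
  expect_equal(got$curve[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(got$curve[nrow(got$curve), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  expect_equal(rocAuc(-sc, lb)$auc, 1 - got$auc, tolerance = 1e-12)
  expect_error(rocAuc(sc, rep(1, 30)), "2 classes")
})

test_that("the two-group test is Welch by default and matches the formula oracle", {
  same <- c(1, 2, 3, 4)
  out <- twoGroupTTest(c(same, same), rep(c("a", "b"), each = 4))
  expect_equal(out$t, 0, tolerance = 1e-12)
  expect_equal(out$pvalue, 1, tolerance = 1e-12)

  shifted <- twoGroupTTest(c(1, 2, 3, 11, 12, 13),
                           rep(c("a", "b"), each = 3))
  expect_lt(shifted$pvalue, 1e-3)

  set.seed(64)
  x <- rnorm(10); y <- rnorm(12, sd = 3)
  got <- twoGroupTTest(c(x, y), rep(c("a", "b"), c(10, 12)))
  oracle <- welchOracle(x, y)
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$pvalue, oracle$pvalue, tolerance = 1e-10)
  expect_error(twoGroupTTest(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("one-way ANOVA matches the sum-of-squares oracle and the pooled t identity", {
  set.seed(65)
  vals <- rnorm(18)
  g3 <- rep(c("a", "b", "c"), each = 6)
  got <- onewayAnova(vals, g3)
  oracle <- anovaSSOracle(vals, g3)
  expect_equal(got$F, oracle$F, tolerance = 1e-10)
  expect_equal(got$pvalue, oracle$pvalue, tolerance = 1e-10)

  # with two groups, F is the square of the pooled-variance t
  v2 <- rnorm(14)
  g2 <- rep(c("a", "b"), c(6, 8))
  f2 <- onewayAnova(v2, g2)
  t2 <- twoGroupTTest(v2, g2, pooled = TRUE)
  expect_equal(f2$F, t2$t^2, tolerance = 1e-10)

  expect_warning(flat <- onewayAnova(rep(2, 9), rep(c("a", "b", "c"), 3)),
                 "identical")
  expect_identical(flat$F, 0)
  expect_error(onewayAnova(1:5, c("a", "a", "b", "b", "c")), ">= 2")
})

test_that("gene pair correlations share the adjacency kernel", {
  expr <- randomExpr(5, 15, seed = 66)
  pc <- genePairCorrelation(expr, rownames(expr)[c(1, 2, 3)])
  expect_identical(nrow(pc), 3L)
  a <- abs(cor(t(expr[1:3, ])))
  for (i in seq_len(nrow(pc))) {
    expect_equal(abs(pc$cor[i]), a[pc$gene1[i], pc$gene2[i]], tolerance = 1e-12)
  }
  self <- genePairCorrelation(expr, c("g01", "g01"))
  expect_equal(self$cor, 1, tolerance = 1e-12)
  expect_error(genePairCorrelation(expr, c("g01", "nope")), "nope")
})

test_that("independent genes show small correlations with uniform p-values", {
  set.seed(67)
  ps <- replicate(300, {
    x <- rnorm(25); y <- rnorm(25)
    expr <- rbind(g1 = x, g2 = y)
    colnames(expr) <- paste0("s", 1:25)
    genePairCorrelation(expr, c("g1", "g2"))$pvalue
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
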