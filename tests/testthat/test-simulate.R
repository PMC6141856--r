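smallCfg <- function(...) {
  args <- utils::modifyList(
    list(nSamples = 30L, moduleSizes = c(20L, 15L),
         nBackgroundGenes = 25L, seed = 7L),
    list(...))
  do.call(simulationConfig, args)
}

test_that("identical seeds give identical datasets, and the global RNG is untouched", {
  set.seed(999)
  before <- .Random.seed
  a <- simulateExpression(smallCfg())
  expect_identical(.Random.seed, before)
  b <- simulateExpression(smallCfg())
  expect_identical(a$expr, b$expr)
  expect_identical(a$traits, b$traits)
  expect_identical(a$truth@moduleLabels, b$truth@moduleLabels)
  sa <- simulateSurvival(a$expr, a$truth, smallCfg())
  sb <- simulateSurvival(b$expr, b$truth, smallCfg())
  expect_identical(sa, sb)
  c <- simulateExpression(smallCfg(seed = 8L))
  expect_false(identical(a$expr, c$expr))
})

test_that("planted labels account for exactly the configured genes", {
  cfg <- simulationConfig(nSamples = 20L, moduleSizes = c(50L, 40L),
                          nBackgroundGenes = 200L, seed = 1L)
  out <- simulateExpression(cfg)
  lab <- out$truth@moduleLabels
  expect_length(lab, 290)
  expect_identical(sum(lab != "grey"), 90L)
  expect_identical(as.integer(table(lab)[c("turquoise", "blue")]),
                   c(50L, 40L))
  # latent eigengenes standardized per module
  expect_lt(max(abs(rowMeans(out$truth@eigengenes))), 1e-10)
  expect_lt(max(abs(apply(out$truth@eigengenes, 1, sd) - 1)), 1e-10)
})

test_that("noiseless unit-loading modules are perfectly correlated", {
  cfg <- simulationConfig(nSamples = 12L, moduleSizes = c(6L, 5L),
                          nBackgroundGenes = 0L, loadingRange = c(1, 1),
                          noiseSd = 0, seed = 3L)
  out <- simulateExpression(cfg)
  lab <- out$truth@moduleLabels
  for (m in c("turquoise", "blue")) {
    r <- cor(t(out$expr[lab == m, ]))
    expect_lt(max(abs(abs(r) - 1)), 1e-12)
  }
  # across modules the latent factors are not identical
  r12 <- cor(out$expr[1, ], out$expr[7, ])
  expect_lt(abs(r12), 1 - 1e-6)
})

test_that("zero censoring yields all events, and the censored fraction tracks its target", {
  cfg <- smallCfg(censoringFraction = 0)
  out <- simulateExpression(cfg)
  surv <- simulateSurvival(out$expr, out$truth, cfg)
  expect_true(all(surv$event == 1L))
  expect_true(all(surv$time >= 0))

  cfg2 <- simulationConfig(nSamples = 400L, moduleSizes = c(20L),
                           nBackgroundGenes = 10L,
                           censoringFraction = 0.4, seed = 5L)
  out2 <- simulateExpression(cfg2)
  surv2 <- simulateSurvival(out2$expr, out2$truth, cfg2)
  expect_lt(abs(mean(surv2$event == 0L) - 0.4), 0.1)
})

test_that("unknown survival gene errors", {
  cfg <- smallCfg(survivalGene = "NOPE")
  out <- simulateExpression(smallCfg())
  expect_error(simulateSurvival(out$expr, out$truth, cfg), "NOPE")
})

test_that("a strong expression-survival effect shortens high-group survival", {
  # coef 2: the high-expression group should have shorter median survival
  # in nearly all replicates
  worse <- vapply(1:100, function(i) {
    cfg <- simulationConfig(nSamples = 100L, moduleSizes = c(10L),
                            nBackgroundGenes = 0L, survivalLogHazard = 2,
                            censoringFraction = 0, seed = 1000L + i)
    out <- simulateExpression(cfg)
    surv <- simulateSurvival(out$expr, out$truth, cfg)
    g <- medianSplit(setNames(out$expr[1, ], colnames(out$expr)))
    median(surv$time[g[surv$sample_id] == "high"]) <
      median(surv$time[g[surv$sample_id] == "low"])
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("tumor labelling hits the exact count and shifts only designated genes", {
  cfg <- simulationConfig(nSamples = 100L, moduleSizes = c(10L, 8L),
                          nBackgroundGenes = 20L, tumorFraction = 0.5,
                          seed = 2L)
  out <- simulateExpression(cfg)
  tl <- simulateTumorLabels(out$expr, out$truth, cfg)
  expect_identical(sum(tl$labels[, "tumor"]), 50)
  shifted <- names(tl$shiftedGenes)
  expect_setequal(shifted,
                  names(out$truth@moduleLabels)[out$truth@moduleLabels == "turquoise"])
  untouched <- setdiff(rownames(out$expr), shifted)
  expect_identical(tl$expr[untouched, ], out$expr[untouched, ])
  normals <- tl$labels[, "tumor"] == 0
  expect_identical(tl$expr[, normals], out$expr[, normals])
})

test_that("tumor shift far above noise separates classes; zero shift does not", {
  cfg <- simulationConfig(nSamples = 60L, moduleSizes = c(5L),
                          nBackgroundGenes = 5L, tumorShiftMean = 8,
                          tumorShiftSd = 0.1, noiseSd = 0.5, seed = 4L)
  out <- simulateExpression(cfg)
  tl <- simulateTumorLabels(out$expr, out$truth, cfg)
  lab <- setNames(tl$labels[, 1], rownames(tl$labels))
  aucs <- vapply(names(tl$shiftedGenes), function(g)
    rocAuc(tl$expr[g, names(lab)], lab)$auc, numeric(1))
  expect_true(all(aucs > 0.95))

  # null: average AUC over replicates stays near 1/2
  nullAuc <- vapply(1:40, function(i) {
    cfg0 <- simulationConfig(nSamples = 60L, moduleSizes = c(5L),
                             nBackgroundGenes = 5L, tumorShiftMean = 0,
                             tumorShiftSd = 0, seed = 300L + i)
    o <- simulateExpression(cfg0)
    t0 <- simulateTumorLabels(o$expr, o$truth, cfg0)
    l0 <- setNames(t0$labels[, 1], rownames(t0$labels))
    rocAuc(t0$expr[1, names(l0)], l0)$auc
  }, numeric(1))
  expect_lt(abs(mean(nullAuc) - 0.5), 0.05)
})
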