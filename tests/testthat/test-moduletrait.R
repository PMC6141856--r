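test_that("a rank-1 module's eigengene is its common profile, positively signed", {
  set.seed(31)
  v <- rnorm(8)
  expr <- matrix(rep(v, each = 4), 4, 8,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  expr <- expr + matrix(rnorm(32, sd = 1e-8), 4, 8)  # break exact ties
  assign <- setNames(rep("turquoise", 4), rownames(expr))
  me <- moduleEigengene(expr, assign, "turquoise")
  expect_gt(cor(me, v), 1 - 1e-6)
  expect_equal(sum(me^2), 1, tolerance = 1e-10)
})

test_that("the eigengene equals the dominant eigenvector of the standardized covariance", {
  expr <- randomExpr(5, 6, seed = 32)
  assign <- setNames(rep("blue", 5), rownames(expr))
  me <- moduleEigengene(expr, assign, "blue")
  xs <- t(scale(t(expr)))
  ev <- eigen(t(xs) %*% xs, symmetric = TRUE)$vectors[, 1]
  expect_lt(min(max(abs(me - ev)), max(abs(me + ev))), 1e-10)
  # ... and captures at least as much variance as any competitor direction
  varOf <- function(u) sum((xs %*% u)^2)
  set.seed(33)
  for (i in 1:25) {
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    expect_gte(varOf(me) + 1e-10, varOf(u))
  }
})

test_that("eigengene preconditions are enforced", {
  expr <- randomExpr(4, 5, seed = 34)
  assign <- setNames(c("blue", "blue", "grey", "grey"), rownames(expr))
  expr["g02", ] <- 2
  expect_error(moduleEigengene(expr, assign, "blue"), "g02")
  expect_error(moduleEigengene(expr, assign, "red"), "fewer than 2")
})

test_that("eigengene-trait correlation flags the right module with exact p mechanics", {
  me <- matrix(c(seq(-1, 1, length.out = 10),
                 rnorm(10)), ncol = 2,
               dimnames = list(paste0("s", 1:10), c("MEturquoise", "MEblue")))
  set.seed(35)
  traits <- matrix(me[, 1], ncol = 1,
                   dimnames = list(rownames(me), "grade"))
  out <- moduleTraitCorrelation(me, traits)
  expect_equal(out$correlation["MEturquoise", "grade"], 1, tolerance = 1e-12)
  expect_lt(out$pvalue["MEturquoise", "grade"], 1e-12)
  expect_identical(out$significantModule, "turquoise")

  # exactly orthogonal trait: r = 0 gives t = 0 and p = 1
  orth <- vectorWithCor(me[, 1], 0, seed = 36)
  traits0 <- matrix(orth, ncol = 1, dimnames = list(rownames(me), "grade"))
  out0 <- moduleTraitCorrelation(me[, 1, drop = FALSE], traits0)
  expect_equal(out0$pvalue["MEturquoise", "grade"], 1, tolerance = 1e-12)

  traitsC <- matrix(1, 10, 1, dimnames = list(rownames(me), "flat"))
  expect_error(moduleTraitCorrelation(me, traitsC), "constant trait")
})

test_that("correlation p-values agree with a permutation oracle", {
  set.seed(37)
  me <- matrix(rnorm(20), ncol = 1,
               dimnames = list(paste0("s", 1:20), "MEturquoise"))
  trait <- rnorm(20)
  traits <- matrix(trait, ncol = 1, dimnames = list(rownames(me), "grade"))
  p <- moduleTraitCorrelation(me, traits)$pvalue[1, 1]
  robs <- abs(cor(me[, 1], trait))
  set.seed(38)
  rperm <- replicate(10000, abs(cor(me[, 1], sample(trait))))
  pPerm <- mean(rperm >= robs)
  expect_lt(abs(p - pPerm), 0.02)
})

test_that("trait rescaling leaves the correlation unchanged up to sign", {
  set.seed(39)
  me <- matrix(rnorm(15), ncol = 1,
               dimnames = list(paste0("s", 1:15), "MEturquoise"))
  tr <- rnorm(15)
  t1 <- matrix(tr, ncol = 1, dimnames = list(rownames(me), "grade"))
  t2 <- matrix(-3 * tr + 10, ncol = 1, dimnames = list(rownames(me), "grade"))
  c1 <- moduleTraitCorrelation(me, t1)
  c2 <- moduleTraitCorrelation(me, t2)
  expect_equal(abs(c1$correlation), abs(c2$correlation), tolerance = 1e-12)
  expect_equal(c1$pvalue, c2$pvalue, tolerance = 1e-12)
})

test_that("gene significance modes follow their definitions", {
  expr <- randomExpr(3, 20, seed = 40)
  trait <- setNames(expr[1, ], colnames(expr))
  gsC <- geneSignificance(expr, trait, "correlation")
  expect_equal(gsC$GS[1], 1, tolerance = 1e-12)

  expr2 <- expr
  expr2[2, ] <- vectorWithCor(trait, 0, seed = 41)
  gsL <- geneSignificance(expr2, trait, "neglogp")
  expect_equal(gsL$GS[2], 0, tolerance = 1e-12)

  # -log10 p matches the definitional t formula
  for (i in 1:3) {
    r <- pearsonOracle(expr[i, ], trait)
    if (abs(r) < 1) {
      t <- r * sqrt(18) / sqrt(1 - r^2)
      p <- 2 * pt(-abs(t), 18)
      expect_lt(abs(gsC$pvalue[i] - p), 1e-10)
    }
  }
})

test_that("module significance averages absolute GS per module", {
  gs <- data.frame(gene_id = paste0("g", 1:5),
                   cor = c(0.1, -0.2, 0.3, 0, 0),
                   pvalue = rep(0.5, 5),
                   GS = c(0.1, -0.2, 0.3, 0, 0))
  assign <- new("ModuleAssignment", genes = paste0("g", 1:5),
                labels = c(rep("turquoise", 3), rep("grey", 2)),
                minModuleSize = 2L)
  ms <- moduleSignificance(gs, assign)
  expect_equal(ms$MS[ms$module == "turquoise"], 0.2, tolerance = 1e-12)
  expect_equal(ms$MS[ms$module == "grey"], 0, tolerance = 1e-12)
  expect_false(ms$isModule[ms$module == "grey"])
  gsBad <- rbind(gs, data.frame(gene_id = "gX", cor = 0, pvalue = 1, GS = 0))
  expect_error(moduleSignificance(gsBad, assign), "gX")
})

test_that("the trait-coupled module attains the top MS in nearly all replicates", {
  top <- vapply(1:100, function(i) {
    cfg <- simulationConfig(nSamples = 40L, moduleSizes = c(30L, 30L, 30L),
                            nBackgroundGenes = 30L, seed = 4000L + i)
    out <- simulateExpression(cfg)
    assign <- new("ModuleAssignment", genes = names(out$truth@moduleLabels),
                  labels = unname(out$truth@moduleLabels), minModuleSize = 2L)
    tv <- setNames(out$traits[, "grade"], rownames(out$traits))
    gs <- geneSignificance(out$expr, tv, "correlation")
    ms <- moduleSignificance(gs, assign)
    msMod <- ms[ms$isModule, ]
    msMod$module[which.max(msMod$MS)] == "turquoise"
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("relateModulesToTraits assembles a coherent result object", {
  cfg <- simulationConfig(nSamples = 30L, moduleSizes = c(35L, 30L),
                          nBackgroundGenes = 20L, seed = 42L)
  out <- simulateExpression(cfg)
  net <- buildNetwork(out$expr, power = 6)
  assign <- cutModules(clusterGenes(net), minModuleSize = 20)
  rel <- relateModulesToTraits(out$expr, assign, out$traits)
  expect_s4_class(rel, "ModuleTraitResult")
  expect_identical(rownames(eigengenes(rel)), colnames(out$expr))
  expect_true(all(abs(rel@correlation) <= 1))
  expect_identical(
    significantModule(rel),
    sub("^ME", "",
        rownames(rel@correlation)[which.max(abs(rel@correlation[, "grade"]))]))
  expect_true(all(c("GS_cor", "GS_neglogp") %in% colnames(rel@geneSignificance)))
})
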