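#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end analysis: variance
#' filtering, network construction, module detection, module-trait
#' relation, hub screening and validation. When no expression input is
#' supplied to [runPipeline()], the simulator in `sim` provides the
#' dataset (and its ground truth).
#'
#' @param sim a [simulationConfig()]; used when no input data are given.
#' @param varianceFraction fraction of genes kept by the variance filter.
#' @param power soft-thresholding power; `NULL` selects automatically.
#' @param powers candidate powers for automatic selection.
#' @param targetR2 scale-free fit target.
#' @param minModuleSize module size floor for the tree cut.
#' @param cutHeightFraction static tree-cut height fraction.
#' @param mmThreshold,gsThreshold hub screening cut-offs.
#' @param trait designated clinical trait name.
#' @param oraAlpha adjusted-p cut-off for over-representation calls.
#' @param seed integer seed overriding `sim$seed` when not `NULL`.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(sim = simulationConfig(),
                           varianceFraction = 0.5,
                           power = NULL, powers = 1:20, targetR2 = 0.90,
                           minModuleSize = 30L, cutHeightFraction = 0.99,
                           mmThreshold = 0.8, gsThreshold = 0.2,
                           trait = "grade", oraAlpha = 0.001,
                           seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, varianceFraction = varianceFraction, power = power,
              powers = powers, targetR2 = targetR2,
              minModuleSize = as.integer(minModuleSize),
              cutHeightFraction = cutHeightFraction,
              mmThreshold = mmThreshold, gsThreshold = gsThreshold,
              trait = trait, oraAlpha = oraAlpha)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full co-expression analysis
#'
#' Executes simulate (when no `expr` is given) -> variance filter ->
#' network construction -> module detection -> module-trait relation ->
#' hub screening -> validation (when survival/label data exist) ->
#' over-representation (when gene sets exist). Every stage is a pure
#' function of its inputs and the seed, so repeated runs are identical.
#' When `outDir` is given, each stage's tables are written as TSV/Newick
#' plus a JSON run summary.
#'
#' @param config a [pipelineConfig()].
#' @param expr optional genes x samples matrix; `NULL` simulates.
#' @param traits optional samples x traits matrix (required with `expr`).
#' @param surv optional survival data.frame.
#' @param labels optional named binary tumor/normal labels.
#' @param geneSets optional named list of gene sets for ORA.
#' @param outDir optional output directory.
#' @return list with the stage outputs (`expr`, `traits`, `truth`,
#'   `filter`, `thresholdScan`, `network`, `geneTree`, `modules`,
#'   `relation`, `hubs`, `validation`, `enrichment`, `summary`).
#' @export
runPipeline <- function(config = pipelineConfig(), expr = NULL, traits = NULL,
                        surv = NULL, labels = NULL, geneSets = NULL,
                        outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  truth <- NULL
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  validationExpr <- NULL
  if (is.null(expr)) {
    # the network is built on the discovery matrix; the tumor/normal
    # mean-shifted copy stands in for a separate validation cohort and is
    # used only for the diagnostic (ROC / group-difference) checks
    simOut <- stage("simulate", function() {
      s <- simulateExpression(config$sim)
      labs <- simulateTumorLabels(s$expr, s$truth, config$sim)
      list(expr = s$expr, traits = s$traits, truth = s$truth,
           labels = stats::setNames(labs$labels[, 1], rownames(labs$labels)),
           validationExpr = labs$expr,
           surv = simulateSurvival(s$expr, s$truth, config$sim),
           shiftedGenes = labs$shiftedGenes)
    })
    expr <- simOut$expr
    traits <- simOut$traits
    truth <- simOut$truth
    validationExpr <- simOut$validationExpr
    if (is.null(surv)) surv <- simOut$surv
    if (is.null(labels)) labels <- simOut$labels
  }
  if (is.null(validationExpr)) validationExpr <- expr
  if (is.null(traits)) {
    stop("pipeline stage 'relate' needs a trait table: supply `traits` ",
         "alongside `expr` (or run without `expr` to simulate one)",
         call. = FALSE)
  }

  filt <- stage("filter", function() varianceFilter(expr, config$varianceFraction))
  fexpr <- filt$expr

  scan <- NULL
  power <- config$power
  if (is.null(power)) {
    scan <- stage("network", function()
      pickSoftThreshold(fexpr, config$powers, config$targetR2))
    power <- attr(scan, "selectedPower")
  }
  net <- stage("network", function() buildNetwork(fexpr, power = power))
  geneTree <- stage("modules", function() clusterGenes(net))
  modules <- stage("modules", function()
    cutModules(geneTree, config$minModuleSize, config$cutHeightFraction))
  relation <- stage("relate", function()
    relateModulesToTraits(fexpr, modules, traits, config$trait))
  hubs <- stage("hubs", function()
    screenHubGenes(fexpr, modules, relation,
                   mmThreshold = config$mmThreshold,
                   gsThreshold = config$gsThreshold))
  hubGenes <- hubs$gene_id[hubs$isHub]

  validation <- NULL
  if ((!is.null(surv) || !is.null(labels)) && length(hubGenes)) {
    # survival stratification uses the discovery matrix; diagnostic ROC /
    # group tests use the (possibly separate) validation matrix
    validation <- stage("validate", function() {
      v <- validateGenes(expr, hubGenes, surv = surv)
      if (!is.null(labels)) {
        v2 <- validateGenes(validationExpr, hubGenes, labels = labels)
        v <- merge(v, v2, by = "gene_id", sort = FALSE)
      }
      v
    })
  }

  enrichment <- NULL
  if (!is.null(geneSets) && length(hubGenes)) {
    enrichment <- stage("enrich", function()
      oraTest(names(moduleLabels(modules))[
                moduleLabels(modules) == significantModule(relation)],
              geneSets, rownames(fexpr), config$oraAlpha))
  }

  sz <- moduleSizes(modules, countGrey = FALSE)
  summary <- list(
    nGenesInput = nrow(expr), nSamples = ncol(expr),
    nGenesRetained = nrow(fexpr),
    selectedPower = as.numeric(power),
    nModules = nrow(sz), nGrey = sum(moduleLabels(modules) == "grey"),
    significantModule = significantModule(relation),
    significantModuleTraitCor = unname(
      relation@correlation[paste0("ME", significantModule(relation)),
                           config$trait]),
    nHubs = length(hubGenes)
  )
  if (!is.null(validation)) {
    summary$validation <- validation
  }

  out <- list(expr = expr, traits = traits, truth = truth, filter = filt,
              thresholdScan = scan, network = net, geneTree = geneTree,
              modules = modules, relation = relation, hubs = hubs,
              validation = validation, enrichment = enrichment,
              summary = summary)
  if (!is.null(outDir)) .writePipelineOutputs(out, surv, outDir)
  out
}

# Persist stage outputs as TSV/Newick plus a JSON run summary.
.writePipelineOutputs <- function(out, surv, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeExpressionMatrix(out$filter$expr, p("expression_filtered.tsv"))
  writeTraitTable(out$traits, p("traits.tsv"))
  if (!is.null(surv)) writeSurvivalTable(surv, p("survival.tsv"))
  if (!is.null(out$thresholdScan)) {
    utils::write.table(out$thresholdScan, p("soft_threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dendrogramToNewick(out$geneTree, p("gene_dendrogram.nwk"))
  writeModuleAssignment(out$modules, p("modules.tsv"))
  .writeIdTable(eigengenes(out$relation), p("module_eigengenes.tsv"),
                "\t", "sample_id")
  .writeIdTable(out$relation@correlation, p("module_trait_cor.tsv"),
                "\t", "module")
  .writeIdTable(out$relation@pvalue, p("module_trait_pvalue.tsv"),
                "\t", "module")
  utils::write.table(out$relation@geneSignificance, p("gene_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$relation@moduleSignificance, p("module_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$hubs, p("hub_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$validation)) {
    utils::write.table(out$validation, p("hub_validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$enrichment)) {
    utils::write.table(out$enrichment, p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out$summary, p("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
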