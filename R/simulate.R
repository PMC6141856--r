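#' Configuration for the latent-factor expression simulator
#'
#' The generator plants co-expression modules through a latent-factor
#' model: each module m has a latent eigengene \eqn{e_m} (one standardized
#' value per sample) and gene g of module m is
#' \eqn{x_g = \mu_g + \lambda_g e_m + \epsilon}, with loading
#' \eqn{\lambda_g} drawn uniformly from `loadingRange` and
#' \eqn{\epsilon \sim N(0, \code{noiseSd}^2)}. Background genes are pure
#' noise. An ordinal grade trait (1-3) is a tertile-binned monotone
#' transform of the eigengene of module `traitModule` plus unit noise
#' scaled against `traitEffect`.
#'
#' @param nSamples number of samples (default 49, a small two-colour-era
#'   breast-tumor cohort size).
#' @param moduleSizes integer vector of planted module sizes.
#' @param nBackgroundGenes number of unassigned pure-noise genes.
#' @param loadingRange interval in (0,1) for per-gene loadings.
#' @param noiseSd residual standard deviation for module genes; background
#'   genes get unit-variance noise.
#' @param baselineMean,baselineSd per-gene baseline expression (log2 scale)
#'   drawn N(baselineMean, baselineSd^2).
#' @param traitModule index of the module whose eigengene drives the grade
#'   trait.
#' @param traitEffect signal weight of the eigengene in the grade trait;
#'   larger means a cleaner eigengene-grade correlation.
#' @param survivalGene identifier of the gene whose expression drives
#'   survival; `NULL` picks the highest-loading gene of `traitModule`.
#' @param survivalLogHazard log-hazard-ratio per SD of the survival gene's
#'   expression.
#' @param baselineHazard exponential baseline event rate.
#' @param censoringFraction target fraction of censored subjects in \[0,1).
#' @param tumorFraction fraction of samples labelled tumor.
#' @param tumorShiftMean,tumorShiftSd mean shift added to the trait
#'   module's genes in tumor samples, per-gene N(tumorShiftMean,
#'   tumorShiftSd^2).
#' @param seed integer seed; all randomness flows from it through a local
#'   RNG (global RNG state is untouched).
#' @return a list of class `simulationConfig`.
#' @export
simulationConfig <- function(nSamples = 49L,
                             moduleSizes = c(100L, 80L, 60L, 40L),
                             nBackgroundGenes = 300L,
                             loadingRange = c(0.6, 0.95),
                             noiseSd = 0.6,
                             baselineMean = 7,
                             baselineSd = 1,
                             traitModule = 1L,
                             traitEffect = 2,
                             survivalGene = NULL,
                             survivalLogHazard = 1,
                             baselineHazard = 0.1,
                             censoringFraction = 0.3,
                             tumorFraction = 0.5,
                             tumorShiftMean = 2,
                             tumorShiftSd = 0.25,
                             seed = 7L) {
  cfg <- list(nSamples = as.integer(nSamples),
              moduleSizes = as.integer(moduleSizes),
              nBackgroundGenes = as.integer(nBackgroundGenes),
              loadingRange = loadingRange, noiseSd = noiseSd,
              baselineMean = baselineMean, baselineSd = baselineSd,
              traitModule = as.integer(traitModule), traitEffect = traitEffect,
              survivalGene = survivalGene,
              survivalLogHazard = survivalLogHazard,
              baselineHazard = baselineHazard,
              censoringFraction = censoringFraction,
              tumorFraction = tumorFraction,
              tumorShiftMean = tumorShiftMean, tumorShiftSd = tumorShiftSd,
              seed = as.integer(seed))
  if (any(cfg$moduleSizes < 2)) stop("module sizes must be >= 2", call. = FALSE)
  if (sum(cfg$moduleSizes) + cfg$nBackgroundGenes == 0) {
    stop("no genes to simulate", call. = FALSE)
  }
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (length(cfg$loadingRange) != 2 || any(cfg$loadingRange <= 0) ||
      any(cfg$loadingRange > 1) || diff(cfg$loadingRange) < 0) {
    stop("loadingRange must be an interval within (0,1]", call. = FALSE)
  }
  if (cfg$censoringFraction < 0 || cfg$censoringFraction >= 1) {
    stop("censoringFraction must lie in [0,1)", call. = FALSE)
  }
  if (length(cfg$moduleSizes) && (cfg$traitModule < 1 ||
      cfg$traitModule > length(cfg$moduleSizes))) {
    stop("traitModule out of range", call. = FALSE)
  }
  class(cfg) <- "simulationConfig"
  cfg
}

# Run fn with a local, seeded RNG; global .Random.seed is preserved.
# `offset` decorrelates the sub-streams of the three generators.
.withSeed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed + offset)
  fn()
}

#' Simulate a module-structured expression matrix with ground truth
#'
#' Generates a genes x samples log-scale matrix under the latent-factor
#' model described in [simulationConfig()], an ordinal grade trait, and a
#' [SyntheticTruth-class] recording the planted structure. Identical seeds
#' give identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `expr` (matrix), `traits` (samples x 1
#'   matrix, column "grade"), and `truth` ([SyntheticTruth-class]).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  .withSeed(config$seed, 0L, function() {
    nS <- config$nSamples
    nMod <- length(config$moduleSizes)
    nGenes <- sum(config$moduleSizes) + config$nBackgroundGenes
    samples <- sprintf("S%03d", seq_len(nS))
    genes <- sprintf("G%05d", seq_len(nGenes))

    # latent eigengenes, standardized per module (mean 0, sd 1)
    E <- matrix(stats::rnorm(nMod * nS), nrow = nMod)
    E <- t(scale(t(E)))
    if (nMod > 0) {
      rownames(E) <- .moduleColor(seq_len(nMod))
    }
    colnames(E) <- samples

    labels <- rep("grey", nGenes)
    loadings <- numeric(nGenes)
    expr <- matrix(0, nGenes, nS, dimnames = list(genes, samples))
    at <- 0L
    for (m in seq_len(nMod)) {
      sz <- config$moduleSizes[m]
      idx <- at + seq_len(sz)
      lam <- stats::runif(sz, config$loadingRange[1], config$loadingRange[2])
      eps <- matrix(stats::rnorm(sz * nS, sd = config$noiseSd), sz, nS)
      expr[idx, ] <- lam %o% E[m, ] + eps
      labels[idx] <- .moduleColor(m)
      loadings[idx] <- lam
      at <- at + sz
    }
    if (config$nBackgroundGenes > 0) {
      # pure noise at the residual scale: background genes carry no latent
      # signal, so their variance (noiseSd^2) sits below any module gene's
      # (loading^2 + noiseSd^2) and the variance filter separates them
      idx <- at + seq_len(config$nBackgroundGenes)
      expr[idx, ] <- matrix(stats::rnorm(config$nBackgroundGenes * nS,
                                         sd = config$noiseSd),
                            config$nBackgroundGenes, nS)
    }
    baseline <- stats::rnorm(nGenes, config$baselineMean, config$baselineSd)
    expr <- expr + baseline

    # ordinal grade: tertile bins of traitEffect * e + N(0,1)
    if (nMod > 0) {
      raw <- config$traitEffect * E[config$traitModule, ] + stats::rnorm(nS)
    } else {
      raw <- stats::rnorm(nS)
    }
    cuts <- stats::quantile(raw, c(1 / 3, 2 / 3))
    grade <- 1L + (raw > cuts[1]) + (raw > cuts[2])
    traits <- matrix(as.numeric(grade), ncol = 1,
                     dimnames = list(samples, "grade"))

    names(labels) <- genes
    names(loadings) <- genes
    truth <- new("SyntheticTruth",
                 moduleLabels = labels,
                 eigengenes = E,
                 loadings = loadings,
                 trait = stats::setNames(as.numeric(grade), samples),
                 params = unclass(config))
    list(expr = expr, traits = traits, truth = truth)
  })
}

#' Simulate survival times driven by one gene's expression
#'
#' Event times are exponential with per-sample rate
#' \eqn{\lambda_s = \lambda_0 \exp(\beta z_s)}, where \eqn{z_s} is the
#' standardized expression of the survival gene. Censoring times are
#' uniform on (0, U) with U tuned so the expected censored fraction
#' matches `censoringFraction`.
#'
#' @param expr genes x samples expression matrix.
#' @param truth [SyntheticTruth-class] from [simulateExpression()] (used
#'   to default the survival gene to the highest-loading trait-module gene).
#' @param config a [simulationConfig()].
#' @return survival data.frame (`sample_id`, `time`, `event`).
#' @export
simulateSurvival <- function(expr, truth, config) {
  stopifnot(inherits(config, "simulationConfig"))
  gene <- config$survivalGene
  if (is.null(gene)) {
    lab <- .moduleColor(config$traitModule)
    cand <- names(truth@moduleLabels)[truth@moduleLabels == lab]
    if (!length(cand)) stop("no trait-module gene to drive survival", call. = FALSE)
    gene <- cand[which.max(truth@loadings[cand])]
  }
  if (!gene %in% rownames(expr)) {
    stop("unknown survival gene: ", gene, call. = FALSE)
  }
  .withSeed(config$seed, 1L, function() {
    z <- as.numeric(scale(expr[gene, ]))
    rate <- config$baselineHazard * exp(config$survivalLogHazard * z)
    tEvent <- stats::rexp(length(z), rate)
    if (config$censoringFraction <= 0) {
      time <- tEvent
      event <- rep(1L, length(z))
    } else {
      # E[censored] for C ~ Unif(0,U) is mean(min(t/U, 1)); solve for U
      frac <- function(U) mean(pmin(tEvent / U, 1)) - config$censoringFraction
      hi <- max(tEvent) * 2
      U <- if (frac(hi) > 0) hi else stats::uniroot(frac, c(1e-9, hi))$root
      cens <- stats::runif(length(z), 0, U)
      event <- as.integer(tEvent <= cens)
      time <- pmin(tEvent, cens)
    }
    data.frame(sample_id = colnames(expr), time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate tumor/normal labels with mean shifts on designated genes
#'
#' Labels a fixed fraction of samples as tumor and adds a positive mean
#' shift (per-gene N(tumorShiftMean, tumorShiftSd^2)) to the trait
#' module's genes in tumor samples — the substrate for diagnostic ROC and
#' group-difference validation.
#'
#' @inheritParams simulateSurvival
#' @return list with `labels` (samples x 1 matrix, column "tumor",
#'   1 = tumor), `expr` (shifted matrix) and `shiftedGenes` (named vector
#'   of per-gene shifts).
#' @export
simulateTumorLabels <- function(expr, truth, config) {
  stopifnot(inherits(config, "simulationConfig"))
  .withSeed(config$seed, 2L, function() {
    nS <- ncol(expr)
    nTumor <- round(config$tumorFraction * nS)
    tumor <- rep(0L, nS)
    tumor[sample.int(nS, nTumor)] <- 1L
    lab <- .moduleColor(config$traitModule)
    shifted <- names(truth@moduleLabels)[truth@moduleLabels == lab]
    shifted <- shifted[shifted %in% rownames(expr)]
    shifts <- stats::rnorm(length(shifted), config$tumorShiftMean,
                           config$tumorShiftSd)
    names(shifts) <- shifted
    out <- expr
    if (length(shifted) && any(tumor == 1L)) {
      out[shifted, tumor == 1L] <- out[shifted, tumor == 1L] + shifts
    }
    labels <- matrix(as.numeric(tumor), ncol = 1,
                     dimnames = list(colnames(expr), "tumor"))
    list(labels = labels, expr = out, shiftedGenes = shifts)
  })
}
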