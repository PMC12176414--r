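# Orchestration: run the whole robustness protocol from one configuration.
#
# Protocol constants under the defaults: training fractions in steps of
# 20% (26 variants per classifier seed), 200 replicate test sets per
# (test fraction, kind), and a 10-seed classifier ensemble whose seeds
# play the role of alternative architectures. All of these scale down via
# the configuration for desk-scale runs; the scaling is recorded in the
# report's provenance.

#' @include AllClasses.R protocol.R classifiers.R metrics.R wilcoxon.R synthetic.R
NULL

#' Experiment configuration
#'
#' @slot data A \linkS4class{SyntheticSpec}, or a named list of
#'   \linkS4class{LabeledImageSet}s (\code{train}, \code{test}, optionally
#'   \code{validation}).
#' @slot perturbation A \linkS4class{PerturbationConfig}.
#' @slot kinds Perturbation kinds to study.
#' @slot fractions Training fractions enumerated (percent).
#' @slot analysisFractions Training fractions carried into the robustness
#'   analysis (protocol default 20/60/100; 40/80 are trained but not
#'   analysed).
#' @slot testFractions Test fractions p' evaluated (percent).
#' @slot nReplicates Replicate test sets per (p', kind).
#' @slot ssimReplicates Replicate sets used for the SSIM intensity table.
#' @slot nSeeds Classifier-ensemble size.
#' @slot multi A \linkS4class{MultiPerturbSpec} or NULL to skip the
#'   simultaneous-perturbation arm.
#' @slot spsa A \linkS4class{SpsaConfig} or NULL to skip the adversarial
#'   control arm.
#' @slot classifierHidden,classifierLambda Reference-classifier size and
#'   ridge penalty.
#' @slot masterSeed One seed fixing every randomized step.
#' @slot outputDir Where [writeReport()] puts tables.
#' @export
setClass("ExperimentConfig",
  representation(data = "ANY", perturbation = "PerturbationConfig",
                 kinds = "character", fractions = "numeric",
                 analysisFractions = "numeric", testFractions = "numeric",
                 nReplicates = "integer", ssimReplicates = "integer",
                 nSeeds = "integer", multi = "ANY", spsa = "ANY",
                 classifierHidden = "integer", classifierLambda = "numeric",
                 masterSeed = "integer", outputDir = "character"))

#' @param data,perturbation,kinds,fractions,analysisFractions,testFractions,nReplicates,ssimReplicates,nSeeds,multi,spsa,classifierHidden,classifierLambda,masterSeed,outputDir
#'   See the class slots.
#' @return An \linkS4class{ExperimentConfig}.
#' @rdname ExperimentConfig-class
#' @export
experimentConfig <- function(data = syntheticSpec(),
                             perturbation = perturbationConfig(),
                             kinds = perturbationKinds(),
                             fractions = c(20, 40, 60, 80, 100),
                             analysisFractions = c(20, 60, 100),
                             testFractions = c(20, 40, 60, 80, 100),
                             nReplicates = 200L,
                             ssimReplicates = min(nReplicates, 20L),
                             nSeeds = 10L, multi = multiPerturbSpec(),
                             spsa = NULL,
                             classifierHidden = 200L, classifierLambda = 1,
                             masterSeed = 1L, outputDir = tempdir()) {
  if (!all(analysisFractions %in% fractions))
    stop("analysisFractions must be a subset of fractions")
  new("ExperimentConfig", data = data, perturbation = perturbation,
      kinds = kinds, fractions = fractions,
      analysisFractions = analysisFractions, testFractions = testFractions,
      nReplicates = as.integer(nReplicates),
      ssimReplicates = as.integer(ssimReplicates),
      nSeeds = as.integer(nSeeds), multi = multi, spsa = spsa,
      classifierHidden = as.integer(classifierHidden),
      classifierLambda = classifierLambda,
      masterSeed = as.integer(masterSeed), outputDir = outputDir)
}

#' Read an experiment configuration from a YAML file
#'
#' Recognised top-level keys mirror the [experimentConfig()] arguments;
#' \code{data} may be a synthetic block (fields of [syntheticSpec()]) and
#' \code{perturbation}, \code{multi}, \code{spsa} blocks carry the fields
#' of their constructors.
#'
#' @param path YAML file path.
#' @return An \linkS4class{ExperimentConfig}.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$data)) args$data <- do.call(syntheticSpec, y$data)
  if (!is.null(y$perturbation))
    args$perturbation <- do.call(perturbationConfig, y$perturbation)
  if (!is.null(y$multi)) args$multi <- do.call(multiPerturbSpec, y$multi)
  if (!is.null(y$spsa)) args$spsa <- do.call(spsaConfig, y$spsa)
  for (k in c("kinds", "fractions", "analysisFractions", "testFractions",
              "nReplicates", "ssimReplicates", "nSeeds",
              "classifierHidden", "classifierLambda", "masterSeed",
              "outputDir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(experimentConfig, args)
}

#' Robustness report
#'
#' @slot cleanGrid Per-variant performance on the unperturbed test set.
#' @slot errorGrid Per (kind, training fraction, test fraction) mean/sd
#'   error and mean precision/recall over replicate test sets, averaged
#'   over the classifier ensemble.
#' @slot wilcoxon One-sided exact Wilcoxon p-values comparing each
#'   analysed variant against the baseline over the ensemble.
#' @slot ssimTable Mean SSIM of fully perturbed test sets per kind.
#' @slot multi Simultaneous-perturbation comparison (per-seed means,
#'   improvement, p-value), or empty list.
#' @slot provenance Config summary, seeds and versions.
#' @export
setClass("RobustnessReport",
  representation(cleanGrid = "data.frame", errorGrid = "data.frame",
                 wilcoxon = "data.frame", ssimTable = "data.frame",
                 multi = "list", provenance = "list"))

setMethod("show", "RobustnessReport", function(object) {
  cat("RobustnessReport\n")
  cat(sprintf("  variants (clean grid): %d; ensemble seeds: %d\n",
              nrow(object@cleanGrid),
              object@provenance$nSeeds))
  cat(sprintf("  error grid cells: %d; replicates per cell: %d\n",
              nrow(object@errorGrid), object@provenance$nReplicates))
  if (length(object@multi))
    cat(sprintf("  multi-perturbation improvement: %.4f (p = %.4g)\n",
                object@multi$meanImprovement, object@multi$pValue))
})

# mean/sd error and mean precision/recall of each model over replicate
# sets, evaluated in one batch per model
.batchEval <- function(models, sets) {
  yTrue <- labels(sets[[1L]])
  n <- length(yTrue); R <- length(sets)
  Xall <- do.call(rbind, lapply(sets, .designMatrix))
  lapply(models, function(m) {
    H <- cbind(1, .featurize(m, Xall))
    pred <- as.integer(as.numeric(H %*% m@beta) > 0)
    res <- lapply(seq_len(R), function(r)
      evalResult(yTrue, pred[((r - 1) * n + 1):(r * n)]))
    summarizeReplicates(res)
  })
}

#' Run the full robustness experiment
#'
#' Executes the protocol end to end: generate or take the data, train the
#' baseline ensemble, build and train every training-set variant, evaluate
#' all of them on the clean test set and on replicated perturbed test sets
#' (single-kind grid and, optionally, the simultaneous-perturbation
#' scheme), measure perturbation intensity by SSIM, and compare each
#' analysed variant against the baseline with the exact one-sided Wilcoxon
#' signed-rank test. Fully deterministic under the config's master seed.
#'
#' @param config An \linkS4class{ExperimentConfig}.
#' @param verbose Print stage progress to stderr.
#' @return A \linkS4class{RobustnessReport}.
#' @export
runExperiment <- function(config = experimentConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "data"
  tryCatch({
    sets <- if (is(config@data, "SyntheticSpec"))
      generateSyntheticData(config@data) else config@data
    train <- sets$train; test <- sets$test
    ms <- config@masterSeed
    nSeeds <- config@nSeeds
    cfgP <- config@perturbation

    stage <- "baseline"
    say("training %d baseline classifiers", nSeeds)
    baselines <- lapply(seq_len(nSeeds), function(s)
      trainBaseline(train, seed = childSeed(ms, "arch", s),
                    hidden = config@classifierHidden,
                    lambda = config@classifierLambda))

    stage <- "variants"
    variants <- enumerateVariants(config@fractions, config@kinds, ms)
    say("building and training %d variants x %d seeds",
        length(variants), nSeeds)
    # one perturbed training pool per variant, shared by the ensemble
    variantSets <- lapply(variants, function(v)
      buildPerturbedTrainingSet(train, v, cfgP))
    variantModels <- lapply(seq_along(variants), function(vi) {
      v <- variants[[vi]]
      if (v@kind == "none") return(baselines)
      lapply(seq_len(nSeeds), function(s)
        retrain(baselines[[s]], variantSets[[vi]],
                seed = childSeed(ms, "retrain", v@kind, v@fractionP, s)))
    })

    stage <- "clean evaluation"
    cleanGrid <- do.call(rbind, lapply(seq_along(variants), function(vi) {
      v <- variants[[vi]]
      res <- lapply(variantModels[[vi]], evaluateClassifier, testSet = test)
      data.frame(kind = v@kind, trainFraction = v@fractionP,
                 meanError = mean(vapply(res, `[[`, numeric(1), "errorRate")),
                 sdError = stats::sd(vapply(res, `[[`, numeric(1), "errorRate")),
                 meanPrecision = mean(vapply(res, `[[`, numeric(1), "precision")),
                 meanRecall = mean(vapply(res, `[[`, numeric(1), "recall")))
    }))

    stage <- "perturbed-test grid"
    errorGrid <- NULL
    wilcoxon <- NULL
    ssimTable <- NULL
    vKey <- vapply(variants, function(v) paste(v@kind, v@fractionP),
                   character(1))
    for (kind in config@kinds) {
      say("perturbed-test grid: %s", kind)
      # variants are only tested against their own perturbation kind
      anaIdx <- match(paste(kind, config@analysisFractions), vKey)
      anaIdx <- anaIdx[!is.na(anaIdx)]
      perSeedPerturbed <- matrix(0, nSeeds, length(anaIdx),
                                 dimnames = list(NULL, vKey[anaIdx]))
      perSeedBaseline <- numeric(nSeeds)
      nCells <- 0L
      for (pp in config@testFractions) {
        repSets <- resamplePerturbedTestSets(test,
          testResampleSpec(pp, kind, config@nReplicates,
                           seed = childSeed(ms, "test", kind, pp)), cfgP)
        models <- c(baselines, unlist(lapply(anaIdx, function(vi)
          variantModels[[vi]]), recursive = FALSE))
        summ <- .batchEval(models, repSets)
        groups <- c(list(baseline = seq_len(nSeeds)),
                    stats::setNames(lapply(seq_along(anaIdx), function(j)
                      nSeeds * j + seq_len(nSeeds)), vKey[anaIdx]))
        rows <- do.call(rbind, lapply(names(groups), function(g) {
          gs <- summ[groups[[g]]]
          tf <- if (g == "baseline") 0 else
            variants[[anaIdx[match(g, vKey[anaIdx])]]]@fractionP
          data.frame(kind = kind,
                     trainFraction = tf,
                     testFraction = pp,
                     meanError = mean(vapply(gs, `[[`, numeric(1), "meanError")),
                     sdError = mean(vapply(gs, `[[`, numeric(1), "sdError")),
                     meanPrecision = mean(vapply(gs, `[[`, numeric(1),
                                                 "meanPrecision")),
                     meanRecall = mean(vapply(gs, `[[`, numeric(1),
                                              "meanRecall")))
        }))
        errorGrid <- rbind(errorGrid, rows)
        if (pp > 0) {
          perSeedBaseline <- perSeedBaseline +
            vapply(summ[seq_len(nSeeds)], `[[`, numeric(1), "meanError")
          for (j in seq_along(anaIdx))
            perSeedPerturbed[, j] <- perSeedPerturbed[, j] +
              vapply(summ[nSeeds * j + seq_len(nSeeds)], `[[`,
                     numeric(1), "meanError")
          nCells <- nCells + 1L
        }
      }
      stage <- "wilcoxon"
      if (nCells > 0 && nSeeds > 1) {
        for (j in seq_along(anaIdx)) {
          # identical per-seed means (tiny desk-scale runs) leave nothing
          # to rank; report NA rather than aborting the run
          w <- tryCatch(
            wilcoxonExact(perSeedPerturbed[, j] / nCells,
                          perSeedBaseline / nCells,
                          alternative = "less"),
            error = function(e) list(statistic = NA_real_,
                                     pValue = NA_real_, nPairs = 0L))
          wilcoxon <- rbind(wilcoxon,
            data.frame(kind = kind,
                       trainFraction = variants[[anaIdx[j]]]@fractionP,
                       statistic = w$statistic, pValue = w$pValue,
                       nPairs = w$nPairs))
        }
      }
      stage <- "ssim"
      ssimSets <- resamplePerturbedTestSets(test,
        testResampleSpec(100, kind, config@ssimReplicates,
                         seed = childSeed(ms, "ssim", kind)), cfgP)
      ssimTable <- rbind(ssimTable,
        data.frame(kind = kind, meanSsim = meanSetSsim(test, ssimSets)))
      stage <- "perturbed-test grid"
    }

    stage <- "multi-perturbation"
    multiRes <- list()
    if (!is.null(config@multi)) {
      say("multi-perturbation arm")
      mspec <- config@multi
      mspec@seed <- childSeed(ms, "multi")
      mspec@nReplicates <- config@nReplicates
      mTestSets <- buildMultiperturbedTestSets(test, mspec, cfgP)
      mModels <- lapply(seq_len(nSeeds), function(s) {
        mTrainSpec <- mspec
        mTrainSpec@seed <- childSeed(ms, "multitrain", s)
        mTrain <- buildMultiperturbedTrainingSet(train, mTrainSpec, cfgP)
        retrain(baselines[[s]], mTrain, seed = childSeed(ms, "mretrain", s))
      })
      baseSumm <- .batchEval(baselines, mTestSets)
      multSumm <- .batchEval(mModels, mTestSets)
      baseMeans <- vapply(baseSumm, `[[`, numeric(1), "meanError")
      multMeans <- vapply(multSumm, `[[`, numeric(1), "meanError")
      w <- if (nSeeds > 1)
        tryCatch(wilcoxonExact(multMeans, baseMeans, alternative = "less"),
                 error = function(e)
                   list(pValue = NA_real_, statistic = NA_real_))
      else list(pValue = NA_real_, statistic = NA_real_)
      multiRes <- list(perSeedBaseline = baseMeans,
                       perSeedMulti = multMeans,
                       meanImprovement = mean(baseMeans - multMeans),
                       pValue = w$pValue, statistic = w$statistic)
    }

    stage <- "spsa control"
    if (!is.null(config@spsa)) {
      say("SPSA adversarial control arm")
      advModels <- lapply(seq_len(nSeeds), function(s) {
        scfg <- config@spsa
        scfg@seed <- childSeed(ms, "spsa", s)
        advTrain <- buildAdversarialTrainingSet(train, baselines[[s]], scfg)
        retrain(baselines[[s]], advTrain,
                seed = childSeed(ms, "advretrain", s))
      })
      advClean <- lapply(advModels, evaluateClassifier, testSet = test)
      cleanGrid <- rbind(cleanGrid, data.frame(
        kind = "spsa", trainFraction = 100,
        meanError = mean(vapply(advClean, `[[`, numeric(1), "errorRate")),
        sdError = stats::sd(vapply(advClean, `[[`, numeric(1), "errorRate")),
        meanPrecision = mean(vapply(advClean, `[[`, numeric(1), "precision")),
        meanRecall = mean(vapply(advClean, `[[`, numeric(1), "recall"))))
    }

    prov <- list(masterSeed = ms, nSeeds = nSeeds,
                 nReplicates = config@nReplicates,
                 ssimReplicates = config@ssimReplicates,
                 kinds = config@kinds, fractions = config@fractions,
                 analysisFractions = config@analysisFractions,
                 testFractions = config@testFractions,
                 classifier = sprintf("rfridge-h%d-l%g",
                                      config@classifierHidden,
                                      config@classifierLambda),
                 nTrain = length(train), nTest = length(test),
                 packageVersion =
                   as.character(utils::packageVersion("PerturbKit")),
                 rVersion = R.version.string)
    prov$configHash <- sprintf("%08x",
      childSeed(1, paste(unlist(prov), collapse = "|")))
    new("RobustnessReport", cleanGrid = cleanGrid, errorGrid = errorGrid,
        wilcoxon = if (is.null(wilcoxon)) data.frame() else wilcoxon,
        ssimTable = ssimTable, multi = multiRes, provenance = prov)
  }, error = function(e) {
    stop("experiment failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Write a robustness report to disk
#'
#' Emits the clean-performance grid, the perturbed-test error grid (rows =
#' test fraction, one block per kind and training fraction), the Wilcoxon
#' p-value table, the SSIM intensity table and the multi-perturbation
#' comparison as CSV, plus a JSON provenance record, and optionally line
#' plots of mean error versus test fraction per kind.
#'
#' @param report A \linkS4class{RobustnessReport}.
#' @param outdir Output directory (created if missing).
#' @param plots Also write one error-vs-test-fraction PNG per kind.
#' @return Character vector of the files written, invisibly.
#' @export
writeReport <- function(report, outdir, plots = FALSE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report@cleanGrid, "clean_performance.csv")
  wr(report@errorGrid, "error_grid.csv")
  wr(report@wilcoxon, "wilcoxon.csv")
  wr(report@ssimTable, "ssim.csv")
  if (length(report@multi))
    wr(data.frame(seed = seq_along(report@multi$perSeedBaseline),
                  baselineError = report@multi$perSeedBaseline,
                  multiError = report@multi$perSeedMulti),
       "multi_perturbation.csv")
  provPath <- file.path(outdir, "provenance.json")
  jsonlite::write_json(c(report@provenance,
                         list(multiPValue = report@multi$pValue,
                              multiImprovement = report@multi$meanImprovement)),
                       provPath, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, provPath)
  if (plots) {
    for (kind in unique(report@errorGrid$kind)) {
      p <- file.path(outdir, paste0("error_vs_fraction_", kind, ".png"))
      grDevices::png(p, width = 640, height = 480)
      sub <- report@errorGrid[report@errorGrid$kind == kind, ]
      tf <- sort(unique(sub$trainFraction))
      cols <- grDevices::hcl.colors(length(tf), "Dark 3")
      plot(NULL, xlim = range(sub$testFraction), ylim = c(0, max(sub$meanError)),
           xlab = "% of test images perturbed", ylab = "mean error rate",
           main = kind)
      for (i in seq_along(tf)) {
        s2 <- sub[sub$trainFraction == tf[i], ]
        graphics::lines(s2$testFraction, s2$meanError, col = cols[i], lwd = 2)
        graphics::points(s2$testFraction, s2$meanError, col = cols[i], pch = 16)
      }
      graphics::legend("topleft", legend = paste0("train ", tf, "%"),
                       col = cols, lwd = 2, bty = "n")
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
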