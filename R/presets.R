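#' Canned numerical experiments
#'
#' Regenerates the package's standard experiments at full or reduced scale:
#'
#' * `"convergence"`: the five two-type parameter triples with effective adhesion
#'   parameter 3 and convergence speed parameters 0, 2, 4, 6, 8 —
#'   `(0.5,0.5,-1)`, `(-0.5,1.5,-1)`, `(-1.5,2.5,-1)`, `(3.5,-2.5,-1)`,
#'   `(-3.5,4.5,-1)` — each simulated `nReplicates` times from random
#'   starts, reporting the first-passage switch counts at order-indicator
#'   thresholds 0.7, 0.8 and 0.9.
#' * `"sweep2"` / `"sweep3"`: uniform sweeps over `[-10,10]` boxes for two and
#'   three types (the three-type sweep restricted to convergence speed
#'   parameter below 3), with the Spearman/Kendall rank correlations between
#'   the effective adhesion parameter and the asymptotic order indicator.
#' * `"classify2"` / `"classify3"`: the same sweeps, classified at the
#'   random-mixture threshold and fitted with both the linear SVM and the
#'   logistic regression.
#' * `"firstpassage"`: a two-type sweep reporting first-passage switch counts versus
#'   the effective adhesion parameter.
#'
#' At full scale the sweeps comprise 2000 runs of 312,499 switches each;
#' `nRuns` and `nSwitches` scale the experiments down for desk use.
#'
#' @param name preset name.
#' @param nRuns sweep size (default 2000, the full scale).
#' @param nSwitches switches per simulation (default 312499).
#' @param nReplicates repeats per parameter set for `"convergence"`
#'   (default 3).
#' @param side lattice side length.
#' @param masterSeed integer seed.
#' @param outDir optional directory; when given, run tables are written as
#'   CSV and summaries as JSON.
#' @return a list with the run table(s) and the preset's summary statistics.
#' @export
presetExperiment <- function(name = c("convergence", "sweep2", "sweep3",
                                      "classify2", "classify3",
                                      "firstpassage"),
                             nRuns = 2000, nSwitches = 312499,
                             nReplicates = 3, side = 25, masterSeed = 1,
                             outDir = NULL) {
  name <- match.arg(name)
  res <- switch(name,
    convergence = presetFirstPassageTriples(nSwitches, nReplicates, side,
                                            masterSeed),
    sweep2 = presetSweep(2L, nRuns, NULL, nSwitches, side, masterSeed),
    sweep3 = presetSweep(3L, nRuns, 3, nSwitches, side, masterSeed),
    classify2 = presetFits(2L, nRuns, NULL, nSwitches, side, masterSeed),
    classify3 = presetFits(3L, nRuns, 3, nSwitches, side, masterSeed),
    firstpassage = presetFirstPassageSweep(nRuns, nSwitches, side, masterSeed))
  if (!is.null(outDir)) writePreset(res, name, outDir)
  res
}

referenceTriples <- function() {
  list(`0` = c(0.5, 0.5, -1), `2` = c(-0.5, 1.5, -1), `4` = c(-1.5, 2.5, -1),
       `6` = c(3.5, -2.5, -1), `8` = c(-3.5, 4.5, -1))
}

presetFirstPassageTriples <- function(nSwitches, nReplicates, side,
                                      masterSeed) {
  triples <- referenceTriples()
  counts <- defaultCounts(side, 2L)
  extremes <- orderExtremes(side, 2L, counts)
  set.seed(masterSeed)
  seeds <- sample.int(2147483646L, length(triples) * nReplicates)
  rows <- list()
  k <- 0L
  for (nm in names(triples)) {
    p <- adhesionParams(triples[[nm]])
    for (rep in seq_len(nReplicates)) {
      k <- k + 1L
      cfg <- randomConfig(side, counts, seed = seeds[k])
      tr <- runDMM(cfg, p, nSwitches = nSwitches, seed = seeds[k],
                   extremes = extremes)
      fp <- firstPassage(tr, c(0.7, 0.8, 0.9))
      rows[[k]] <- data.frame(beta_delta = as.numeric(nm), replicate = rep,
                              seed = seeds[k],
                              threshold = c(0.7, 0.8, 0.9),
                              first_passage = unname(fp),
                              omega_bar = asymptoticOmega(tr))
    }
  }
  fpTable <- do.call(rbind, rows)
  list(firstPassage = fpTable)
}

presetSweep <- function(nTypes, nRuns, maxBetaDelta, nSwitches, side,
                        masterSeed) {
  tab <- sweepRuns(nTypes, nRuns, maxBetaDelta = maxBetaDelta,
                   nSwitches = nSwitches, side = side,
                   masterSeed = masterSeed)
  list(runs = tab, correlations = rankCorrelations(tab))
}

presetFits <- function(nTypes, nRuns, maxBetaDelta, nSwitches, side,
                       masterSeed) {
  res <- presetSweep(nTypes, nRuns, maxBetaDelta, nSwitches, side, masterSeed)
  tab <- classifyRuns(res$runs)
  list(runs = tab, correlations = res$correlations,
       svm = fitHyperplane(tab, "svm"),
       logit = fitHyperplane(tab, "logit"))
}

presetFirstPassageSweep <- function(nRuns, nSwitches, side, masterSeed) {
  betas <- drawBeta(2L, nRuns, seed = masterSeed)
  runSeeds <- sample.int(2147483646L, nRuns)
  counts <- defaultCounts(side, 2L)
  extremes <- orderExtremes(side, 2L, counts)
  rows <- lapply(seq_len(nRuns), function(i) {
    p <- betas[[i]]
    cfg <- randomConfig(side, counts, seed = runSeeds[i])
    tr <- runDMM(cfg, p, nSwitches = nSwitches, seed = runSeeds[i],
                 extremes = extremes)
    fp <- firstPassage(tr, c(0.7, 0.8, 0.9))
    data.frame(run_id = i, seed = runSeeds[i],
               beta_star = effectiveAdhesion(p),
               beta_delta = convergenceSpeed(p),
               omega_bar = asymptoticOmega(tr),
               fp_0.7 = unname(fp[1L]), fp_0.8 = unname(fp[2L]),
               fp_0.9 = unname(fp[3L]))
  })
  list(runs = do.call(rbind, rows))
}

writePreset <- function(res, name, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(outDir, paste0(name, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  summary <- lapply(res, function(x) {
    if (is.data.frame(x)) NULL
    else if (is(x, "HyperplaneFit"))
      list(method = x@method, relative = as.list(x@relative),
           cv_accuracy = x@cvAccuracy, n_points = x@nPoints)
    else x
  })
  summary <- summary[!vapply(summary, is.null, logical(1L))]
  jsonlite::write_json(summary, file.path(outDir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
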