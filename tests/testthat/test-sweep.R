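test_that("parameter draws respect the box, constraint and seed", {
  betas <- drawBeta(3, 50, seed = 3)
  vals <- do.call(rbind, lapply(betas, betaVector))
  expect_true(all(vals >= -10 & vals <= 10))
  expect_equal(dim(vals), c(50L, 6L))
  # same seed reproduces the draws
  again <- drawBeta(3, 50, seed = 3)
  expect_equal(vals, do.call(rbind, lapply(again, betaVector)))
  # rejection constraint holds for every accepted draw
  constrained <- drawBeta(3, 50, maxBetaDelta = 3, seed = 4)
  expect_true(all(vapply(constrained, convergenceSpeed, numeric(1)) < 3))
  # an impossible constraint errors instead of looping forever
  expect_error(drawBeta(2, 1, constraint = function(p) FALSE, seed = 1,
                        minAcceptance = 0.1), "rejection rate")
})

test_that("sweeps are reproducible and carry consistent derived columns", {
  tab <- sweepRuns(2, 5, nSwitches = 2000, masterSeed = 7)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("b00", "b11", "b01", "beta_s", "beta_star", "beta_delta",
                    "omega_bar", "class_label") %in% names(tab)))
  expect_equal(tab$beta_star, tab$b00 + tab$b11 - 2 * tab$b01)
  expect_equal(tab$beta_delta, abs(tab$b00 - tab$b11))
  expect_true(all(tab$omega_bar >= 0 & tab$omega_bar <= 1))
  expect_true(all(is.na(tab$class_label)))
  tab2 <- sweepRuns(2, 5, nSwitches = 2000, masterSeed = 7)
  expect_equal(tab, tab2)
  # constrained three-type sweep: every row satisfies the constraint
  tab3 <- sweepRuns(3, 4, maxBetaDelta = 3, nSwitches = 2000, masterSeed = 8)
  expect_true(all(tab3$beta_delta < 3))
})

test_that("rank correlations behave on trivial inputs", {
  tab <- data.frame(beta_star = 1:20,
                    omega_bar = plogis(seq(-3, 3, length.out = 20)))
  rc <- rankCorrelations(tab)
  expect_equal(unname(rc["spearman"]), 1)
  expect_equal(unname(rc["kendall"]), 1)
  set.seed(5)
  shuf <- data.frame(beta_star = rnorm(300), omega_bar = rnorm(300))
  expect_lt(abs(rankCorrelations(shuf)["spearman"]), 0.15)
  const <- data.frame(beta_star = rep(1, 20), omega_bar = runif(20))
  expect_error(rankCorrelations(const), "constant column")
})

test_that("classification thresholds at the random-mixture level, strictly", {
  tab <- data.frame(n_types = 2L, omega_bar = c(0.6, 0.5, 0.49, 0.51))
  lab <- classifyRuns(tab)
  expect_equal(lab$class_label, c(1L, -1L, -1L, 1L))  # 0.5 exactly -> -1
  tab3 <- data.frame(n_types = 3L, omega_bar = c(0.34, 0.3))
  expect_equal(classifyRuns(tab3)$class_label, c(1L, -1L))
  expect_equal(classifyRuns(tab, threshold = 0.55)$class_label,
               c(1L, -1L, -1L, -1L))
})

test_that("both estimators recover the analytic boundary from labeled draws", {
  for (N in 2:3) {
    tab <- analyticRunTable(N, 500)
    expected <- -2 / (N - 1)
    for (m in c("svm", "logit")) {
      fit <- fitHyperplane(tab, m, cost = 1000)
      expect_equal(fit@relative[["a/a"]], 1)
      expect_equal(fit@relative[["b/a"]], expected, tolerance = 0.02)
      # the recovered direction is within 1% angular error of the
      # effective-adhesion direction (1, -2/(N-1))
      v <- c(1, fit@relative[["b/a"]])
      ref <- c(1, expected)
      cosang <- sum(v * ref) / sqrt(sum(v^2) * sum(ref^2))
      expect_gt(cosang, cos(0.01))
      # analytic labels are fully separable: the full fit classifies
      # every point correctly
      feats <- dmmsort:::reducedFeatures(tab)
      score <- fit@a * feats$hom_sum + fit@b * feats$het_sum + fit@intercept
      expect_equal(ifelse(score > 0, 1L, -1L), tab$class_label)
    }
  }
  # single-class input is rejected
  one <- analyticRunTable(2, 50)
  one$class_label <- 1L
  expect_error(fitHyperplane(one), "both classes")
})

test_that("presets regenerate their experiment structure at reduced scale", {
  res <- presetExperiment("convergence", nSwitches = 3000, nReplicates = 1,
                          side = 10, masterSeed = 5)
  fp <- res$firstPassage
  expect_equal(sort(unique(fp$beta_delta)), c(0, 2, 4, 6, 8))
  expect_equal(unique(fp$threshold), c(0.7, 0.8, 0.9))
  # the reference triples all share effective adhesion parameter 3
  triples <- dmmsort:::referenceTriples()
  expect_equal(vapply(triples, function(b)
    effectiveAdhesion(adhesionParams(b)), numeric(1)),
    c(`0` = 3, `2` = 3, `4` = 3, `6` = 3, `8` = 3))
  expect_equal(vapply(names(triples), function(nm)
    convergenceSpeed(adhesionParams(triples[[nm]])), numeric(1)),
    c(`0` = 0, `2` = 2, `4` = 4, `6` = 6, `8` = 8))
  # a scaled-down fit preset writes CSV + JSON summaries
  outDir <- tempfile()
  res1 <- presetExperiment("classify2", nRuns = 30, nSwitches = 2000,
                           side = 10, masterSeed = 6, outDir = outDir)
  expect_s4_class(res1$svm, "HyperplaneFit")
  expect_s4_class(res1$logit, "HyperplaneFit")
  expect_true(file.exists(file.path(outDir, "classify2_runs.csv")))
  expect_true(file.exists(file.path(outDir, "classify2_summary.json")))
  expect_error(presetExperiment("nope"), "should be one of")
})
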