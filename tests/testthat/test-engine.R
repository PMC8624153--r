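test_that("runs are reproducible and indexed by switch count", {
  cfg <- randomConfig(10, nTypes = 2, seed = 1)
  p <- adhesionParams(c(0.8, 0.2, -0.5))
  t1 <- runDMM(cfg, p, nSwitches = 500, recordStride = 1, seed = 3)
  t2 <- runDMM(cfg, p, nSwitches = 500, recordStride = 1, seed = 3)
  expect_identical(t1@omega, t2@omega)
  expect_identical(latticeTypes(t1@finalConfig), latticeTypes(t2@finalConfig))
  # indices advance by exactly one per switch at stride 1
  expect_equal(t1@switchIndex, 0:500)
  expect_true(all(t1@omega >= 0 & t1@omega <= 1))
  # counts conserved end to end
  expect_equal(typeCounts(t1@finalConfig), typeCounts(cfg))
  # zero switches: only the start is recorded
  t0 <- runDMM(cfg, p, nSwitches = 0, recordStride = 1, seed = 3)
  expect_equal(t0@switchIndex, 0)
  expect_identical(latticeTypes(t0@finalConfig), latticeTypes(cfg))
})

test_that("selection frequencies match rate/total over many draws", {
  # small lattice held one step at a time via the R reference stepper
  cfg <- randomConfig(4, counts = c(13, 3), seed = 2)
  p <- adhesionParams(c(0.5, -0.5, 0.3))
  tab <- buildEventTable(cfg, p)
  total <- attr(tab, "totalRate")
  keys <- paste(tab$x_row, tab$x_col, tab$y_row, tab$y_col)
  set.seed(99)
  n <- 20000
  picks <- character(n)
  waits <- numeric(n)
  for (i in seq_len(n)) {
    st <- stepDMM(cfg, p)  # always from the same configuration
    picks[i] <- paste(st$x[1], st$x[2], st$y[1], st$y[2])
    waits[i] <- st$waitingTime
  }
  freq <- table(factor(picks, levels = keys)) / n
  prob <- tab$rate / total
  # 3-sigma binomial envelope per event
  sigma <- sqrt(prob * (1 - prob) / n)
  expect_true(all(abs(as.numeric(freq) - prob) <= 3 * sigma + 1e-12))
  # waiting times are exponential with the total rate
  expect_equal(mean(waits), 1 / total, tolerance = 4 / sqrt(n))
})

test_that("incrementally maintained event table equals a rebuilt one", {
  for (seedK in 1:3) {
    cfg <- randomConfig(8, nTypes = 3, seed = seedK)
    p <- adhesionParams(c(1.5, -2, 0.6, 0.8, -0.3, 0.1))
    # periodic refresh disabled so the test sees pure incremental updates
    tr <- runDMM(cfg, p, nSwitches = 3000, seed = seedK, refreshEvery = 0)
    set.seed(seedK)
    res <- dmmsort:::.dmm_run(latticeTypes(cfg), betaMatrix(p), 3000,
                              3000L, FALSE, 0L)
    fresh <- dmmsort:::allEdgeRates(tr@finalConfig, p)
    expect_equal(res$edge_rates, fresh, tolerance = 1e-12)
    expect_equal(res$total_rate, sum(fresh), tolerance = 1e-9)
  }
})

test_that("switch-averaged omega matches the exact jump-chain expectation", {
  # 3x3 torus, two types with counts (4,5): 126 enumerable configurations
  p <- adhesionParams(c(0.3, -0.2, 0.4))
  ex <- orderExtremes(3, 2, c(4, 5), method = "exhaustive")
  jc <- jumpChainStationary(3, c(4, 5), p, ex)
  expect_equal(nrow(jc$configs), 126L)
  expect_equal(sum(jc$pi), 1)
  tr <- runDMM(randomConfig(3, c(4, 5), seed = 1), p, nSwitches = 1e6,
               recordStride = 1, seed = 42, extremes = ex)
  sim <- mean(tr@omega[-1])
  # batch means to account for autocorrelation of the chain
  batches <- colMeans(matrix(tr@omega[-1], ncol = 100))
  se <- stats::sd(batches) / sqrt(100)
  expect_lt(abs(sim - jc$expectedOmega), 3 * se)
})

test_that("a global shift leaves the switch sequence invariant and rescales time", {
  cfg <- randomConfig(10, nTypes = 2, seed = 5)
  p <- adhesionParams(c(0.5, -0.3, 0.2))
  theta <- 0.7
  pShift <- adhesionParams(betaMatrix(p) + theta)
  t1 <- runDMM(cfg, p, nSwitches = 2000, recordStride = 1, seed = 9,
               recordWaiting = TRUE)
  t2 <- runDMM(cfg, pShift, nSwitches = 2000, recordStride = 1, seed = 9,
               recordWaiting = TRUE)
  expect_identical(t1@omega, t2@omega)
  expect_identical(latticeTypes(t1@finalConfig), latticeTypes(t2@finalConfig))
  expect_equal(t2@waitingTimes, t1@waitingTimes * exp(8 * theta),
               tolerance = 1e-9)
})

test_that("trajectories serialize to CSV with a provenance sidecar", {
  cfg <- randomConfig(6, nTypes = 2, seed = 4)
  p <- adhesionParams(c(0.4, 0.1, -0.2))
  tr <- runDMM(cfg, p, nSwitches = 200, recordStride = 1, seed = 8,
               recordWaiting = TRUE)
  path <- tempfile(fileext = ".csv")
  writeTrajectory(tr, path)
  back <- readTrajectory(path)
  expect_equal(back$data$switch_index, tr@switchIndex)
  expect_equal(back$data$omega, tr@omega)
  expect_equal(back$data$waiting_time[-1], tr@waitingTimes)
  expect_equal(unlist(back$provenance$beta), unname(betaVector(p)))
  expect_equal(back$provenance$seed, 8)
})
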