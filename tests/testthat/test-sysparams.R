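test_that("scaling parameter sums all bond strengths", {
  expect_equal(scalingParam(adhesionParams(c(1, 1, -1))), 1)
  expect_equal(scalingParam(adhesionParams(rep(0, 6))), 0)
  # shift by theta adds theta * (N + N(N-1)/2)
  p <- adhesionParams(c(0.3, -0.7, 1.1, 0.2, -0.4, 0.9))
  expect_equal(scalingParam(adhesionParams(betaMatrix(p) + 0.5)),
               scalingParam(p) + 0.5 * 6)
})

test_that("effective adhesion parameter matches its closed forms", {
  expect_equal(effectiveAdhesion(adhesionParams(c(0.5, 0.5, -1))), 3)
  # three types: sum of homotypic minus sum of heterotypic entries
  expect_equal(effectiveAdhesion(
    adhesionParams(c(0.6, 0.6, 2.3, -0.9, -1.1, -1.5))), 7)
  # all entries equal: homotypic and heterotypic contributions cancel
  for (N in 2:5) {
    k <- N + N * (N - 1) / 2
    expect_equal(effectiveAdhesion(adhesionParams(rep(1.7, k))), 0)
  }
  # invariance under a global shift (orthogonality to the scaling direction)
  set.seed(4)
  for (N in 2:4) {
    k <- N + N * (N - 1) / 2
    p <- adhesionParams(stats::runif(k, -5, 5))
    th <- stats::runif(1, -3, 3)
    expect_equal(effectiveAdhesion(adhesionParams(betaMatrix(p) + th)),
                 effectiveAdhesion(p), tolerance = 1e-10)
  }
})

test_that("the defining directions are orthogonal for N = 2..10", {
  for (N in 2:10) {
    dirs <- paramDirections(N)
    kHet <- N * (N - 1) / 2
    # exact integer identity: scale a_star by (N-1) to clear the fraction,
    # then <a_s, (N-1) a_star> = N(N-1) - 2 * N(N-1)/2 = 0 exactly
    scaled <- c(rep(N - 1L, N), rep(-2L, kHet))
    expect_identical(sum(as.integer(dirs$a_s) * scaled), 0L)
    expect_equal(dirs$a_star, scaled / (N - 1))
  }
})

test_that("convergence speed parameter: pairwise and distance forms", {
  expect_equal(convergenceSpeed(adhesionParams(c(-1.5, 2.5, -1))), 4)
  expect_equal(convergenceSpeed(adhesionParams(c(0.5, 0.5, -1))), 0)
  # two-type distance form is |b00 - b11| / sqrt(2)
  set.seed(6)
  for (k in 1:10) {
    p <- adhesionParams(stats::runif(3, -5, 5))
    expect_equal(convergenceSpeed(p, definition = "distance"),
                 convergenceSpeed(p, definition = "pairwise") / sqrt(2))
  }
  # symmetric vectors have zero convergence speed for any N
  expect_equal(convergenceSpeed(adhesionParams(c(2, 2, 2, -1, -1, -1))), 0)
})

test_that("symmetric projection preserves beta_s and beta* and is idempotent", {
  expect_equal(betaVector(symmetricProjection(adhesionParams(c(-0.5, 1.5, -1)))),
               betaVector(adhesionParams(c(0.5, 0.5, -1))))
  set.seed(7)
  for (N in 2:4) {
    k <- N + N * (N - 1) / 2
    p <- adhesionParams(stats::runif(k, -5, 5))
    s <- symmetricProjection(p)
    expect_equal(scalingParam(s), scalingParam(p))
    expect_equal(effectiveAdhesion(s), effectiveAdhesion(p))
    expect_equal(convergenceSpeed(s, definition = "distance"), 0)
    expect_equal(betaVector(symmetricProjection(s)), betaVector(s))
  }
})

test_that("limit-scenario rates obey the exp(3*beta*) ratio identity", {
  p0 <- adhesionParams(c(0, 0, 0))
  hr <- heuristicRates(p0)
  expect_equal(unname(unlist(hr)), rep(1, 4))
  set.seed(12)
  for (k in 1:200) {
    p <- adhesionParams(stats::runif(3, -10, 10))
    hr <- heuristicRates(p)
    expect_equal(hr$c_mix,
                 exp(-(3 * (betaMatrix(p)[1, 1] + betaMatrix(p)[2, 2]) +
                       2 * betaMatrix(p)[1, 2])))
    expect_equal(hr$unmix_mix_ratio, exp(3 * effectiveAdhesion(p)),
                 tolerance = 1e-9)
  }
  expect_error(heuristicRates(adhesionParams(rep(0, 6))), "two cell types")
})

test_that("contact tensions map to the effective adhesion parameter", {
  expect_equal(tensionToEAP(matrix(0, 2, 2)), 0)
  expect_equal(tensionToEAP(matrix(c(2, 2, 2, 2), 2, 2)), 0)  # uniform tension
  set.seed(13)
  for (k in 1:20) {
    T <- matrix(0, 2, 2)
    T[1, 1] <- stats::runif(1, -3, 3); T[2, 2] <- stats::runif(1, -3, 3)
    T[1, 2] <- T[2, 1] <- stats::runif(1, -3, 3)
    expect_equal(tensionToEAP(T), effectiveAdhesion(adhesionParams(-T)))
    expect_equal(tensionToEAP(T), -T[1, 1] - T[2, 2] + 2 * T[1, 2])
  }
})
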