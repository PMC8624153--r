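# shared fixtures and cached heavy computations

# a 5x5 two-type configuration with a single type-0 cell at (2,2)
intruderConfig <- function() {
  tm <- matrix(1L, 5, 5)
  tm[3, 3] <- 0L
  new("LatticeConfig", side = 5L, nTypes = 2L, types = tm)
}

# hand-built 4x4 two-type configuration with a known homotypic contact count
#   0 0 1 1
#   0 0 1 1
#   1 1 0 0
#   1 1 0 0
# Each 2x2 block contributes 4 internal homotypic edges (2 horizontal + 2
# vertical); all block-to-block edges, including wrap edges, are heterotypic
# except where diagonal blocks of equal type meet -- here they never share an
# edge, so d = 4 blocks * 4 = 16.
blockConfig <- function() {
  tm <- rbind(c(0L, 0L, 1L, 1L),
              c(0L, 0L, 1L, 1L),
              c(1L, 1L, 0L, 0L),
              c(1L, 1L, 0L, 0L))
  new("LatticeConfig", side = 4L, nTypes = 2L, types = tm)
}

# cache for expensive shared objects (sweeps reused across test files)
.cache <- new.env(parent = emptyenv())

cachedSweep2 <- function() {
  if (is.null(.cache$sweep2))
    .cache$sweep2 <- sweepRuns(2, 500, nSwitches = 312499, masterSeed = 2024)
  .cache$sweep2
}

cachedSweep3 <- function() {
  if (is.null(.cache$sweep3))
    .cache$sweep3 <- sweepRuns(3, 500, maxBetaDelta = 3, nSwitches = 312499,
                               masterSeed = 2025)
  .cache$sweep3
}

# analytic run table: labels are the sign of the effective adhesion
# parameter, no simulation involved
analyticRunTable <- function(nTypes, n = 500, seed = 77) {
  betas <- drawBeta(nTypes, n, seed = seed)
  tab <- as.data.frame(do.call(rbind, lapply(betas, betaVector)))
  tab$n_types <- nTypes
  tab$beta_star <- vapply(betas, effectiveAdhesion, numeric(1))
  tab <- tab[abs(tab$beta_star) > 1e-9, ]
  tab$omega_bar <- ifelse(tab$beta_star > 0, 1, 0)
  tab$class_label <- ifelse(tab$beta_star > 0, 1L, -1L)
  tab
}
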