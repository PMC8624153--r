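#' Run one event-driven sorting simulation
#'
#' Simulates the lattice dynamics with a Gillespie-type algorithm: the rates
#' of all adjacent heterotypic pairs are kept in an incrementally updated
#' event table, a pair is sampled with probability proportional to its rate,
#' an exponential waiting time with the total rate is drawn (pair first, then
#' time, from one seeded stream), the switch is applied and only the rates of
#' events touching the switched sites and their neighbourhoods are
#' recomputed. The trajectory is indexed by the number of switches performed;
#' the order indicator is recorded every `recordStride` switches plus at the
#' start and the end.
#'
#' The default termination after 312,499 switches corresponds to 500
#' sweeps-worth of movement on the default 25 x 25 lattice; the default
#' stride keeps about 1000 recorded points so the last-10% averaging window
#' of [asymptoticOmega()] always contains at least 100 points.
#'
#' @param config starting [LatticeConfig-class].
#' @param params an [AdhesionParams-class] with `nTypes(params) >=`
#'   the number of types in `config`.
#' @param nSwitches number of cell switches to perform (default 312499).
#' @param recordStride recording stride in switches; default
#'   `max(1, floor(nSwitches / 1000))`.
#' @param seed optional integer seed; same seed and inputs give a
#'   bit-identical trajectory.
#' @param recordWaiting keep the per-switch exponential waiting times
#'   (memory-heavy for long runs; off by default).
#' @param extremes [OrderExtremes-class] used to normalize the order
#'   indicator; computed for the configuration when omitted.
#' @param refreshEvery rebuild the full event table every this many switches
#'   to cap floating-point drift in the maintained rate sums (default 10000;
#'   0 disables, used by consistency tests).
#' @return a [Trajectory-class].
#' @examples
#' cfg <- randomConfig(10, nTypes = 2, seed = 7)
#' tr <- runDMM(cfg, adhesionParams(c(1, 1, -1)), nSwitches = 2000, seed = 7)
#' asymptoticOmega(tr)
#' @export
runDMM <- function(config, params, nSwitches = 312499, recordStride = NULL,
                   seed = NULL, recordWaiting = FALSE, extremes = NULL,
                   refreshEvery = 10000) {
  stopifnot(is(config, "LatticeConfig"), is(params, "AdhesionParams"))
  if (params@nTypes < config@nTypes)
    stop("params cover fewer types than present in the configuration")
  if (nSwitches < 0) stop("nSwitches must be nonnegative")
  if (is.null(recordStride))
    recordStride <- max(1L, as.integer(floor(nSwitches / 1000)))
  if (is.null(extremes))
    extremes <- orderExtremes(config@side, config@nTypes, typeCounts(config))
  if (!is.null(seed)) set.seed(seed)
  res <- .dmm_run(config@types, params@beta, as.numeric(nSwitches),
                  as.integer(recordStride), isTRUE(recordWaiting),
                  as.integer(refreshEvery))
  omega <- (res$d - extremes@dMin) / (extremes@dMax - extremes@dMin)
  omega <- pmin(pmax(omega, 0), 1)
  new("Trajectory",
      switchIndex = res$switch_index, omega = omega,
      waitingTimes = res$waiting_times, params = params,
      extremes = extremes,
      finalConfig = newConfig(res$types, config@nTypes),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      stride = as.integer(recordStride))
}

#' @export
setMethod("show", "Trajectory", function(object) {
  n <- length(object@switchIndex)
  cat("Trajectory:", max(object@switchIndex), "switches,", n,
      "recorded points\n")
  cat("  omega(0) =", signif(object@omega[1L], 3),
      " omega(end) =", signif(object@omega[n], 3))
  if (n >= 10L)
    cat("  omega_bar =", signif(asymptoticOmega(object), 3))
  cat("\n")
  invisible(object)
})

#' Exact jump-chain analysis on a small lattice
#'
#' Enumerates every configuration with the given per-type counts, builds the
#' transition matrix of the embedded jump chain (each heterotypic neighbour
#' pair is one transition, taken with probability rate / total rate), solves
#' its stationary distribution and returns the exact expectation of the order
#' indicator under it. Because the simulated time axis counts switches, the
#' switch-averaged order indicator of a long run converges to exactly this
#' expectation, which makes the function an independent correctness oracle
#' for the event-driven engine. Only feasible on lattices with a few hundred
#' thousand states or fewer (e.g. 3 x 3).
#'
#' @param side lattice side length (>= 3).
#' @param counts per-type cell counts summing to `side^2`.
#' @param params an [AdhesionParams-class].
#' @param extremes optional [OrderExtremes-class]; exhaustive extremes for
#'   the same lattice are computed when omitted.
#' @param maxStates safety cap on the number of configurations.
#' @return list with `expectedOmega`, the stationary distribution `pi`, the
#'   per-configuration `omega`, and the configuration matrix `configs`
#'   (one row per configuration, row-major 0-based types).
#' @export
jumpChainStationary <- function(side, counts, params, extremes = NULL,
                                maxStates = 2e5) {
  side <- as.integer(side)
  counts <- as.integer(counts)
  stopifnot(sum(counts) == side^2, is(params, "AdhesionParams"))
  if (countStates(side^2, counts) > maxStates)
    stop("state space too large to enumerate")
  cfgs <- enumAssignments(side^2, counts)
  nStates <- nrow(cfgs)
  key <- apply(cfgs, 1L, paste, collapse = ",")
  lookup <- seq_len(nStates)
  names(lookup) <- key
  if (is.null(extremes))
    extremes <- orderExtremes(side, length(counts), counts,
                              method = "exhaustive")
  P <- matrix(0, nStates, nStates)
  omega <- numeric(nStates)
  for (i in seq_len(nStates)) {
    tv <- cfgs[i, ]
    cfg <- newConfig(matrix(tv, side, side, byrow = TRUE), length(counts))
    omega[i] <- orderIndicator(cfg, extremes)
    rates <- allEdgeRates(cfg, params)
    live <- which(rates > 0)
    total <- sum(rates[live])
    for (e in live) {
      s <- (e - 1L) %/% 2L
      a <- s + 1L
      b <- if ((e - 1L) %% 2L == 0L) {
        r <- s %/% side; c <- s %% side
        r * side + (c + 1L) %% side + 1L
      } else {
        r <- s %/% side; c <- s %% side
        ((r + 1L) %% side) * side + c + 1L
      }
      tv2 <- tv
      tv2[c(a, b)] <- tv2[c(b, a)]
      j <- lookup[[paste(tv2, collapse = ",")]]
      P[i, j] <- P[i, j] + rates[e] / total
    }
  }
  # stationary distribution: solve pi = pi P with sum(pi) = 1
  A <- t(P) - diag(nStates)
  A[nStates, ] <- 1
  rhs <- c(rep(0, nStates - 1L), 1)
  statDist <- solve(A, rhs)
  statDist[statDist < 0 & statDist > -1e-12] <- 0
  statDist <- statDist / sum(statDist)
  list(expectedOmega = sum(statDist * omega), pi = statDist, omega = omega,
       configs = cfgs)
}
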