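#' Cell switch rate of an adjacent pair
#'
#' Rate at which the cells at adjacent sites `x` and `y` exchange positions.
#' A homotypic pair has rate 0 (the exchange would not change the
#' configuration). A heterotypic pair switches with rate
#' \deqn{c(x,y,\eta) = \exp\Big(-\sum_{z \in N(x)} \beta_{\eta(x)\eta(z)}
#'   - \sum_{z \in N(y)} \beta_{\eta(y)\eta(z)}\Big),}
#' where each von Neumann neighbourhood includes the partner site, so the
#' exponent is a sum of 8 bond terms. Consequently adding a constant
#' \eqn{\theta} to every bond strength multiplies every rate by
#' \eqn{\exp(-8\theta)}, rescaling waiting times without changing the order
#' of events.
#'
#' @param config a [LatticeConfig-class].
#' @param x,y adjacent 0-based `c(row, col)` sites.
#' @param params an [AdhesionParams-class].
#' @return a single nonnegative rate; strictly positive for heterotypic pairs.
#' @examples
#' cfg <- referenceConfig("stripes", 6, 2)
#' p <- adhesionParams(c(1, 1, -1))
#' switchRate(cfg, c(2, 0), c(3, 0), p)  # interface pair: exp(-4)
#' @export
switchRate <- function(config, x, y, params) {
  stopifnot(is(config, "LatticeConfig"), is(params, "AdhesionParams"))
  if (!isAdjacent(x, y, config@side))
    stop("contract violation: sites are not adjacent on the torus")
  tm <- config@types
  b <- params@beta
  tx <- tm[x[1L] + 1L, x[2L] + 1L]
  ty <- tm[y[1L] + 1L, y[2L] + 1L]
  if (tx == ty) return(0)
  nx <- vonNeumannNeighbors(x, config@side)
  ny <- vonNeumannNeighbors(y, config@side)
  ex <- sum(b[cbind(tx + 1L, tm[nx + 1L] + 1L)]) +
        sum(b[cbind(ty + 1L, tm[ny + 1L] + 1L)])
  exp(-ex)
}

# Per-site local bond field: F[x] = sum over z in N(x) of beta[t(x), t(z)].
# The switch-rate exponent of edge (x, y) is F[x] + F[y].
localField <- function(typesMatrix, beta) {
  L <- nrow(typesMatrix)
  up <- typesMatrix[c(L, seq_len(L - 1L)), , drop = FALSE]
  down <- typesMatrix[c(seq_len(L)[-1L], 1L), , drop = FALSE]
  left <- typesMatrix[, c(L, seq_len(L - 1L)), drop = FALSE]
  right <- typesMatrix[, c(seq_len(L)[-1L], 1L), drop = FALSE]
  own <- typesMatrix + 1L
  matrix(beta[cbind(c(own), c(up) + 1L)] + beta[cbind(c(own), c(down) + 1L)] +
         beta[cbind(c(own), c(left) + 1L)] + beta[cbind(c(own), c(right) + 1L)],
         L, L)
}

# Rates of all 2*side^2 lattice edges in the canonical edge order
# e = 2*(row*side + col) + dir, dir 0 = right neighbour, dir 1 = down
# neighbour (0-based, row-major). Homotypic edges have rate 0.
allEdgeRates <- function(config, params) {
  tm <- config@types
  L <- config@side
  f <- localField(tm, params@beta)
  right <- tm[, c(seq_len(L)[-1L], 1L), drop = FALSE]
  down <- tm[c(seq_len(L)[-1L], 1L), , drop = FALSE]
  fRight <- f[, c(seq_len(L)[-1L], 1L), drop = FALSE]
  fDown <- f[c(seq_len(L)[-1L], 1L), , drop = FALSE]
  # row-major site order: s = row*L + col
  siteR <- rep(0:(L - 1L), each = L)
  siteC <- rep(0:(L - 1L), times = L)
  idx <- cbind(siteR + 1L, siteC + 1L)
  rateRight <- ifelse(tm[idx] == right[idx], 0, exp(-(f[idx] + fRight[idx])))
  rateDown <- ifelse(tm[idx] == down[idx], 0, exp(-(f[idx] + fDown[idx])))
  rates <- numeric(2L * L^2)
  rates[seq(1L, by = 2L, length.out = L^2)] <- rateRight
  rates[seq(2L, by = 2L, length.out = L^2)] <- rateDown
  rates
}

#' Event table of all possible switches
#'
#' Enumerates every unordered adjacent heterotypic pair of the configuration
#' together with its switch rate. This is the rate bookkeeping that drives the
#' event-driven simulation; the compiled engine maintains the same table
#' incrementally.
#'
#' @param config a [LatticeConfig-class].
#' @param params an [AdhesionParams-class].
#' @return a `data.frame` with columns `x_row, x_col, y_row, y_col, rate`
#'   (0-based sites) and attribute `totalRate`.
#' @export
buildEventTable <- function(config, params) {
  stopifnot(is(config, "LatticeConfig"), is(params, "AdhesionParams"))
  if (length(unique(as.integer(config@types))) < 2L)
    stop("fewer than 2 types present: no switch events exist")
  L <- config@side
  rates <- allEdgeRates(config, params)
  e <- which(rates > 0) - 1L
  s <- e %/% 2L
  dir <- e %% 2L
  xr <- s %/% L; xc <- s %% L
  yr <- ifelse(dir == 1L, (xr + 1L) %% L, xr)
  yc <- ifelse(dir == 0L, (xc + 1L) %% L, xc)
  tab <- data.frame(x_row = xr, x_col = xc, y_row = yr, y_col = yc,
                    rate = rates[e + 1L])
  attr(tab, "totalRate") <- sum(tab$rate)
  tab
}

#' Single Gillespie step (reference implementation)
#'
#' Draws one event from the current event table: a pair is chosen with
#' probability proportional to its rate (first draw), then an exponential
#' waiting time with the total rate (second draw), and the switch is applied.
#' This R-level step rebuilds the event table from scratch each call and is
#' meant for small lattices and cross-checks; use [runDMM()] for simulations.
#'
#' @param config a [LatticeConfig-class].
#' @param params an [AdhesionParams-class].
#' @return list with elements `config` (after the switch), `x`, `y` (the
#'   chosen pair), `waitingTime`, and `rate` of the chosen event.
#' @export
stepDMM <- function(config, params) {
  tab <- buildEventTable(config, params)
  total <- attr(tab, "totalRate")
  if (!isTRUE(total > 0)) stop("frozen state: total switch rate is not positive")
  u <- stats::runif(1L) * total
  k <- findInterval(u, cumsum(tab$rate)) + 1L
  k <- min(k, nrow(tab))
  w <- -log(stats::runif(1L)) / total
  x <- c(tab$x_row[k], tab$x_col[k])
  y <- c(tab$y_row[k], tab$y_col[k])
  list(config = applySwitch(config, x, y), x = x, y = y,
       waitingTime = w, rate = tab$rate[k])
}
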