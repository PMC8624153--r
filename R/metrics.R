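#' Total number of homotypic contacts
#'
#' Counts the undirected nearest-neighbour contacts between cells of the same
#' type, i.e. half the sum over sites of the number of same-type von Neumann
#' neighbours. A single-type lattice has `2*side^2` homotypic contacts (every
#' edge of the torus); a perfect two-type chessboard has none.
#'
#' @param config a [LatticeConfig-class].
#' @return nonnegative integer \eqn{d(\eta)}.
#' @rdname totalHomotypic
#' @name totalHomotypic
#' @export
setMethod("totalHomotypic", "LatticeConfig", function(config) {
  tm <- config@types
  L <- config@side
  right <- tm[, c(seq_len(L)[-1L], 1L), drop = FALSE]
  down <- tm[c(seq_len(L)[-1L], 1L), , drop = FALSE]
  sum(tm == right) + sum(tm == down)
})

# undirected edge endpoint indices (1-based, row-major flat sites) of the torus
edgeEndpoints <- function(side) {
  L <- as.integer(side)
  s <- 0:(L^2 - 1L)
  r <- s %/% L; c <- s %% L
  right <- r * L + (c + 1L) %% L
  down <- ((r + 1L) %% L) * L + c
  cbind(a = rep(s, 2L) + 1L, b = c(right, down) + 1L)
}

# all assignments of the multiset of types given by `counts` to nSites slots;
# returns an integer matrix, one configuration per row (0-based types)
enumAssignments <- function(nSites, counts) {
  counts <- as.integer(counts)
  stopifnot(sum(counts) == nSites)
  build <- function(slots, counts, typeIdx, current) {
    if (length(counts) == 1L) {
      current[slots] <- typeIdx
      return(list(current))
    }
    res <- list()
    for (ch in utils::combn(slots, counts[1L], simplify = FALSE)) {
      cur <- current
      cur[ch] <- typeIdx
      res <- c(res, build(setdiff(slots, ch), counts[-1L], typeIdx + 1L, cur))
    }
    res
  }
  lst <- build(seq_len(nSites), counts, 0L, integer(nSites))
  do.call(rbind, lst)
}

countStates <- function(nSites, counts) {
  exp(lgamma(nSites + 1) - sum(lgamma(counts + 1)))
}

#' Normalization extremes of the order indicator
#'
#' Computes the maximal and minimal numbers of homotypic contacts attainable
#' for a lattice of a given side, number of types and per-type counts. On
#' lattices small enough to enumerate every configuration (`method = "auto"`
#' switches below 2e5 states) the extremes are exact; otherwise they are the
#' contact counts of constructed anchor patterns: horizontal stripes for the
#' maximum, the alternating chessboard (two types) or diagonal stripes
#' (`(row+col) mod N`) for the minimum. On sides where the minimizing pattern
#' does not tile the torus perfectly the result is flagged and `dMin` includes
#' the wrap defects.
#'
#' @param side lattice side length.
#' @param nTypes number of cell types.
#' @param counts per-type counts; defaults to a near-equal split.
#' @param method `"auto"`, `"constructive"` or `"exhaustive"`.
#' @return an [OrderExtremes-class].
#' @examples
#' orderExtremes(26, 2)  # dMin = 0 (chessboard), dMax = 1300 (stripes)
#' @export
orderExtremes <- function(side, nTypes, counts = NULL,
                          method = c("auto", "constructive", "exhaustive")) {
  method <- match.arg(method)
  side <- as.integer(side)
  nTypes <- as.integer(nTypes)
  if (is.null(counts)) counts <- defaultCounts(side, nTypes)
  counts <- as.integer(counts)
  stopifnot(sum(counts) == side^2, length(counts) == nTypes)
  if (method == "auto")
    method <- if (countStates(side^2, counts) <= 2e5) "exhaustive"
              else "constructive"
  if (method == "exhaustive") {
    cfgs <- enumAssignments(side^2, counts)
    ep <- edgeEndpoints(side)
    d <- apply(cfgs, 1L, function(tv) sum(tv[ep[, 1L]] == tv[ep[, 2L]]))
    return(new("OrderExtremes", side = side, nTypes = nTypes, counts = counts,
               dMin = as.integer(min(d)), dMax = as.integer(max(d)),
               method = "exhaustive", flagged = FALSE))
  }
  stripes <- referenceConfig("stripes", side, nTypes, counts)
  dMax <- totalHomotypic(stripes)
  minKind <- if (nTypes == 2L) "chessboard" else "diagonal_stripes"
  minCfg <- withCallingHandlers(
    referenceConfig(minKind, side, nTypes),
    warning = function(w) invokeRestart("muffleWarning"))
  dMin <- totalHomotypic(minCfg)
  flagged <- isTRUE(attr(minCfg, "flagged"))
  new("OrderExtremes", side = side, nTypes = nTypes, counts = counts,
      dMin = as.integer(dMin), dMax = as.integer(dMax),
      method = "constructive", flagged = flagged)
}

#' @export
setMethod("show", "OrderExtremes", function(object) {
  cat("OrderExtremes (", object@method, "): side ", object@side, ", ",
      object@nTypes, " types, counts ", paste(object@counts, collapse = "/"),
      "\n  dMin = ", object@dMin, ", dMax = ", object@dMax,
      if (object@flagged) "  [minimizing pattern has wrap defects]" else "",
      "\n", sep = "")
  invisible(object)
})

#' Order indicator of a configuration
#'
#' The normalized count of homotypic contacts,
#' \eqn{\omega(\eta) = (d(\eta) - d_{min}) / (d_{max} - d_{min})}: 0 at the
#' all-heterotypic extreme, 1 at full phase separation, about `1/N` for a
#' uniformly random configuration with near-equal counts.
#'
#' @param config a [LatticeConfig-class].
#' @param extremes an [OrderExtremes-class] for the matching side and number
#'   of types; computed on the fly when omitted.
#' @return \eqn{\omega \in [0, 1]}; values outside the constructed extremes
#'   are clipped with a warning.
#' @export
orderIndicator <- function(config, extremes = NULL) {
  stopifnot(is(config, "LatticeConfig"))
  if (is.null(extremes))
    extremes <- orderExtremes(config@side, config@nTypes,
                              typeCounts(config))
  stopifnot(is(extremes, "OrderExtremes"))
  if (extremes@side != config@side || extremes@nTypes != config@nTypes)
    stop("extremes were computed for a different lattice")
  d <- totalHomotypic(config)
  w <- (d - extremes@dMin) / (extremes@dMax - extremes@dMin)
  if (w < 0 || w > 1) {
    warning("configuration exceeds the constructed extremes; clipping omega")
    w <- min(max(w, 0), 1)
  }
  w
}

#' Asymptotic order indicator of a trajectory
#'
#' The asymptotic segregation level is estimated as the arithmetic mean of the
#' order indicator over the recorded points in the last 10% of the
#' switch-indexed time series (indices `t > 0.9 * t_max`).
#'
#' @param trajectory a [Trajectory-class] with at least 10 recorded points.
#' @return \eqn{\bar\omega \in [0, 1]}.
#' @export
asymptoticOmega <- function(trajectory) {
  stopifnot(is(trajectory, "Trajectory"))
  idx <- trajectory@switchIndex
  if (length(idx) < 10L)
    stop("trajectory too short: need at least 10 recorded points")
  keep <- idx > 0.9 * max(idx)
  mean(trajectory@omega[keep])
}

#' First-passage switch counts
#'
#' For each threshold, the smallest recorded switch index at which the order
#' indicator reaches or exceeds the threshold; `NA` when the trajectory never
#' does. Larger convergence speed parameters delay these passages.
#'
#' @param trajectory a [Trajectory-class].
#' @param thresholds numeric thresholds in (0, 1).
#' @return named numeric vector of switch counts (`NA` when not reached).
#' @export
firstPassage <- function(trajectory, thresholds = c(0.7, 0.8, 0.9)) {
  stopifnot(is(trajectory, "Trajectory"), all(thresholds > 0 & thresholds < 1))
  out <- vapply(thresholds, function(th) {
    hit <- which(trajectory@omega >= th)
    if (length(hit)) trajectory@switchIndex[hit[1L]] else NA_real_
  }, numeric(1L))
  names(out) <- format(thresholds)
  out
}
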