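#' Derived system parameters of a bond-strength vector
#'
#' Three scalar functionals of the bond strengths govern the sorting dynamics:
#'
#' * the scaling parameter \eqn{\beta^s = \sum_i \beta_{ii} +
#'   \sum_{i<j} \beta_{ij}}, the inner product with \eqn{a_s = (1,\dots,1)};
#'   it only rescales waiting times (adding \eqn{\theta} to every entry
#'   multiplies every switch rate by \eqn{\exp(-8\theta)});
#' * the effective adhesion parameter \eqn{\beta^* = \sum_i \beta_{ii} -
#'   \tfrac{2}{N-1} \sum_{i<j} \beta_{ij}}, the unique (up to scale) linear
#'   functional that is invariant under relabeling and orthogonal to
#'   \eqn{a_s}; it predicts the asymptotic segregation level, with critical
#'   value 0 at which the system stays randomly mixed;
#' * the convergence speed parameter \eqn{\beta^\Delta}: for two types the
#'   absolute homotypic difference \eqn{|\beta_{00} - \beta_{11}|}, for
#'   \eqn{N \ge 3} the Euclidean distance of the flat vector to its
#'   type-symmetric projection; larger values mean more switches are needed
#'   to reach the asymptotic level.
#'
#' `symmetricProjection()` replaces the homotypic entries by their mean and
#' the heterotypic entries by theirs; it preserves \eqn{\beta^s} and
#' \eqn{\beta^*} exactly and is the fastest-converging parameter set with
#' those values. `systemParams()` bundles the three scalars plus the pairwise
#' homotypic differences.
#'
#' @param params an [AdhesionParams-class].
#' @param ... for `convergenceSpeed`, optional `definition = c("auto",
#'   "pairwise", "distance")`: `"pairwise"` is the two-type
#'   \eqn{|\beta_{00}-\beta_{11}|} form, `"distance"` the projection
#'   distance (for two types these differ by a factor \eqn{\sqrt 2});
#'   `"auto"` uses `"pairwise"` for N = 2 and `"distance"` otherwise.
#' @return `scalingParam`, `effectiveAdhesion`, `convergenceSpeed`: a single
#'   number; `symmetricProjection`: an `AdhesionParams`; `systemParams`: a
#'   named list.
#' @examples
#' p <- adhesionParams(c(-0.5, 1.5, -1))
#' effectiveAdhesion(p)   # 3
#' convergenceSpeed(p)    # 2
#' symmetricProjection(p) # (0.5, 0.5, -1)
#' @name systemParams
NULL

#' @rdname systemParams
#' @export
setMethod("scalingParam", "AdhesionParams", function(params) {
  sum(betaVector(params))
})

#' @rdname systemParams
#' @export
setMethod("effectiveAdhesion", "AdhesionParams", function(params) {
  N <- params@nTypes
  v <- betaVector(params)
  hom <- v[seq_len(N)]
  het <- v[-seq_len(N)]
  sum(hom) - 2 / (N - 1) * sum(het)
})

#' @rdname systemParams
#' @export
setMethod("convergenceSpeed", "AdhesionParams",
          function(params, definition = c("auto", "pairwise", "distance")) {
  definition <- match.arg(definition)
  N <- params@nTypes
  if (definition == "auto")
    definition <- if (N == 2L) "pairwise" else "distance"
  if (definition == "pairwise") {
    if (N != 2L)
      stop("the pairwise definition |b00 - b11| applies to two types only")
    return(abs(params@beta[1L, 1L] - params@beta[2L, 2L]))
  }
  sqrt(sum((betaVector(params) - betaVector(symmetricProjection(params)))^2))
})

#' @rdname systemParams
#' @export
setMethod("symmetricProjection", "AdhesionParams", function(params) {
  N <- params@nTypes
  v <- betaVector(params)
  hom <- v[seq_len(N)]
  het <- v[-seq_len(N)]
  adhesionParams(c(rep(mean(hom), N), rep(mean(het), length(het))))
})

#' @rdname systemParams
#' @export
systemParams <- function(params) {
  stopifnot(is(params, "AdhesionParams"))
  N <- params@nTypes
  b <- params@beta
  pairs <- pairIndex(N)
  hetIdx <- which(pairs[, 1L] != pairs[, 2L])
  pd <- numeric(0)
  nm <- character(0)
  for (k in hetIdx) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    pd <- c(pd, abs(b[i + 1L, i + 1L] - b[j + 1L, j + 1L]))
    nm <- c(nm, paste0("d", i, j))
  }
  names(pd) <- nm
  list(beta_s = scalingParam(params),
       beta_star = effectiveAdhesion(params),
       beta_delta = convergenceSpeed(params),
       pairwise_deltas = pd)
}

#' Directions defining the system parameters
#'
#' Flat-vector forms of the functionals behind [scalingParam()]
#' (`a_s`, all ones) and [effectiveAdhesion()] (`a_star`, ones on homotypic
#' entries and `-2/(N-1)` on heterotypic entries). They are orthogonal for
#' every N, which is what makes the effective adhesion parameter insensitive
#' to the global waiting-time rescaling.
#'
#' @param nTypes number of cell types.
#' @return list with numeric vectors `a_s` and `a_star`.
#' @export
paramDirections <- function(nTypes) {
  N <- as.integer(nTypes)
  k <- flatLength(N)
  a_star <- c(rep(1, N), rep(-2 / (N - 1), k - N))
  list(a_s = rep(1, k), a_star = a_star)
}

#' Limit-scenario switch rates for two cell types
#'
#' Closed-form rates of the two heuristic limit scenarios that motivate the
#' effective adhesion parameter: a mixing switch of two cells at a straight
#' interface between clusters, `c_mix = exp(-(3*(b00 + b11) + 2*b01))`, and
#' the unmixing switches of a single cell of one type inside a cluster of the
#' other, `c_unmix0 = exp(-(3*b11 + 5*b01))` and
#' `c_unmix1 = exp(-(3*b00 + 5*b01))`. Their ratio
#' `c_unmix0 * c_unmix1 / c_mix^2` equals `exp(3*beta_star)` identically, so
#' the rates balance exactly at the critical value `beta_star = 0` where the
#' system is expected to stay mixed.
#'
#' @param params a two-type [AdhesionParams-class].
#' @return named list `c_mix`, `c_unmix_0`, `c_unmix_1`, `unmix_mix_ratio`.
#' @export
heuristicRates <- function(params) {
  stopifnot(is(params, "AdhesionParams"))
  if (params@nTypes != 2L)
    stop("limit-scenario rates are defined for two cell types")
  b00 <- params@beta[1L, 1L]
  b11 <- params@beta[2L, 2L]
  b01 <- params@beta[1L, 2L]
  cMix <- exp(-(3 * (b00 + b11) + 2 * b01))
  cU0 <- exp(-(3 * b11 + 5 * b01))
  cU1 <- exp(-(3 * b00 + 5 * b01))
  list(c_mix = cMix, c_unmix_0 = cU0, c_unmix_1 = cU1,
       unmix_mix_ratio = cU0 * cU1 / cMix^2)
}

#' Effective adhesion parameter from relative contact tensions
#'
#' Maps a symmetric 2x2 matrix of relative contact tensions (as used in
#' Cellular Potts descriptions of two-tissue segregation) to the effective
#' adhesion parameter by identifying high tension with low bond strength,
#' `beta_ij = -T_ij`, so `beta_star = -T00 - T11 + 2*T01`. High heterotypic
#' tension and strong differential adhesion both yield a large effective
#' adhesion parameter and hence strong segregation.
#'
#' @param tensions symmetric numeric 2x2 matrix of relative contact tensions
#'   (`T[1,1] = T00`, `T[1,2] = T01`, `T[2,2] = T11`).
#' @return the effective adhesion parameter of the mapped bond strengths.
#' @export
tensionToEAP <- function(tensions) {
  stopifnot(is.matrix(tensions), nrow(tensions) == 2L, ncol(tensions) == 2L)
  if (!isTRUE(all.equal(tensions, t(tensions), tolerance = 1e-9)))
    stop("tension matrix must be symmetric")
  effectiveAdhesion(adhesionParams(-tensions))
}
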