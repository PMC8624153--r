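#' @import methods
NULL

#' Intercellular adhesion parameters
#'
#' An `AdhesionParams` object holds the symmetric matrix of dimensionless bond
#' strengths \eqn{\beta_{ij}} between cell types \eqn{i,j \in \{0,\dots,N-1\}}.
#' Positive entries model binding that hinders cell motility; negative entries
#' model repulsion that enhances it. The object has an equivalent flat-vector
#' form of length \eqn{N + N(N-1)/2}: homotypic entries
#' \eqn{\beta_{00},\dots,\beta_{N-1,N-1}} first, then heterotypic pairs
#' \eqn{i<j} in lexicographic order, e.g.
#' \eqn{(\beta_{00},\beta_{11},\beta_{22},\beta_{01},\beta_{02},\beta_{12})}
#' for three types.
#'
#' @slot nTypes integer, number of cell types \eqn{N \ge 2}.
#' @slot beta symmetric numeric `nTypes x nTypes` matrix of bond strengths.
#'
#' @seealso [adhesionParams()], [betaVector()], [effectiveAdhesion()]
#' @export
setClass("AdhesionParams",
  representation(nTypes = "integer", beta = "matrix"),
  validity = function(object) {
    msg <- character(0)
    N <- object@nTypes
    b <- object@beta
    if (length(N) != 1L || is.na(N) || N < 2L)
      msg <- c(msg, "nTypes must be a single integer >= 2")
    if (!is.numeric(b) || nrow(b) != N || ncol(b) != N)
      msg <- c(msg, "beta must be a numeric nTypes x nTypes matrix")
    else {
      if (any(!is.finite(b)))
        msg <- c(msg, "beta entries must be finite")
      else if (!isTRUE(all.equal(b, t(b), tolerance = 1e-12)))
        msg <- c(msg, "beta must be symmetric (beta[i,j] == beta[j,i])")
    }
    if (length(msg)) msg else TRUE
  })

#' Lattice configuration of a multi-type cell population
#'
#' A `LatticeConfig` assigns one cell type to every site of a periodic square
#' lattice (torus). Each cell occupies exactly one site and the number of cells
#' of each type is conserved by the dynamics.
#'
#' @slot side integer, sites per dimension (the lattice has `side^2` sites).
#' @slot nTypes integer, number of cell types present in the system.
#' @slot types integer `side x side` matrix of type indices in
#'   `0:(nTypes-1)`; row `r`, column `c` is lattice site `(r-1, c-1)`.
#'
#' @seealso [randomConfig()], [referenceConfig()], [applySwitch()]
#' @export
setClass("LatticeConfig",
  representation(side = "integer", nTypes = "integer", types = "matrix"),
  validity = function(object) {
    msg <- character(0)
    L <- object@side
    if (length(L) != 1L || is.na(L) || L < 3L)
      msg <- c(msg, "side must be a single integer >= 3 (degenerate lattice otherwise)")
    if (object@nTypes < 2L)
      msg <- c(msg, "nTypes must be >= 2")
    tm <- object@types
    if (!is.numeric(tm) || nrow(tm) != L || ncol(tm) != L)
      msg <- c(msg, "types must be a side x side matrix")
    else if (any(is.na(tm)) || any(tm != floor(tm)) ||
             any(tm < 0) || any(tm >= object@nTypes))
      msg <- c(msg, "type indices must be integers in 0:(nTypes-1)")
    if (length(msg)) msg else TRUE
  })

#' Normalization extremes of the order indicator
#'
#' Holds the maximal (`dMax`, fully phase-separated stripes) and minimal
#' (`dMin`, alternating chessboard-like pattern) number of homotypic
#' nearest-neighbour contacts attainable for a given lattice size, number of
#' types and per-type cell counts, together with how they were obtained
#' (`"exhaustive"` enumeration on small lattices, `"constructive"` reference
#' patterns otherwise). A `flagged` extremes object marks sides on which the
#' perfect minimizing pattern does not tile periodically (e.g. a chessboard on
#' an odd side), so `dMin` includes wrap defects.
#'
#' @slot side,nTypes integers describing the lattice.
#' @slot counts integer per-type cell counts, summing to `side^2`.
#' @slot dMin,dMax integer homotypic-contact counts of the two anchors.
#' @slot method character, `"exhaustive"` or `"constructive"`.
#' @slot flagged logical, `TRUE` when the minimizing pattern has wrap defects.
#' @export
setClass("OrderExtremes",
  representation(side = "integer", nTypes = "integer", counts = "integer",
                 dMin = "integer", dMax = "integer",
                 method = "character", flagged = "logical"),
  validity = function(object) {
    if (object@dMax <= object@dMin)
      return("dMax must exceed dMin (degenerate normalization)")
    if (sum(object@counts) != object@side^2)
      return("counts must sum to side^2")
    TRUE
  })

#' Switch-indexed trajectory of a sorting simulation
#'
#' Records the order indicator \eqn{\omega} along one simulation, indexed by
#' the number of cell switches performed (`switchIndex`), plus provenance. The
#' index advances by exactly one per applied switch; recording happens at a
#' stride plus the first and last index. Exponentially distributed waiting
#' times between switches are kept when requested; all standard analyses are
#' indexed by switch count, not physical time.
#'
#' @slot switchIndex numeric, recorded switch counts (starting at 0).
#' @slot omega numeric in `[0,1]`, order indicator at the recorded indices.
#' @slot waitingTimes numeric, per-switch waiting times (length 0 unless
#'   recording was requested).
#' @slot params the [AdhesionParams-class] used.
#' @slot extremes the [OrderExtremes-class] used to normalize omega.
#' @slot finalConfig the [LatticeConfig-class] after the last switch.
#' @slot seed integer seed used for the run (`NA` if none was set).
#' @slot stride integer recording stride.
#' @export
setClass("Trajectory",
  representation(switchIndex = "numeric", omega = "numeric",
                 waitingTimes = "numeric", params = "AdhesionParams",
                 extremes = "OrderExtremes", finalConfig = "LatticeConfig",
                 seed = "integer", stride = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@switchIndex) != length(object@omega))
      msg <- c(msg, "switchIndex and omega must have equal length")
    if (length(object@omega) && (min(object@omega) < -1e-9 ||
                                 max(object@omega) > 1 + 1e-9))
      msg <- c(msg, "omega values must lie in [0, 1]")
    if (is.unsorted(object@switchIndex, strictly = TRUE))
      msg <- c(msg, "switchIndex must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Symmetry-reduced linear decision boundary fit
#'
#' Result of fitting a linear classifier to sweep results on the two reduced
#' features (sum of homotypic bond strengths, sum of heterotypic bond
#' strengths). The decision boundary is \eqn{0 = a\,\Sigma_{hom} +
#' b\,\Sigma_{het} + i}; coefficients are reported relative to the homotypic
#' coefficient `a`, so the theoretical expectation from the effective adhesion
#' parameter is `b/a = -2/(N-1)` and `i/a = 0`.
#'
#' @slot method `"svm"` or `"logit"`.
#' @slot a,b,intercept raw fitted coefficients.
#' @slot relative named numeric `(a/a, b/a, i/a)`.
#' @slot cvAccuracy mean accuracy over stratified 5-fold cross-validation.
#' @slot nPoints number of runs used.
#' @slot threshold classification threshold applied to the asymptotic order
#'   indicator.
#' @export
setClass("HyperplaneFit",
  representation(method = "character", a = "numeric", b = "numeric",
                 intercept = "numeric", relative = "numeric",
                 cvAccuracy = "numeric", nPoints = "integer",
                 threshold = "numeric"))
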