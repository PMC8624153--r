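#' Canonical ordering of bond-strength entries
#'
#' The flat-vector form lists the N homotypic entries first, then the
#' N(N-1)/2 heterotypic pairs `i < j` in lexicographic order. `pairIndex()`
#' returns that ordering as a two-column matrix of 0-based type indices.
#'
#' @param nTypes number of cell types.
#' @return integer matrix with columns `i`, `j` (0-based), one row per flat
#'   entry.
#' @examples
#' pairIndex(3)   # (0,0) (1,1) (2,2) (0,1) (0,2) (1,2)
#' @export
pairIndex <- function(nTypes) {
  N <- as.integer(nTypes)
  stopifnot(N >= 2L)
  hom <- cbind(i = 0:(N - 1L), j = 0:(N - 1L))
  het <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  het <- het[order(het[, 1L], het[, 2L]), , drop = FALSE] - 1L
  colnames(het) <- c("i", "j")
  rbind(hom, het)
}

flatLength <- function(nTypes) nTypes + nTypes * (nTypes - 1L) / 2L

flatNames <- function(nTypes) {
  idx <- pairIndex(nTypes)
  paste0("b", idx[, 1L], idx[, 2L])
}

#' Construct intercellular adhesion parameters
#'
#' Builds an [AdhesionParams-class] object from either a symmetric `N x N`
#' matrix or the canonical flat vector (homotypic entries first, then
#' heterotypic pairs `i < j`; see [pairIndex()]).
#'
#' @param x symmetric numeric matrix of bond strengths, or a flat numeric
#'   vector of length `N + N(N-1)/2`.
#' @return an `AdhesionParams` object.
#' @examples
#' p <- adhesionParams(c(0.5, 0.5, -1))   # two types: b00, b11, b01
#' betaMatrix(p)
#' effectiveAdhesion(p)                   # 0.5 + 0.5 - 2*(-1) = 3
#' @export
adhesionParams <- function(x) {
  if (is.matrix(x)) {
    N <- nrow(x)
    obj <- new("AdhesionParams", nTypes = as.integer(N),
               beta = (x + t(x)) / 2)
    if (!isTRUE(all.equal(x, t(x), tolerance = 1e-9)))
      stop("adhesion matrix must be symmetric")
    return(obj)
  }
  x <- as.numeric(x)
  # N + N(N-1)/2 = len  =>  N = (-1 + sqrt(1 + 8 len)) / 2
  N <- (-1 + sqrt(1 + 8 * length(x))) / 2
  if (abs(N - round(N)) > 1e-9 || round(N) < 2)
    stop("flat vector length must be N + N(N-1)/2 for some integer N >= 2")
  N <- as.integer(round(N))
  b <- matrix(0, N, N)
  idx <- pairIndex(N)
  for (k in seq_len(nrow(idx))) {
    b[idx[k, 1L] + 1L, idx[k, 2L] + 1L] <- x[k]
    b[idx[k, 2L] + 1L, idx[k, 1L] + 1L] <- x[k]
  }
  new("AdhesionParams", nTypes = N, beta = b)
}

#' @rdname adhesionParams
#' @param x an `AdhesionParams` object.
#' @export
setMethod("nTypes", "AdhesionParams", function(x) x@nTypes)

#' @rdname adhesionParams
#' @export
setMethod("betaMatrix", "AdhesionParams", function(x) x@beta)

#' @rdname adhesionParams
#' @export
setMethod("betaVector", "AdhesionParams", function(x) {
  idx <- pairIndex(x@nTypes)
  v <- x@beta[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L)]
  names(v) <- flatNames(x@nTypes)
  v
})

#' Relabel cell types
#'
#' Applies a permutation of the type labels consistently to an object. The
#' dynamics and all derived system parameters are invariant under relabeling.
#'
#' @param x an [AdhesionParams-class] or [LatticeConfig-class] object.
#' @param perm integer permutation of `0:(N-1)`: old type `w` becomes
#'   `perm[w + 1]`.
#' @export
relabelTypes <- function(x, perm) {
  perm <- as.integer(perm)
  if (is(x, "AdhesionParams")) {
    N <- x@nTypes
    stopifnot(length(perm) == N, setequal(perm, 0:(N - 1L)))
    b <- matrix(0, N, N)
    b[cbind(rep(perm + 1L, N), rep(perm + 1L, each = N))] <- x@beta
    return(new("AdhesionParams", nTypes = N, beta = b))
  }
  if (is(x, "LatticeConfig")) {
    N <- x@nTypes
    stopifnot(length(perm) == N, setequal(perm, 0:(N - 1L)))
    tm <- matrix(perm[x@types + 1L], x@side, x@side)
    return(new("LatticeConfig", side = x@side, nTypes = N, types = tm))
  }
  stop("relabelTypes() supports AdhesionParams and LatticeConfig objects")
}

#' @export
setMethod("show", "AdhesionParams", function(object) {
  cat("AdhesionParams with", object@nTypes, "cell types\n")
  v <- betaVector(object)
  cat("  flat vector:", paste(names(v), signif(v, 4), sep = "=",
                              collapse = " "), "\n")
  cat("  beta_s =", signif(scalingParam(object), 4),
      " beta* =", signif(effectiveAdhesion(object), 4),
      " beta_Delta =", signif(convergenceSpeed(object), 4), "\n")
  invisible(object)
})
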