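#' Draw bond-strength vectors uniformly from a box
#'
#' Draws flat bond-strength vectors component-wise uniformly from
#' `[bounds[1], bounds[2]]`, optionally rejecting draws until a constraint on
#' the resulting [AdhesionParams-class] holds (e.g. a cap on the convergence
#' speed parameter, which the three-type experiments use to keep the sample
#' dominated by runs that converge within the simulated switch budget).
#'
#' @param nTypes number of cell types.
#' @param n number of vectors to draw.
#' @param bounds numeric length-2 box, default `c(-10, 10)`.
#' @param maxBetaDelta optional upper bound on [convergenceSpeed()]; draws
#'   are rejected until the constraint holds.
#' @param constraint optional `function(AdhesionParams) -> logical`, a
#'   general rejection predicate (combined with `maxBetaDelta` if both are
#'   given).
#' @param seed optional integer seed.
#' @param minAcceptance rejection-sampling guard: once enough proposals have
#'   been made to judge it, an observed acceptance rate below this fraction
#'   (default 0.1%) is an error rather than an endless loop.
#' @return list of [AdhesionParams-class] objects.
#' @export
drawBeta <- function(nTypes, n, bounds = c(-10, 10), maxBetaDelta = NULL,
                     constraint = NULL, seed = NULL, minAcceptance = 0.001) {
  stopifnot(n >= 1, length(bounds) == 2L, bounds[1] < bounds[2])
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(nTypes)
  k <- flatLength(N)
  # vectorized convergence speed on rows of flat proposals, mirroring the
  # N-dependent default definition of convergenceSpeed()
  deltaOf <- function(m) {
    if (N == 2L) return(abs(m[, 1L] - m[, 2L]))
    hom <- m[, seq_len(N), drop = FALSE]
    het <- m[, -seq_len(N), drop = FALSE]
    sqrt(rowSums((hom - rowMeans(hom))^2) + rowSums((het - rowMeans(het))^2))
  }
  out <- vector("list", n)
  got <- 0L
  tries <- 0
  batch <- max(256L, 2L * n)
  while (got < n) {
    prop <- matrix(stats::runif(batch * k, bounds[1], bounds[2]), batch, k)
    tries <- tries + batch
    idx <- seq_len(batch)
    if (!is.null(maxBetaDelta)) idx <- which(deltaOf(prop) < maxBetaDelta)
    for (r in idx) {
      p <- adhesionParams(prop[r, ])
      if (!is.null(constraint) && !isTRUE(constraint(p))) next
      got <- got + 1L
      out[[got]] <- p
      if (got == n) break
    }
    # only judge the acceptance rate once there is real evidence
    if (got < n && tries >= max(1000, 10 / minAcceptance) &&
        got / tries < minAcceptance)
      stop("constraint rejection rate above ",
           format(100 * (1 - minAcceptance)), "%; loosen the constraint")
  }
  out
}

#' Seeded parameter sweep of sorting simulations
#'
#' Draws `nRuns` bond-strength vectors uniformly from a box (with optional
#' rejection constraint), runs one simulation per draw from a fresh seeded
#' random start configuration, and collects one row per run: the flat bond
#' strengths, the derived system parameters, the seeds, and the asymptotic
#' order indicator. All per-run seeds are derived deterministically from
#' `masterSeed`, so the whole table is reproducible from a single integer.
#'
#' @param nTypes number of cell types.
#' @param nRuns number of simulations.
#' @param bounds box for the uniform draw, default `c(-10, 10)`.
#' @param maxBetaDelta,constraint rejection constraint, see [drawBeta()].
#' @param nSwitches switches per simulation (default 312499).
#' @param side lattice side length (default 25).
#' @param masterSeed integer seed controlling draws and per-run seeds.
#' @param recordStride recording stride passed to [runDMM()].
#' @return a `data.frame` ("run table") with columns `run_id`, `n_types`,
#'   `side`, `seed`, the flat bond strengths (`b00`, `b11`, `b01`, ...),
#'   `beta_s`, `beta_star`, `beta_delta`, `n_switches`, `omega_bar` and
#'   `class_label` (`NA` until [classifyRuns()] is applied).
#' @export
sweepRuns <- function(nTypes, nRuns, bounds = c(-10, 10),
                      maxBetaDelta = NULL, constraint = NULL,
                      nSwitches = 312499, side = 25, masterSeed = 1,
                      recordStride = NULL) {
  stopifnot(nRuns >= 1)
  nTypes <- as.integer(nTypes)
  betas <- drawBeta(nTypes, nRuns, bounds, maxBetaDelta, constraint,
                    seed = masterSeed)
  runSeeds <- sample.int(2147483646L, nRuns)
  counts <- defaultCounts(side, nTypes)
  extremes <- orderExtremes(side, nTypes, counts)
  rows <- vector("list", nRuns)
  for (i in seq_len(nRuns)) {
    p <- betas[[i]]
    cfg <- randomConfig(side, counts, seed = runSeeds[i])
    tr <- runDMM(cfg, p, nSwitches = nSwitches, recordStride = recordStride,
                 seed = runSeeds[i], extremes = extremes)
    v <- betaVector(p)
    rows[[i]] <- c(list(run_id = i, n_types = nTypes, side = as.integer(side),
                        seed = runSeeds[i]),
                   as.list(v),
                   list(beta_s = scalingParam(p),
                        beta_star = effectiveAdhesion(p),
                        beta_delta = convergenceSpeed(p),
                        n_switches = as.numeric(nSwitches),
                        omega_bar = asymptoticOmega(tr),
                        class_label = NA_integer_))
  }
  do.call(rbind.data.frame, c(rows, list(make.row.names = FALSE)))
}

betaColumns <- function(table) {
  nTypes <- table$n_types[1L]
  flatNames(nTypes)
}

#' Rank correlations between the effective adhesion parameter and sorting
#'
#' Spearman and Kendall rank correlations between the `beta_star` and
#' `omega_bar` columns of a run table. A strongly positive value supports the
#' prediction that the effective adhesion parameter determines the asymptotic
#' segregation level.
#'
#' @param table a run table from [sweepRuns()] with at least 10 rows.
#' @return named numeric `c(spearman = ..., kendall = ...)`.
#' @export
rankCorrelations <- function(table) {
  stopifnot(nrow(table) >= 10L)
  if (stats::sd(table$beta_star) == 0 || stats::sd(table$omega_bar) == 0)
    stop("undefined correlation: constant column")
  c(spearman = stats::cor(table$beta_star, table$omega_bar,
                          method = "spearman"),
    kendall = stats::cor(table$beta_star, table$omega_bar,
                         method = "kendall"))
}

#' Label runs by their asymptotic segregation level
#'
#' Sets `class_label` to `+1` for runs whose asymptotic order indicator
#' strictly exceeds the threshold and `-1` otherwise. The default threshold
#' is the random-mixture level `1/N` (0.5 for two types, 0.33 for three):
#' class `+1` runs segregated beyond a random configuration.
#'
#' @param table a run table from [sweepRuns()].
#' @param threshold classification threshold; default `1 / n_types`.
#' @return the run table with `class_label` filled in.
#' @export
classifyRuns <- function(table, threshold = NULL) {
  stopifnot("omega_bar" %in% names(table))
  if (is.null(threshold)) threshold <- 1 / table$n_types[1L]
  table$class_label <- ifelse(table$omega_bar > threshold, 1L, -1L)
  attr(table, "threshold") <- threshold
  table
}

reducedFeatures <- function(table) {
  nTypes <- table$n_types[1L]
  nm <- flatNames(nTypes)
  hom <- nm[seq_len(nTypes)]
  het <- nm[-seq_len(nTypes)]
  data.frame(
    hom_sum = rowSums(table[, hom, drop = FALSE]),
    het_sum = rowSums(table[, het, drop = FALSE]))
}

#' Fit the symmetry-reduced linear decision boundary
#'
#' Estimates the effective adhesion parameter from classified sweep results.
#' Because the dynamics are invariant under relabeling of cell types, the
#' linear functional separating sorted from mixed runs can only weight all
#' homotypic bond strengths with one coefficient `a` and all heterotypic ones
#' with another coefficient `b`; the features are therefore compressed to the
#' two sums before fitting, which is equivalent to tying coefficients inside
#' the optimizer but method-agnostic. The fitted boundary
#' `0 = a*hom_sum + b*het_sum + i` is reported relative to `a`; the
#' theoretical expectation is `b/a = -2/(N-1)` and `i/a = 0`. Accuracy is
#' estimated by seeded stratified 5-fold cross-validation.
#'
#' @param table a classified run table (see [classifyRuns()]) containing both
#'   classes.
#' @param method `"svm"` (linear kernel, soft margin, cost 1, no feature
#'   scaling) or `"logit"` (unpenalized logistic regression).
#' @param cost SVM regularization strength.
#' @param folds number of cross-validation folds.
#' @param cvSeed seed for the fold assignment.
#' @return a [HyperplaneFit-class].
#' @export
fitHyperplane <- function(table, method = c("svm", "logit"), cost = 1,
                          folds = 5, cvSeed = 1) {
  method <- match.arg(method)
  if (!all(c(-1L, 1L) %in% table$class_label))
    stop("both classes must be present; run classifyRuns() first")
  feats <- reducedFeatures(table)
  y <- factor(table$class_label, levels = c(-1L, 1L))
  coefs <- fitLinearBoundary(feats, y, method, cost)
  rel <- c(coefs["a"] / coefs["a"], coefs["b"] / coefs["a"],
           coefs["i"] / coefs["a"])
  names(rel) <- c("a/a", "b/a", "i/a")
  acc <- cvAccuracy(feats, y, method, cost, folds, cvSeed)
  thr <- attr(table, "threshold")
  new("HyperplaneFit", method = method,
      a = unname(coefs["a"]), b = unname(coefs["b"]),
      intercept = unname(coefs["i"]), relative = rel,
      cvAccuracy = acc, nPoints = nrow(table),
      threshold = if (is.null(thr)) NA_real_ else thr)
}

fitLinearBoundary <- function(feats, y, method, cost) {
  if (method == "svm") {
    m <- e1071::svm(x = as.matrix(feats), y = y, kernel = "linear",
                    cost = cost, scale = FALSE)
    w <- drop(crossprod(m$coefs, m$SV))
    i <- -m$rho
    # libsvm orients the decision function by order of label appearance in
    # the training data; orient so a positive score means class +1
    score <- as.matrix(feats) %*% w + i
    if (mean((score > 0) == (y == "1")) < 0.5) {
      w <- -w
      i <- -i
    }
    c(a = unname(w[1L]), b = unname(w[2L]), i = unname(i))
  } else {
    y01 <- as.integer(y == "1")
    m <- suppressWarnings(stats::glm(y01 ~ hom_sum + het_sum,
                                     data = cbind(feats, y01 = y01),
                                     family = stats::binomial(),
                                     control = list(maxit = 100)))
    cf <- stats::coef(m)
    c(a = unname(cf["hom_sum"]), b = unname(cf["het_sum"]),
      i = unname(cf["(Intercept)"]))
  }
}

predictLinear <- function(coefs, feats) {
  score <- coefs["a"] * feats$hom_sum + coefs["b"] * feats$het_sum + coefs["i"]
  ifelse(score > 0, "1", "-1")
}

cvAccuracy <- function(feats, y, method, cost, folds, cvSeed) {
  set.seed(cvSeed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- fold != f
    coefs <- fitLinearBoundary(feats[train, , drop = FALSE], droplevels(y[train]),
                               method, cost)
    pred <- predictLinear(coefs, feats[!train, , drop = FALSE])
    acc[f] <- mean(pred == as.character(y[!train]))
  }
  mean(acc)
}

#' @export
setMethod("show", "HyperplaneFit", function(object) {
  cat("HyperplaneFit (", object@method, "), ", object@nPoints,
      " runs, threshold ", signif(object@threshold, 3), "\n", sep = "")
  cat("  0 = a*hom_sum + b*het_sum + i, relative coefficients:\n")
  print(signif(object@relative, 5))
  cat("  5-fold CV accuracy:", signif(object@cvAccuracy, 4), "\n")
  invisible(object)
})
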