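#' Read and write lattice configurations
#'
#' Two plain-text formats are supported. The grid format holds one lattice
#' row per line as whitespace-separated type indices. The JSON format stores
#' `side`, `n_types`, `counts`, the flat row-major type list and, when known,
#' the seed the configuration was generated from.
#'
#' @param config a [LatticeConfig-class].
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else) unless `format` is given.
#' @param format `"grid"` or `"json"`.
#' @param seed optional provenance seed stored in the JSON format.
#' @return `writeLatticeConfig` invisibly returns `path`;
#'   `readLatticeConfig` returns a [LatticeConfig-class].
#' @export
writeLatticeConfig <- function(config, path, format = NULL, seed = NULL) {
  stopifnot(is(config, "LatticeConfig"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "grid"
  if (format == "grid") {
    lines <- apply(config@types, 1L, paste, collapse = " ")
    writeLines(lines, path)
  } else {
    obj <- list(side = config@side, n_types = config@nTypes,
                counts = typeCounts(config),
                types = as.integer(t(config@types)))
    if (!is.null(seed)) obj$seed <- as.integer(seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeLatticeConfig
#' @param nTypes number of types for the grid format (defaults to
#'   `max(type) + 1`).
#' @export
readLatticeConfig <- function(path, format = NULL, nTypes = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "grid"
  if (format == "grid") {
    rows <- lapply(strsplit(trimws(readLines(path)), "\\s+"), as.integer)
    rows <- rows[lengths(rows) > 0L]
    tm <- do.call(rbind, rows)
    if (is.null(nTypes)) nTypes <- max(tm) + 1L
    return(newConfig(tm, nTypes))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- matrix(as.integer(obj$types), obj$side, obj$side, byrow = TRUE)
  newConfig(tm, obj$n_types)
}

#' Read and write trajectories
#'
#' A trajectory is serialized as a CSV with columns `switch_index`, `omega`
#' and `waiting_time` (`NA` where waiting times were not recorded; waiting
#' times are per-switch, so they are only fully present when the recording
#' stride is 1), plus a JSON sidecar (same path with extension `.json`)
#' holding the provenance: the flat bond strengths, lattice side, counts,
#' seed, stride and the normalization extremes.
#'
#' @param trajectory a [Trajectory-class].
#' @param path CSV file path; the sidecar path is derived from it.
#' @return `writeTrajectory` invisibly returns `path`; `readTrajectory`
#'   returns a list with elements `data` (data.frame) and `provenance`
#'   (list) rather than a full [Trajectory-class], since snapshots of the
#'   final configuration are not serialized.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  n <- length(trajectory@switchIndex)
  wt <- rep(NA_real_, n)
  if (length(trajectory@waitingTimes) &&
      isTRUE(trajectory@stride == 1L)) {
    # waiting_time[k] is the wait before the k-th recorded switch
    wt[-1L] <- trajectory@waitingTimes[trajectory@switchIndex[-1L]]
  }
  df <- data.frame(switch_index = trajectory@switchIndex,
                   omega = trajectory@omega, waiting_time = wt)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path, ignore.case = TRUE)
  if (identical(side, path)) side <- paste0(path, ".json")
  prov <- list(beta = unname(betaVector(trajectory@params)),
               n_types = trajectory@params@nTypes,
               side = trajectory@finalConfig@side,
               counts = typeCounts(trajectory@finalConfig),
               seed = trajectory@seed, stride = trajectory@stride,
               d_min = trajectory@extremes@dMin,
               d_max = trajectory@extremes@dMax)
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- sub("\\.csv$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  prov <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  list(data = df, provenance = prov)
}
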