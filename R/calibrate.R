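#' Configuration for leave-one-source-out alpha2 calibration
#'
#' @param grid strictly increasing candidate alpha2 values, all > 0.
#'   The default is a 7-point log-ish grid from 1e-4 to 1e-1 that
#'   includes the two values commonly useful in practice (0.00415,
#'   0.01).
#' @param epsilon leakage tolerance: the maximum permitted increase of
#'   a remaining source's mean proportion when another source is
#'   removed (default 0.05; one restart-SD of slack is added per cell
#'   to absorb Monte-Carlo noise).
#' @return list of class `CalibrationConfig`.
#' @export
calibrationConfig <- function(grid = c(1e-4, 3e-4, 1e-3, 0.00415, 0.01,
                                       0.03, 0.1),
                              epsilon = 0.05) {
  if (length(grid) == 0 || any(grid <= 0) || is.unsorted(grid,
                                                         strictly = TRUE))
    stop("grid must be strictly increasing and positive")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  structure(list(grid = grid, epsilon = epsilon),
            class = "CalibrationConfig")
}

#' Refit a sink with one source environment removed
#'
#' Identical fit to [fitMixture()] but with the removed environment's
#' training counts deleted; the remaining environment labels are
#' preserved and the removed label is absent from the output.
#'
#' @inheritParams fitMixture
#' @param removed label of the source environment to remove; at least
#'   one source must remain.
#' @return A [MixtureEstimate-class] over the remaining sources plus
#'   Unknown.
#' @export
leaveOneSourceOut <- function(sink, sources, removed,
                              config = gibbsConfig(), seed = 1,
                              sinkId = NULL) {
  fitMixture(sink, dropSource(sources, removed), config, seed = seed,
             sinkId = sinkId)
}

#' Calibrate the Unknown-environment hyperparameter alpha2
#'
#' Implements the leave-one-source-out identifiability screen: for each
#' candidate alpha2 and each source environment, the source proportions
#' are re-estimated after removing that environment from the training
#' data, and compared with the full-model fit at the same alpha2 and
#' the same seeds. Removal of one source must not cause the proportion
#' assigned to any *other* source to increase (beyond the tolerance) —
#' the removed mass should flow to Unknown instead. The chosen value is
#' the largest candidate passing for every removed source and every
#' sink, which keeps Unknown as absorbent as the data allow without
#' inducing source-confusion.
#'
#' @param sinks a one-column [FeatureTable-class], a multi-column one
#'   (each column a sink), or a list of sink vectors/tables.
#' @param sources a [SourceSet-class].
#' @param config a [calibrationConfig()].
#' @param gibbs a [gibbsConfig()]; its `alpha2` is overridden by each
#'   candidate.
#' @param seed master seed; the same per-sink, per-fit seeds are reused
#'   across candidates so that differences reflect alpha2, not
#'   sampling noise.
#' @return A [CalibrationResult-class].
#' @export
calibrateAlpha2 <- function(sinks, sources, config = calibrationConfig(),
                            gibbs = gibbsConfig(), seed = 1) {
  stopifnot(inherits(config, "CalibrationConfig"), is(sources, "SourceSet"))
  sinks <- asSinkList(sinks)
  envs <- envNames(sources)
  V <- length(envs)
  nC <- length(config$grid)
  leak <- array(NA_real_, dim = c(nC, V, V),
                dimnames = list(signif(config$grid, 6), envs, envs))
  slack <- array(0, dim = dim(leak), dimnames = dimnames(leak))
  fitSeeds <- splitSeeds(seed, length(sinks) * (V + 1L))
  for (ci in seq_len(nC)) {
    g <- gibbs
    g@alpha2 <- config$grid[ci]
    for (si in seq_along(sinks)) {
      base <- (si - 1L) * (V + 1L)
      full <- fitMixture(sinks[[si]], sources, g, seed = fitSeeds[base + 1L])
      fullMu <- mixtureProportions(full)
      for (vi in seq_len(V)) {
        if (V < 2) next     # nothing left to leak into
        lo <- leaveOneSourceOut(sinks[[si]], sources, envs[vi], g,
                                seed = fitSeeds[base + 1L + vi])
        rem <- setdiff(envs, envs[vi])
        inc <- mixtureProportions(lo)[rem] - fullMu[rem]
        sdv <- mixtureSD(lo)[rem]
        old <- leak[ci, vi, rem]
        take <- is.na(old) | inc > old
        if (any(take)) {
          leak[ci, vi, rem[take]] <- inc[take]
          slack[ci, vi, rem[take]] <- sdv[take]
        }
      }
    }
  }
  pass <- matrix(TRUE, nC, V, dimnames = list(signif(config$grid, 6), envs))
  if (V >= 2) {
    for (ci in seq_len(nC))
      for (vi in seq_len(V)) {
        cells <- leak[ci, vi, ]
        tol <- config$epsilon + slack[ci, vi, ]
        pass[ci, vi] <- all(cells[!is.na(cells)] <=
                              tol[!is.na(cells)])
      }
  }
  ok <- apply(pass, 1, all)
  chosen <- if (any(ok)) max(config$grid[ok]) else NA_real_
  new("CalibrationResult", grid = config$grid, leakage = leak,
      pass = pass, epsilon = config$epsilon, chosen = chosen)
}

asSinkList <- function(sinks) {
  if (is(sinks, "FeatureTable")) {
    out <- lapply(seq_len(ncol(sinks)), function(j) sinks[, j])
    names(out) <- colnames(sinks)
    return(out)
  }
  if (!is.list(sinks)) return(list(sinks))
  sinks
}
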