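#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib sourcemixr, .registration = TRUE
NULL

#' FeatureTable: a taxa-by-samples count matrix
#'
#' The universal currency of the pipeline: an integer count matrix with
#' taxa (features) as rows and samples as columns, tagged with the
#' taxonomic level of its rows (`"otu"`, `"species"`, ..., `"phylum"`).
#'
#' @slot counts integer-valued matrix, taxa x samples, with unique
#'   row and column names.
#' @slot level single character string naming the feature level.
#' @export
setClass("FeatureTable",
  representation(counts = "matrix", level = "character"))

setValidity("FeatureTable", function(object) {
  cts <- object@counts
  msg <- character()
  if ((nrow(cts) > 0 && is.null(rownames(cts))) ||
      (ncol(cts) > 0 && is.null(colnames(cts))))
    msg <- c(msg, "counts must have row (taxon) and column (sample) names")
  else {
    if (anyDuplicated(rownames(cts))) msg <- c(msg, "duplicate taxon ids")
    if (anyDuplicated(colnames(cts))) msg <- c(msg, "duplicate sample ids")
  }
  if (length(cts) && (any(is.na(cts)) || any(cts < 0)))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(cts) && any(abs(cts - round(cts)) > 1e-8))
    msg <- c(msg, "counts must be integer-valued")
  if (length(object@level) != 1L)
    msg <- c(msg, "level must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param counts taxa x samples matrix of non-negative integer counts,
#'   with row and column names.
#' @param level taxonomic level of the rows (free-form label; the
#'   conventional values are `"otu"`, `"species"`, `"genus"`, ...,
#'   `"phylum"`).
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' featureTable(m)
#' @export
featureTable <- function(counts, level = "otu") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  counts <- round(counts)
  new("FeatureTable", counts = counts, level = level)
}

#' @describeIn featureTable Counts matrix accessor.
#' @param object,x a `FeatureTable`.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "FeatureTable", function(object) object@counts)

#' @describeIn featureTable Feature level accessor.
#' @export
tableLevel <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@level
}

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@counts))

#' @export
setMethod("dimnames", "FeatureTable", function(x) dimnames(x@counts))

#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  featureTable(x@counts[i, j, drop = FALSE], level = x@level)
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable (level: ", object@level, "): ",
      nrow(object@counts), " taxa x ", ncol(object@counts), " samples\n",
      sep = "")
  tot <- colSums(object@counts)
  if (length(tot))
    cat("  depth per sample: ", paste0(utils::head(tot, 6), collapse = ", "),
        if (length(tot) > 6) ", ..." else "", "\n", sep = "")
})

#' SourceSet: aggregated training counts per source environment
#'
#' Holds, for each known source environment, the taxon counts pooled
#' over that environment's training samples, on a taxon index shared
#' with the sink samples to be tracked. The Unknown environment is
#' implicit: it has no training counts and is always appended as the
#' last mixture component during fitting.
#'
#' @slot envs ordered environment labels (length V).
#' @slot training V x T matrix of pooled training counts.
#' @export
setClass("SourceSet",
  representation(envs = "character", training = "matrix"))

setValidity("SourceSet", function(object) {
  msg <- character()
  if (nrow(object@training) != length(object@envs))
    msg <- c(msg, "one training row per environment required")
  if (any(object@training < 0)) msg <- c(msg, "negative training counts")
  if (is.null(colnames(object@training)))
    msg <- c(msg, "training matrix must carry taxon ids as column names")
  if (anyDuplicated(object@envs)) msg <- c(msg, "duplicate environment labels")
  if (length(msg)) msg else TRUE
})

#' Build a SourceSet from training samples
#'
#' Pools the columns of a training [FeatureTable-class] by their
#' environment label into one count row per source environment.
#'
#' @param table a `FeatureTable` whose columns are training samples.
#' @param envs character vector, one environment label per column of
#'   `table` (recycled names are not allowed; must match `ncol(table)`).
#' @return A [SourceSet-class] with environments in first-appearance order.
#' @export
sourceSet <- function(table, envs) {
  stopifnot(is(table, "FeatureTable"))
  cts <- counts(table)
  if (length(envs) != ncol(cts))
    stop("need one environment label per training sample column")
  lev <- unique(envs)
  m <- t(vapply(lev, function(v) rowSums(cts[, envs == v, drop = FALSE]),
                numeric(nrow(cts))))
  rownames(m) <- lev
  new("SourceSet", envs = lev, training = m)
}

#' @describeIn sourceSet Environment labels.
#' @param x a `SourceSet`.
#' @export
envNames <- function(x) {
  stopifnot(is(x, "SourceSet"))
  x@envs
}

#' @describeIn sourceSet V x T pooled training count matrix.
#' @export
trainingCounts <- function(x) {
  stopifnot(is(x, "SourceSet"))
  x@training
}

#' Remove one source environment from a SourceSet
#'
#' @param x a `SourceSet`.
#' @param env label of the environment to drop.
#' @return A `SourceSet` without `env`; at least one source must remain.
#' @export
dropSource <- function(x, env) {
  stopifnot(is(x, "SourceSet"))
  if (!env %in% x@envs) stop("unknown environment label: ", env)
  if (length(x@envs) < 2L) stop("cannot remove the last source environment")
  keep <- x@envs != env
  new("SourceSet", envs = x@envs[keep],
      training = x@training[keep, , drop = FALSE])
}

setMethod("show", "SourceSet", function(object) {
  cat("SourceSet: ", length(object@envs), " source environments over ",
      ncol(object@training), " taxa (+ implicit Unknown)\n", sep = "")
  cat("  ", paste0(object@envs, " (", rowSums(object@training), ")",
                   collapse = ", "), "\n", sep = "")
})

#' Configuration for the collapsed Gibbs sampler
#'
#' @param alpha1 Dirichlet pseudocount added to each taxon of every
#'   known source's community distribution. Default 0.001.
#' @param alpha2 pseudocount for the Unknown environment, which has no
#'   training counts; larger values make Unknown more absorbent.
#'   Default 0.00415 (see [calibrateAlpha2()] for how to choose it on
#'   your own data).
#' @param beta Dirichlet pseudocount on the sink's mixing proportions.
#'   Default 10.
#' @param burnIn number of full Gibbs sweeps before the proportion
#'   estimate is drawn. Default 1000.
#' @param restarts number of independent random restarts; one
#'   proportion estimate is drawn per restart. Default 25.
#' @param drawsPerRestart draws recorded per restart (successive draws
#'   are separated by one full sweep). Default 1.
#' @param trainingOnly if `TRUE`, known-source emission probabilities
#'   use training counts only; by default the sink reads currently
#'   assigned to a source also inform its distribution (the collapsed
#'   sampler convention).
#' @param sdThreshold across-restart standard deviation above which an
#'   estimate is flagged low-confidence. Default 0.15.
#' @return A `GibbsConfig` object.
#' @export
gibbsConfig <- function(alpha1 = 0.001, alpha2 = 0.00415, beta = 10,
                        burnIn = 1000, restarts = 25, drawsPerRestart = 1,
                        trainingOnly = FALSE, sdThreshold = 0.15) {
  new("GibbsConfig", alpha1 = alpha1, alpha2 = alpha2, beta = beta,
      burnIn = as.integer(burnIn), restarts = as.integer(restarts),
      drawsPerRestart = as.integer(drawsPerRestart),
      trainingOnly = trainingOnly, sdThreshold = sdThreshold)
}

#' @rdname gibbsConfig
#' @export
setClass("GibbsConfig",
  representation(alpha1 = "numeric", alpha2 = "numeric", beta = "numeric",
                 burnIn = "integer", restarts = "integer",
                 drawsPerRestart = "integer", trainingOnly = "logical",
                 sdThreshold = "numeric"))

setValidity("GibbsConfig", function(object) {
  msg <- character()
  if (object@alpha1 <= 0 || object@alpha2 <= 0 || object@beta <= 0)
    msg <- c(msg, "pseudocounts alpha1, alpha2 and beta must be > 0")
  if (object@burnIn < 0) msg <- c(msg, "burnIn must be >= 0")
  if (object@restarts < 1) msg <- c(msg, "restarts must be >= 1")
  if (object@drawsPerRestart < 1) msg <- c(msg, "drawsPerRestart must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GibbsConfig", function(object) {
  cat(sprintf(
    "GibbsConfig: alpha1=%g alpha2=%g beta=%g burnIn=%d restarts=%d\n",
    object@alpha1, object@alpha2, object@beta, object@burnIn,
    object@restarts))
})

#' MixtureEstimate: source proportions for one sink sample
#'
#' @slot sinkId sink sample label.
#' @slot draws restarts x (V+1) matrix of per-restart proportion draws;
#'   columns are the source environments plus `"Unknown"`; each row sums
#'   to 1.
#' @slot mean,sd per-environment mean and across-restart standard
#'   deviation of the draws.
#' @slot lowConfidence `TRUE` if any environment's across-restart SD
#'   exceeds the configured threshold.
#' @slot drawOrder permutation of restart rows placing similar mixtures
#'   adjacently (for display, as in restart-variability plots).
#' @export
setClass("MixtureEstimate",
  representation(sinkId = "character", draws = "matrix", mean = "numeric",
                 sd = "numeric", lowConfidence = "logical",
                 drawOrder = "integer"))

setValidity("MixtureEstimate", function(object) {
  rs <- rowSums(object@draws)
  if (length(rs) && any(abs(rs - 1) > 1e-9))
    return("each draw row must sum to 1")
  if (!setequal(names(object@mean), colnames(object@draws)))
    return("mean names must match draw columns")
  TRUE
})

#' @describeIn mixtureProportions Across-restart proportion draws.
#' @export
mixtureDraws <- function(x) {
  stopifnot(is(x, "MixtureEstimate"))
  x@draws
}

#' Accessors for MixtureEstimate
#'
#' @param x a [MixtureEstimate-class].
#' @return `mixtureProportions`: named mean proportion per environment
#'   (including `"Unknown"`); `mixtureDraws`: the restarts x (V+1) draw
#'   matrix; `mixtureSD`: across-restart SD; `isLowConfidence`: the
#'   confidence flag.
#' @export
mixtureProportions <- function(x) {
  stopifnot(is(x, "MixtureEstimate"))
  x@mean
}

#' @describeIn mixtureProportions Across-restart standard deviations.
#' @export
mixtureSD <- function(x) {
  stopifnot(is(x, "MixtureEstimate"))
  x@sd
}

#' @describeIn mixtureProportions Low-confidence flag.
#' @export
isLowConfidence <- function(x) {
  stopifnot(is(x, "MixtureEstimate"))
  x@lowConfidence
}

setMethod("show", "MixtureEstimate", function(object) {
  cat("MixtureEstimate for sink '", object@sinkId, "' (",
      nrow(object@draws), " restarts",
      if (object@lowConfidence) ", LOW CONFIDENCE" else "", ")\n", sep = "")
  m <- rbind(mean = round(object@mean, 3), sd = round(object@sd, 3))
  print(m)
})

#' CalibrationResult: leave-one-source-out calibration of alpha2
#'
#' @slot grid candidate alpha2 values (strictly increasing).
#' @slot leakage 3-d array `[candidate, removed source, remaining
#'   source]`: the largest increase (over sinks) of the remaining
#'   source's mean proportion when the removed source is deleted from
#'   the training data, relative to the full-model fit at the same
#'   alpha2 and seeds. `NA` on the diagonal.
#' @slot pass logical matrix `[candidate, removed source]`: whether no
#'   remaining source's increase exceeded the tolerance.
#' @slot epsilon the leakage tolerance used.
#' @slot chosen the largest passing candidate, or `NA` if none passed.
#' @export
setClass("CalibrationResult",
  representation(grid = "numeric", leakage = "array", pass = "matrix",
                 epsilon = "numeric", chosen = "numeric"))

#' @describeIn calibrateAlpha2 Chosen alpha2 accessor (NA if no
#'   candidate passed).
#' @param x a `CalibrationResult`.
#' @export
chosenAlpha2 <- function(x) {
  stopifnot(is(x, "CalibrationResult"))
  x@chosen
}

#' @describeIn calibrateAlpha2 Leakage array accessor.
#' @export
leakageMatrix <- function(x) {
  stopifnot(is(x, "CalibrationResult"))
  x@leakage
}

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult: grid ", paste0(signif(object@grid, 3),
      collapse = ", "), "\n  epsilon = ", object@epsilon,
      "; chosen alpha2 = ",
      if (is.na(object@chosen)) "none" else object@chosen, "\n", sep = "")
})
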