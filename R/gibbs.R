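#' The per-read Gibbs full conditional
#'
#' Reference implementation of the collapsed sampler's full
#' conditional: with read `i` (of taxon `t`) removed from the current
#' assignment counts, the probability of assigning it to environment
#' `v` is proportional to `p(t | v) * (n[v] + beta)`, where for a known
#' source `p(t | v) = (m[v,t] + n[v,t] + alpha1) / (m[v.] + n[v.] +
#' T*alpha1)` (training counts `m` plus currently assigned sink counts
#' `n`; training only if `trainingOnly`), and for the Unknown
#' environment the same form with no training counts and `alpha2`.
#'
#' @param taxon taxon id (or 1-based index into the source taxa).
#' @param n current assigned sink counts with read `i` removed: a
#'   `(V+1) x T` matrix, Unknown last.
#' @param sources a [SourceSet-class].
#' @param config a [gibbsConfig()].
#' @return normalized probability vector over `c(envNames(sources),
#'   "Unknown")`.
#' @export
gibbsConditional <- function(taxon, n, sources, config = gibbsConfig()) {
  m <- trainingCounts(sources)
  V <- nrow(m); T <- ncol(m)
  if (is.character(taxon)) taxon <- match(taxon, colnames(m))
  if (is.na(taxon) || taxon < 1 || taxon > T) stop("unknown taxon")
  stopifnot(nrow(n) == V + 1, ncol(n) == T)
  nv <- rowSums(n)
  p <- numeric(V + 1)
  for (v in seq_len(V)) {
    num <- m[v, taxon] + config@alpha1
    den <- sum(m[v, ]) + T * config@alpha1
    if (!config@trainingOnly) {
      num <- num + n[v, taxon]
      den <- den + nv[v]
    }
    p[v] <- num / den * (nv[v] + config@beta)
  }
  p[V + 1] <- (n[V + 1, taxon] + config@alpha2) / (nv[V + 1] +
                T * config@alpha2) * (nv[V + 1] + config@beta)
  stats::setNames(p / sum(p), c(envNames(sources), "Unknown"))
}

sinkVector <- function(sink, sources) {
  taxa <- colnames(trainingCounts(sources))
  if (is(sink, "FeatureTable")) {
    if (ncol(sink) != 1L)
      stop("sink must be a single sample (one-column FeatureTable)")
    v <- counts(sink)[, 1]
  } else v <- sink
  if (is.null(names(v))) {
    if (length(v) != length(taxa))
      stop("unnamed sink vector must match the source taxon index length")
    names(v) <- taxa
  }
  extra <- setdiff(names(v)[v > 0], taxa)
  if (length(extra))
    stop("sink contains taxa absent from the source taxon index: ",
         paste(utils::head(extra, 5), collapse = ", "))
  out <- stats::setNames(numeric(length(taxa)), taxa)
  out[names(v)[names(v) %in% taxa]] <- v[names(v) %in% taxa]
  out
}

splitSeeds <- function(seed, n) {
  # documented seed splitter: one child seed per independent unit,
  # drawn from the master-seeded stream
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Estimate a sink's source mixture by collapsed Gibbs sampling
#'
#' Runs `restarts` independent chains: each starts from an i.i.d.
#' uniform random assignment of the sink's reads over the known
#' sources plus Unknown, performs `burnIn` full sweeps of the
#' per-read full conditional ([gibbsConditional()]) in fixed read
#' order, and then records one proportion draw (the fraction of reads
#' assigned to each environment). Across-restart variability yields
#' the confidence flag.
#'
#' @param sink one-column [FeatureTable-class] or named count vector on
#'   the sources' taxon index, with total >= 1.
#' @param sources a [SourceSet-class].
#' @param config a [gibbsConfig()].
#' @param seed master seed; one child seed per restart is derived from
#'   it (see the package vignette).
#' @param sinkId label used when `sink` is a bare vector.
#' @return A [MixtureEstimate-class].
#' @examples
#' m <- matrix(c(90, 5, 5, 5, 5, 90), 2, 3, byrow = TRUE,
#'             dimnames = list(c("gut", "soil"), c("t1", "t2", "t3")))
#' src <- new("SourceSet", envs = rownames(m), training = m)
#' est <- fitMixture(c(t1 = 30, t2 = 2, t3 = 1), src,
#'                   gibbsConfig(burnIn = 50, restarts = 5), seed = 1)
#' mixtureProportions(est)
#' @export
fitMixture <- function(sink, sources, config = gibbsConfig(), seed = 1,
                       sinkId = NULL) {
  stopifnot(is(sources, "SourceSet"), is(config, "GibbsConfig"))
  if (is.null(sinkId))
    sinkId <- if (is(sink, "FeatureTable")) colnames(sink)[1] else "sink"
  v <- sinkVector(sink, sources)
  N <- sum(v)
  if (N < 1) stop("empty sink: at least one read is required")
  x <- rep.int(seq_along(v) - 1L, v)           # 0-based taxon per read
  m <- trainingCounts(sources)
  envs <- c(envNames(sources), "Unknown")
  seeds <- splitSeeds(seed, config@restarts)
  draws <- matrix(0, config@restarts * config@drawsPerRestart,
                  length(envs), dimnames = list(NULL, envs))
  for (r in seq_len(config@restarts)) {
    set.seed(seeds[r])
    d <- gibbs_chain_cpp(as.integer(x), m, config@alpha1, config@alpha2,
                         config@beta, config@burnIn,
                         config@drawsPerRestart, 1L, config@trainingOnly)
    rows <- (r - 1L) * config@drawsPerRestart + seq_len(config@drawsPerRestart)
    draws[rows, ] <- d / N
  }
  summarizeRestarts(draws, sdThreshold = config@sdThreshold,
                    sinkId = sinkId)
}

#' Exact posterior mean proportions by enumeration
#'
#' Test oracle for small instances: enumerates every assignment vector
#' of the `N` sink reads over the `V` known sources plus Unknown, and
#' weights each by the product of sequential Dirichlet-multinomial
#' predictive terms — the same counts-based terms as the Gibbs
#' conditional, applied in read order. The terms are exchangeable, so
#' the result is order-invariant. Feasible for `N <= 8` reads and
#' `V <= 3` sources.
#'
#' @inheritParams fitMixture
#' @return named expected proportion per environment (including
#'   `"Unknown"`).
#' @export
exactPosterior <- function(sink, sources, config = gibbsConfig()) {
  stopifnot(is(sources, "SourceSet"))
  v <- sinkVector(sink, sources)
  N <- sum(v)
  m <- trainingCounts(sources)
  V <- nrow(m); T <- ncol(m); E <- V + 1
  if (N > 8 || V > 3)
    stop("instance too large for enumeration (limits: N <= 8, V <= 3)")
  x <- rep.int(seq_len(T), v)
  mv <- rowSums(m)
  envs <- c(envNames(sources), "Unknown")
  grid <- as.matrix(expand.grid(rep(list(seq_len(E)), N)))
  logw <- numeric(nrow(grid))
  prop <- matrix(0, nrow(grid), E)
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    n <- matrix(0, E, T); nv <- numeric(E)
    lw <- 0
    for (i in seq_len(N)) {
      t <- x[i]; zi <- z[i]
      if (zi <= V) {
        num <- m[zi, t] + config@alpha1
        den <- mv[zi] + T * config@alpha1
        if (!config@trainingOnly) {
          num <- num + n[zi, t]; den <- den + nv[zi]
        }
      } else {
        num <- n[E, t] + config@alpha2
        den <- nv[E] + T * config@alpha2
      }
      lw <- lw + log(num / den) +
        log((nv[zi] + config@beta) / (i - 1 + E * config@beta))
      n[zi, t] <- n[zi, t] + 1; nv[zi] <- nv[zi] + 1
    }
    logw[g] <- lw
    prop[g, ] <- nv / N
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  stats::setNames(as.vector(crossprod(prop, w)), envs)
}

chainLength <- function(draws, ord) {
  if (length(ord) < 2) return(0)
  sum(sqrt(rowSums((draws[ord[-1], , drop = FALSE] -
                    draws[ord[-length(ord)], , drop = FALSE])^2)))
}

#' Summarize restart draws into a MixtureEstimate
#'
#' Computes per-environment means and across-restart standard
#' deviations, flags the estimate low-confidence if any environment's
#' SD exceeds `sdThreshold`, and reorders the draw rows by a
#' deterministic nearest-neighbour chaining (Euclidean distance,
#' best over all starting rows, never longer than the input order) so
#' that similar mixtures sit next to one another for display.
#'
#' @param draws a restarts x (V+1) proportion matrix (rows sum to 1)
#'   or a [MixtureEstimate-class] to re-summarize.
#' @param sdThreshold across-restart SD above which the estimate is
#'   flagged (default 0.15).
#' @param sinkId sample label.
#' @return A [MixtureEstimate-class].
#' @export
summarizeRestarts <- function(draws, sdThreshold = 0.15, sinkId = "sink") {
  if (is(draws, "MixtureEstimate")) {
    sinkId <- draws@sinkId
    draws <- draws@draws
  }
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  mu <- colMeans(draws)
  sdev <- if (nrow(draws) > 1) apply(draws, 2, stats::sd)
          else stats::setNames(rep(NA_real_, ncol(draws)), colnames(draws))
  nr <- nrow(draws)
  bestOrd <- seq_len(nr)
  # multi-start greedy chaining is cubic in the number of draws; it is a
  # display aid for restart-sized matrices, so search all starts only up
  # to 200 rows and fall back to a single start beyond that
  starts <- if (nr <= 200) seq_len(nr) else 1L
  if (nr > 2) {
    D <- as.matrix(stats::dist(draws))
    best <- chainLength(draws, bestOrd)
    for (start in starts) {
      ord <- integer(nr); used <- rep(FALSE, nr)
      ord[1] <- start; used[start] <- TRUE
      for (k in 2:nr) {
        d <- D[ord[k - 1], ]; d[used] <- Inf
        ord[k] <- which.min(d)          # ties: lowest index
        used[ord[k]] <- TRUE
      }
      len <- chainLength(draws, ord)
      if (len < best - 1e-12) { best <- len; bestOrd <- ord }
    }
  }
  low <- any(sdev > sdThreshold, na.rm = TRUE)
  new("MixtureEstimate", sinkId = sinkId, draws = draws, mean = mu,
      sd = sdev, lowConfidence = low, drawOrder = as.integer(bestOrd))
}

#' Check sinks for contaminant source signal
#'
#' A sample fails if the mean estimated proportion of any designated
#' contaminant environment (e.g. human skin for ancient samples
#' processed in a modern laboratory) exceeds `threshold`.
#'
#' @param estimates a [MixtureEstimate-class] or a list of them.
#' @param contaminantEnvs environment labels to screen against; must
#'   exist in the estimates.
#' @param threshold maximum tolerated mean proportion (default 0.1).
#' @return data.frame `sample`, `maxContaminant`, `proportion`, `pass`.
#' @export
contaminationCheck <- function(estimates, contaminantEnvs,
                               threshold = 0.1) {
  if (is(estimates, "MixtureEstimate")) estimates <- list(estimates)
  out <- lapply(estimates, function(e) {
    mu <- mixtureProportions(e)
    miss <- setdiff(contaminantEnvs, names(mu))
    if (length(miss))
      stop("unknown environment label(s): ", paste(miss, collapse = ", "))
    sub <- mu[contaminantEnvs]
    k <- which.max(sub)
    data.frame(sample = e@sinkId, maxContaminant = names(sub)[k],
               proportion = unname(sub[k]), pass = sub[k] <= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Source-proportion robustness across rarefaction depths
#'
#' Rarefies the sink at each depth (samples already at or below a
#' requested depth are used in full) and refits the mixture, to verify
#' that conclusions do not hinge on sequencing depth.
#'
#' @inheritParams fitMixture
#' @param depths rarefaction depths (default `c(500, 1000, 2000,
#'   5000)`).
#' @return data.frame `depth`, `env`, `mean`, `sd`; the fitted
#'   [MixtureEstimate-class]s are attached as `attr(, "estimates")`.
#' @export
depthRobustness <- function(sink, sources, config = gibbsConfig(),
                            depths = c(500, 1000, 2000, 5000), seed = 1) {
  v <- sinkVector(sink, sources)
  seeds <- splitSeeds(seed, 2L * length(depths))
  res <- list(); ests <- list()
  for (k in seq_along(depths)) {
    d <- depths[k]
    vd <- v
    if (sum(v) > d) {
      tb <- featureTable(matrix(v, ncol = 1,
                                dimnames = list(names(v), "sink")))
      vd <- counts(rarefyTable(tb, d, seed = seeds[2 * k - 1]))[, 1]
    }
    est <- fitMixture(vd, sources, config, seed = seeds[2 * k],
                      sinkId = paste0("depth", d))
    ests[[as.character(d)]] <- est
    res[[k]] <- data.frame(depth = d, env = names(mixtureProportions(est)),
                           mean = unname(mixtureProportions(est)),
                           sd = unname(mixtureSD(est)))
  }
  out <- do.call(rbind, res)
  attr(out, "estimates") <- ests
  out
}
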