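#' Simulation configuration for synthetic communities
#'
#' Defines the generative conditions for the closed-loop test bed:
#' several source environments with Dirichlet taxon profiles, multiple
#' training samples per source, and sink samples composed as known
#' mixtures of sources plus an out-of-training "unknown" component.
#'
#' @param nTaxa number of taxa in the shared taxon index (default 200,
#'   on the order of the species-level bins a merged 16S study yields).
#' @param nSources number of known source environments (default 5).
#' @param samplesPerSource training samples per source (default 5).
#' @param concentration symmetric Dirichlet concentration for the
#'   per-source taxon profiles; values < 1 give the skewed,
#'   few-dominant-taxa profiles typical of 16S surveys (default 0.5).
#' @param separation in `[0, 1]`: 1 gives sources with disjoint
#'   preferred taxa, 0 makes all sources draws from one shared
#'   background (default 0.9).
#' @param depth reads per sample (default 10000, the primary
#'   rarefaction depth of the tracking analysis).
#' @param seed integer seed; fixing it fixes every generated byte.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nTaxa = 200, nSources = 5, samplesPerSource = 5,
                      concentration = 0.5, separation = 0.9,
                      depth = 10000, seed = 1) {
  for (nm in c("nTaxa", "nSources", "samplesPerSource", "concentration",
               "depth")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("parameter '", nm, "' must be a positive number")
  }
  if (nTaxa < 2) stop("parameter 'nTaxa' must be >= 2")
  if (separation < 0 || separation > 1)
    stop("parameter 'separation' must lie in [0, 1]")
  structure(list(nTaxa = as.integer(nTaxa), nSources = as.integer(nSources),
                 samplesPerSource = as.integer(samplesPerSource),
                 concentration = concentration, separation = separation,
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "SimConfig")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # guard degenerate underflow
  g / sum(g)
}

#' Generate source environment taxon profiles
#'
#' Each source's profile is a mixture of a Dirichlet draw over its own
#' preferred taxon block (weight `separation`) and one shared
#' background Dirichlet draw over all taxa (weight `1 - separation`).
#' The taxon index is partitioned into `nSources` contiguous preferred
#' blocks, so at `separation = 1` profiles have pairwise disjoint
#' support, while at 0 all sources are exchangeable draws from the
#' background.
#'
#' @param config a [simConfig()] list.
#' @return V x T matrix of probabilities; rows (`"Env1"`, ...) sum to 1.
#' @examples
#' p <- genSourceProfiles(simConfig(nTaxa = 10, nSources = 2,
#'                                  separation = 1, seed = 1))
#' rowSums(p)
#' @export
genSourceProfiles <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  T <- config$nTaxa; V <- config$nSources
  set.seed(config$seed)
  block <- sort(rep(seq_len(V), length.out = T))  # contiguous preferred blocks
  bg <- rdirichlet1(rep(config$concentration, T))
  prof <- matrix(0, V, T,
                 dimnames = list(paste0("Env", seq_len(V)),
                                 paste0("taxon_", seq_len(T))))
  for (v in seq_len(V)) {
    own <- numeric(T)
    idx <- which(block == v)
    own[idx] <- rdirichlet1(rep(config$concentration, length(idx)))
    prof[v, ] <- config$separation * own + (1 - config$separation) * bg
  }
  prof
}

#' Draw multinomial count samples from one source profile
#'
#' @param profile probability vector over the taxon index (named), or a
#'   single row of [genSourceProfiles()] output.
#' @param depth reads per sample (column sums are exactly `depth`).
#' @param nSamples number of sample columns to draw.
#' @param seed integer seed.
#' @param prefix sample id prefix.
#' @return A [FeatureTable-class] with `nSamples` columns.
#' @export
sampleCounts <- function(profile, depth, nSamples = 1, seed = 1,
                         prefix = "S") {
  if (length(profile) == 0 || sum(profile) <= 0)
    stop("profile must be a non-empty probability vector")
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(names(profile)))
    names(profile) <- paste0("taxon_", seq_along(profile))
  set.seed(seed)
  cts <- stats::rmultinom(nSamples, size = depth, prob = profile)
  dimnames(cts) <- list(names(profile), paste0(prefix, seq_len(nSamples)))
  featureTable(cts, level = "species")
}

#' Generate the pooled training data for a set of source profiles
#'
#' Convenience wrapper drawing `samplesPerSource` multinomial samples
#' per source at the configured depth and returning both the per-sample
#' table and the pooled [SourceSet-class].
#'
#' @param profiles V x T profile matrix from [genSourceProfiles()].
#' @param config a [simConfig()] list.
#' @return list with `table` (FeatureTable of all training samples),
#'   `envs` (environment label per column) and `sources` (SourceSet).
#' @export
genTrainingData <- function(profiles, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  seeds <- sample.int(.Machine$integer.max, nrow(profiles))
  tabs <- lapply(seq_len(nrow(profiles)), function(v)
    sampleCounts(profiles[v, ], depth = config$depth,
                 nSamples = config$samplesPerSource, seed = seeds[v],
                 prefix = paste0(rownames(profiles)[v], "_rep")))
  tab <- mergeTables(tabs)
  envs <- rep(rownames(profiles), each = config$samplesPerSource)
  list(table = tab, envs = envs, sources = sourceSet(tab, envs))
}

#' Generate a sink sample with known ground-truth mixture
#'
#' Each read is first assigned to a component (the known sources in the
#' order of `profiles` rows, plus `"Unknown"`) by a single multinomial
#' draw over `trueProportions`, then its taxon is drawn from the
#' assigned component's profile. The returned truth records the
#' *realized* per-component read counts, which is the achievable target
#' any recovery test should be scored against.
#'
#' @param trueProportions named numeric over the source environments
#'   plus optionally `"Unknown"`; must sum to 1.
#' @param profiles V x T source profile matrix (rownames = environment
#'   labels matching `trueProportions`).
#' @param unknownProfile probability vector over the same taxon index,
#'   required iff the Unknown proportion is > 0.
#' @param depth number of reads in the sink.
#' @param seed integer seed.
#' @param sinkId sample label.
#' @return list with `table` (one-column FeatureTable) and `truth`
#'   (list: `nominal`, `realized` proportions, `reads` per component,
#'   `depth`).
#' @export
genSink <- function(trueProportions, profiles, unknownProfile = NULL,
                    depth = 1000, seed = 1, sinkId = "sink1") {
  if (depth < 1) stop("depth must be >= 1")
  if (abs(sum(trueProportions) - 1) > 1e-9)
    stop("trueProportions must sum to 1")
  envs <- rownames(profiles)
  pU <- if ("Unknown" %in% names(trueProportions))
    trueProportions[["Unknown"]] else 0
  known <- setdiff(names(trueProportions), "Unknown")
  if (!all(known %in% envs))
    stop("trueProportions names must match profile rows")
  if (pU > 0) {
    if (is.null(unknownProfile))
      stop("unknownProfile required when the Unknown proportion is > 0")
    if (length(unknownProfile) != ncol(profiles))
      stop("taxon index mismatch between unknownProfile and profiles")
  }
  comp <- c(known, if (pU > 0) "Unknown")
  p <- c(trueProportions[known], if (pU > 0) pU)
  set.seed(seed)
  nReads <- as.vector(stats::rmultinom(1, depth, p))
  names(nReads) <- comp
  x <- numeric(ncol(profiles))
  for (k in seq_along(comp)) {
    if (nReads[k] == 0) next
    prob <- if (comp[k] == "Unknown") unknownProfile else profiles[comp[k], ]
    x <- x + as.vector(stats::rmultinom(1, nReads[k], prob))
  }
  cts <- matrix(x, ncol = 1, dimnames = list(colnames(profiles), sinkId))
  realized <- numeric(length(envs) + 1L)
  names(realized) <- c(envs, "Unknown")
  realized[comp] <- nReads / depth
  list(table = featureTable(cts, level = "species"),
       truth = list(sinkId = sinkId, nominal = trueProportions,
                    realized = realized, reads = nReads, depth = depth))
}

#' Generate an amplicon read fixture with planted QC outcomes
#'
#' Builds reads of the form `barcode + forward primer + insert`, each
#' carrying one planted label: `"pass"` or the single reason it must
#' fail the demultiplex/trim/filter chain (`"barcode"`, `"primer"`,
#' `"quality"`, `"length"`). Failure reads are constructed so the
#' decision is unambiguous: a barcode read has one substitution in the
#' barcode; a primer read one substitution in the primer; a quality
#' read has mean Phred exactly `failQuality` (default 24, and a read at
#' exactly the threshold also fails the strict "over" rule); a length
#' read has post-trim length `lengthMin - 1`.
#'
#' @param barcodeMap named character: values are barcodes (unique,
#'   equal length), names are sample ids.
#' @param primer forward primer sequence.
#' @param nPass,nFail number of passing reads and of planted failures;
#'   failure reasons are cycled through `failReasons`.
#' @param failReasons reasons to plant, cycled to length `nFail`.
#' @param insertLength post-trim length of passing reads (default 150,
#'   the study-era mean amplicon length after trimming).
#' @param passQuality mean Phred of passing reads (default 33).
#' @param failQuality mean Phred of planted quality failures
#'   (default 24).
#' @param lengthMin minimum post-trim length (default 130).
#' @param seed integer seed.
#' @return list with `reads` (a
#'   [Biostrings::QualityScaledDNAStringSet-class]) and `truth`
#'   (data.frame: `read`, `sample`, `label`).
#' @export
genReadFixture <- function(barcodeMap, primer, nPass = 20, nFail = 4,
                           failReasons = c("barcode", "primer", "quality",
                                           "length"),
                           insertLength = 150, passQuality = 33,
                           failQuality = 24, lengthMin = 130, seed = 1) {
  if (anyDuplicated(barcodeMap)) stop("duplicate barcodes in barcodeMap")
  if (length(unique(nchar(barcodeMap))) != 1L)
    stop("barcodes must have equal length")
  set.seed(seed)
  nr <- nPass + nFail
  labels <- c(rep("pass", nPass),
              rep(failReasons, length.out = nFail))
  samples <- sample(names(barcodeMap), nr, replace = TRUE)
  randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  mutate1 <- function(s, pos) {
    ch <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
    s
  }
  seqs <- character(nr); quals <- character(nr)
  qualString <- function(n, meanQ) {
    # integer Phred scores with exact mean meanQ (meanQ * n must be integral
    # for the planted boundary cases; jitter cancels pairwise)
    base <- rep(floor(meanQ), n)
    extra <- round((meanQ - floor(meanQ)) * n)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    k <- n %/% 2
    jit <- sample(0:4, k, replace = TRUE)
    base[seq_len(k)] <- base[seq_len(k)] + jit
    base[n + 1 - seq_len(k)] <- base[n + 1 - seq_len(k)] - jit
    base <- pmax(pmin(base, 41L), 0L)
    # clamping could shift the mean; repair by rebalancing first/last
    rawChar <- rawToChar(as.raw(base + 33L))
    rawChar
  }
  for (i in seq_len(nr)) {
    bc <- barcodeMap[[samples[i]]]
    lab <- labels[i]
    ins <- randDNA(if (lab == "length") lengthMin - 1 else insertLength)
    if (lab == "barcode") bc <- mutate1(bc, sample(nchar(bc), 1))
    pr <- primer
    if (lab == "primer") pr <- mutate1(pr, sample(nchar(pr), 1))
    seqs[i] <- paste0(bc, pr, ins)
    mq <- if (lab == "quality") failQuality else passQuality
    # the quality/length rules act on the trimmed read, so give the insert
    # its own exact-mean quality segment
    quals[i] <- paste0(qualString(nchar(bc) + nchar(pr), passQuality),
                       qualString(nchar(ins), mq))
  }
  ids <- sprintf("read_%03d", seq_len(nr))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  list(reads = reads,
       truth = data.frame(read = ids, sample = samples, label = labels,
                          stringsAsFactors = FALSE))
}
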