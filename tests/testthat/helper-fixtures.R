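# Shared fixture builders; everything is generated in code at test time.

# A SourceSet straight from a hand-specified training matrix.
toySourceSet <- function(m) {
  new("SourceSet", envs = rownames(m), training = m)
}

# Block profiles over T taxa: each of the first `n` row ids gets its own
# contiguous taxon block (disjoint support), Dirichlet(conc) within it.
blockProfiles <- function(nBlocks, taxaPerBlock = 20, conc = 0.5,
                          seed = 1) {
  set.seed(seed)
  T <- nBlocks * taxaPerBlock
  out <- matrix(0, nBlocks, T,
                dimnames = list(paste0("Env", seq_len(nBlocks)),
                                paste0("taxon_", seq_len(T))))
  for (i in seq_len(nBlocks)) {
    idx <- ((i - 1) * taxaPerBlock + 1):(i * taxaPerBlock)
    g <- stats::rgamma(taxaPerBlock, conc)
    out[i, idx] <- g / sum(g)
  }
  out
}

# Training table + SourceSet sampled from given profiles.
trainedSources <- function(prof, depth = 2000, reps = 4, seed = 100) {
  tabs <- lapply(seq_len(nrow(prof)), function(v)
    sampleCounts(prof[v, ], depth, reps, seed = seed + v,
                 prefix = paste0(rownames(prof)[v], "_")))
  tab <- mergeTables(tabs)
  list(table = tab,
       sources = sourceSet(tab, rep(rownames(prof), each = reps)))
}

# Random feature table for conservation-style property tests.
randomTable <- function(nTaxa = 12, nSamples = 4, lambda = 20, seed = 1,
                        level = "otu") {
  set.seed(seed)
  m <- matrix(stats::rpois(nTaxa * nSamples, lambda), nTaxa, nSamples,
              dimnames = list(paste0("f", seq_len(nTaxa)),
                              paste0("s", seq_len(nSamples))))
  featureTable(m, level = level)
}

# Random Greengenes-style taxonomy over a table's features.
randomTaxmap <- function(table, nPhyla = 3, nGenera = 5, nSpecies = 8,
                         seed = 1) {
  set.seed(seed)
  ids <- rownames(counts(table))
  p <- sample(nPhyla, length(ids), replace = TRUE)
  g <- sample(nGenera, length(ids), replace = TRUE)
  s <- sample(nSpecies, length(ids), replace = TRUE)
  stats::setNames(sprintf(
    "k__Bacteria; p__P%d; c__C%d; o__O%d; f__F%d; g__G%d; s__S%d",
    p, p, g, g, g, s), ids)
}

# Straight-line independent recomputation of the per-read conditional
# (the oracle for gibbsConditional and exactPosterior).
refConditional <- function(taxon, n, m, alpha1, alpha2, beta,
                           trainingOnly = FALSE) {
  V <- nrow(m); T <- ncol(m); p <- numeric(V + 1)
  for (v in 1:V) {
    num <- m[v, taxon] + alpha1 + if (trainingOnly) 0 else n[v, taxon]
    den <- sum(m[v, ]) + T * alpha1 +
      if (trainingOnly) 0 else sum(n[v, ])
    p[v] <- num / den * (sum(n[v, ]) + beta)
  }
  p[V + 1] <- (n[V + 1, taxon] + alpha2) / (sum(n[V + 1, ]) + T * alpha2) *
    (sum(n[V + 1, ]) + beta)
  p / sum(p)
}

# Barcode map + primer used across QC fixtures.
qcBarcodes <- c(sampleA = "ACGTACGTAC", sampleB = "TTGGCCAATT")
qcPrimer <- "CCTACGGGAGGCAGCAG"
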