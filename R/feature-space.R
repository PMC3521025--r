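#' Pairwise sequence identity
#'
#' Fraction of matching columns under global alignment with free end
#' gaps (match +1, mismatch -1, gap -2 by default), the standard notion
#' for short homologous amplicons: identity = matches / aligned
#' columns, end overhangs excluded.
#'
#' @param a,b DNA sequences (character or [Biostrings::DNAString-class]).
#' @param match,mismatch,gap alignment scores (gap is the per-base
#'   extension cost, applied positively as a penalty).
#' @return identity in `[0, 1]`.
#' @export
sequenceIdentity <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  aln <- Biostrings::pairwiseAlignment(
    as.character(a), as.character(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = 0, gapExtension = gap)
  len <- Biostrings::nchar(aln)
  ifelse(len > 0, Biostrings::nmatch(aln) / len, 0)
}

identityToSet <- function(query, set, match = 1, mismatch = -1, gap = 2) {
  vapply(seq_along(set),
         function(j) sequenceIdentity(query, set[[j]], match, mismatch, gap),
         numeric(1))
}

#' Greedy de novo OTU clustering
#'
#' Deterministic greedy centroid clustering: sequences are processed in
#' decreasing abundance (ties broken by label); each sequence joins the
#' first existing centroid with identity at least `threshold`, else
#' founds a new centroid/OTU.
#'
#' @param seqs named character vector or `DNAStringSet` of unique
#'   (dereplicated) uppercase DNA sequences.
#' @param abundances numeric vector of per-sequence abundances
#'   (default all 1).
#' @param threshold identity threshold in `(0, 1]` (default 0.99, the
#'   de novo level used before species binning).
#' @return data.frame `seq` (label), `otu` (e.g. `"OTU_1"`),
#'   `centroid` (logical), in input order; zero rows for empty input.
#' @export
clusterOTUsDeNovo <- function(seqs, abundances = NULL, threshold = 0.99) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n == 0)
    return(data.frame(seq = character(), otu = character(),
                      centroid = logical()))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (is.null(abundances)) abundances <- rep(1, n)
  ord <- order(-abundances, names(seqs))
  centroidIdx <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(centroidIdx)) {
      if (sequenceIdentity(seqs[i], seqs[centroidIdx[k]]) >= threshold) {
        hit <- k; break
      }
    }
    if (hit == 0L) {
      centroidIdx <- c(centroidIdx, i)
      hit <- length(centroidIdx)
    }
    assign[i] <- hit
  }
  data.frame(seq = names(seqs), otu = paste0("OTU_", assign),
             centroid = seq_len(n) %in% centroidIdx,
             stringsAsFactors = FALSE)
}

#' Closed-reference OTU assignment
#'
#' Maps each query to the highest-identity reference sequence when that
#' identity is at least `threshold` (inclusive boundary: exactly 97.0%
#' is assigned at the default), else leaves it unassigned. Ties are
#' broken by reference order.
#'
#' @param seqs named character vector or `DNAStringSet` of queries.
#' @param reference named character vector or `DNAStringSet` of
#'   reference sequences (non-empty).
#' @param threshold identity threshold (default 0.97).
#' @return data.frame `seq`, `feature` (reference name or `NA`),
#'   `identity` (best identity found).
#' @export
assignClosedReference <- function(seqs, reference, threshold = 0.97) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  reference <- stats::setNames(as.character(reference), names(reference))
  if (length(reference) == 0) stop("reference must be non-empty")
  if (is.null(names(reference)))
    names(reference) <- paste0("ref", seq_along(reference))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  feat <- rep(NA_character_, length(seqs))
  best <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    ident <- identityToSet(seqs[i], reference)
    j <- which.max(ident)          # first max: ties go to reference order
    best[i] <- ident[j]
    if (ident[j] >= threshold) feat[i] <- names(reference)[j]
  }
  data.frame(seq = names(seqs), feature = feat, identity = best,
             stringsAsFactors = FALSE)
}

greengenesRanks <- c(kingdom = "k__", phylum = "p__", class = "c__",
                     order = "o__", family = "f__", genus = "g__",
                     species = "s__")

#' Parse and truncate Greengenes-style lineage strings
#'
#' @param lineages character vector like
#'   `"k__Bacteria; p__Firmicutes; c__Clostridia; ..."`.
#' @param level rank at which to truncate (`"kingdom"` ... `"species"`).
#' @return character vector of lineages truncated at `level`, with
#'   missing ranks filled as empty (`"p__"` etc.).
#' @export
truncateLineage <- function(lineages, level = "species") {
  level <- match.arg(level, names(greengenesRanks))
  k <- which(names(greengenesRanks) == level)
  vapply(lineages, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    out <- character(k)
    for (i in seq_len(k)) {
      pref <- greengenesRanks[i]
      hit <- parts[startsWith(parts, pref)]
      out[i] <- if (length(hit)) hit[1] else pref
    }
    paste(out, collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse a feature table by taxonomy
#'
#' Sums counts over features whose lineages agree when truncated at
#' `level`. Features missing from the taxonomy map are pooled into a
#' reserved `"Unassigned"` lineage rather than dropped, so per-sample
#' totals are conserved exactly.
#'
#' @param table a [FeatureTable-class].
#' @param taxmap named character vector (names = feature ids, values =
#'   Greengenes-style lineage strings), or a data.frame whose first two
#'   columns are feature id and lineage.
#' @param level target rank (`"species"`, ..., `"phylum"`).
#' @return A `FeatureTable` at `level` whose rows are truncated
#'   lineages.
#' @export
collapseTaxonomy <- function(table, taxmap, level = "species") {
  stopifnot(is(table, "FeatureTable"))
  if (is.data.frame(taxmap))
    taxmap <- stats::setNames(as.character(taxmap[[2]]),
                              as.character(taxmap[[1]]))
  cts <- counts(table)
  lin <- taxmap[rownames(cts)]
  lin[is.na(lin)] <- "Unassigned"
  grp <- ifelse(lin == "Unassigned", "Unassigned",
                truncateLineage(lin, level))
  out <- rowsum(cts, group = grp, reorder = TRUE)
  featureTable(out, level = level)
}

#' Merge feature tables over the union of their taxa
#'
#' @param tables list of [FeatureTable-class] objects at the same
#'   level; sample ids must be globally unique.
#' @return A `FeatureTable` whose taxon index is the union (absent
#'   entries 0) and whose samples are the concatenation of the inputs'.
#' @export
mergeTables <- function(tables) {
  if (is(tables, "FeatureTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1, all(vapply(tables, is, TRUE,
                                            "FeatureTable")))
  levels <- unique(vapply(tables, tableLevel, character(1)))
  if (length(levels) != 1L)
    stop("cannot merge tables at different levels: ",
         paste(levels, collapse = ", "))
  allSamples <- unlist(lapply(tables, colnames))
  if (anyDuplicated(allSamples))
    stop("duplicate sample ids across tables: ",
         paste(unique(allSamples[duplicated(allSamples)]), collapse = ", "))
  allTaxa <- unique(unlist(lapply(tables, rownames)))
  out <- matrix(0, length(allTaxa), length(allSamples),
                dimnames = list(allTaxa, allSamples))
  for (tb in tables) {
    cts <- counts(tb)
    out[rownames(cts), colnames(cts)] <- cts
  }
  featureTable(out, level = levels)
}

subsampleCounts <- function(cnt, depth) {
  pool <- rep.int(seq_along(cnt), cnt)
  tabulate(sample(pool, depth), nbins = length(cnt))
}

#' Rarefy a feature table (subsample without replacement)
#'
#' Each sample column is subsampled without replacement to exactly
#' `depth` reads. Samples with fewer than `depth` reads are handled per
#' `shallow`: kept at their full depth (default, mirroring the
#' fewer-for-low-coverage convention), dropped, or an error.
#'
#' @param table a [FeatureTable-class].
#' @param depth target reads per sample (> 0).
#' @param seed integer seed; fixing it fixes the output.
#' @param shallow `"keep"`, `"drop"`, or `"error"`.
#' @return A `FeatureTable`; shallow-kept samples are reported in
#'   `attr(, "shallow")`.
#' @export
rarefyTable <- function(table, depth, seed = 1, shallow = c("keep", "drop",
                                                            "error")) {
  stopifnot(is(table, "FeatureTable"))
  shallow <- match.arg(shallow)
  if (depth <= 0) stop("depth must be > 0")
  cts <- counts(table)
  tot <- colSums(cts)
  low <- tot < depth
  if (any(low) && shallow == "error")
    stop("samples below rarefaction depth: ",
         paste(colnames(cts)[low], collapse = ", "))
  if (shallow == "drop") {
    cts <- cts[, !low, drop = FALSE]
    low <- low[!low]
  }
  set.seed(seed)
  out <- cts
  for (j in which(colSums(cts) > depth))
    out[, j] <- subsampleCounts(cts[, j], depth)
  res <- featureTable(out, level = tableLevel(table))
  attr(res, "shallow") <- names(low)[low]
  res
}

#' Expected richness after rarefaction (closed form)
#'
#' The expected number of distinct features retained when drawing
#' `depth` reads without replacement from a sample with taxon counts
#' `N_t` and total `N` is `sum_t [1 - C(N - N_t, d) / C(N, d)]`.
#'
#' @param x numeric count vector, or a [FeatureTable-class] (then
#'   computed per sample).
#' @param depth subsample size (at most the sample total).
#' @return expected richness (vector over samples for a table).
#' @export
expectedRichness <- function(x, depth) {
  one <- function(cnt) {
    N <- sum(cnt)
    if (depth > N) stop("depth exceeds sample total")
    cnt <- cnt[cnt > 0]
    sum(1 - exp(lchoose(N - cnt, depth) - lchoose(N, depth)))
  }
  if (is(x, "FeatureTable")) apply(counts(x), 2, one) else one(x)
}

#' Monte-Carlo rarefaction (richness) curves
#'
#' Mean distinct-feature count per rarefaction depth per sample over
#' `reps` independent subsamples without replacement. At a depth equal
#' to a sample's total the curve equals its observed richness exactly.
#'
#' @param table a [FeatureTable-class].
#' @param depths increasing depths (each must not exceed the sample
#'   totals it is evaluated at; larger depths are skipped per sample).
#' @param reps resamples per depth (default 10).
#' @param seed integer seed.
#' @return data.frame `sample`, `depth`, `richness` (mean), `sd`.
#' @export
richnessCurve <- function(table, depths, reps = 10, seed = 1) {
  stopifnot(is(table, "FeatureTable"))
  cts <- counts(table)
  set.seed(seed)
  res <- list()
  for (s in colnames(cts)) {
    cnt <- cts[, s]
    N <- sum(cnt)
    for (d in depths) {
      if (d > N) next
      if (d == N) {
        r <- sum(cnt > 0); sdev <- 0
      } else {
        rich <- vapply(seq_len(reps),
                       function(i) sum(subsampleCounts(cnt, d) > 0),
                       numeric(1))
        r <- mean(rich); sdev <- stats::sd(rich)
      }
      res[[length(res) + 1L]] <- data.frame(sample = s, depth = d,
                                            richness = r, sd = sdev)
    }
  }
  do.call(rbind, res)
}
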