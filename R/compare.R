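#' Per-sample phylum profiles with an abundance floor
#'
#' Collapses a table to phylum, converts to per-sample relative
#' abundances, and marks phyla below `minFreq` in a sample as masked
#' (for display they are pooled into `"Other"`); the full normalized
#' vectors are retained unmasked for clustering, so nothing is
#' renormalized away.
#'
#' @param table a [FeatureTable-class] (any level collapsible to
#'   phylum, or already at phylum level).
#' @param taxmap taxonomy map as in [collapseTaxonomy()]; ignored if
#'   the table is already at `"phylum"` level.
#' @param minFreq display threshold (default 0.05).
#' @return list of class `PhylumProfiles` with `profiles` (phyla x
#'   samples relative abundances, columns sum to 1), `retained`
#'   (logical matrix: at or above the floor), and `display` (profiles
#'   with sub-floor mass pooled into `"Other"`).
#' @export
phylumProfiles <- function(table, taxmap = NULL, minFreq = 0.05) {
  stopifnot(is(table, "FeatureTable"))
  if (tableLevel(table) != "phylum" && !is.null(taxmap))
    table <- collapseTaxonomy(table, taxmap, level = "phylum")
  # without a taxonomy map the table's own feature level is profiled
  cts <- counts(table)
  tot <- colSums(cts)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(colnames(cts)[tot == 0], collapse = ", "))
  prof <- sweep(cts, 2, tot, "/")
  retained <- prof >= minFreq
  display <- prof * retained
  other <- 1 - colSums(display)
  display <- rbind(display, Other = other)
  structure(list(profiles = prof, retained = retained, display = display,
                 minFreq = minFreq),
            class = "PhylumProfiles")
}

#' Hierarchical clustering of phylum profiles
#'
#' Agglomerative clustering of samples on their full (unmasked)
#' relative-abundance vectors, Euclidean distance and complete linkage
#' by default. Profiles over differing phylum sets are aligned on the
#' union with zeros.
#'
#' @param profiles a `PhylumProfiles` (from [phylumProfiles()]), a
#'   phyla x samples matrix, or a list of such objects to align and
#'   combine.
#' @param method distance measure passed to [stats::dist()].
#' @param linkage linkage passed to [stats::hclust()].
#' @return An [stats::hclust] tree over the samples.
#' @export
clusterProfiles <- function(profiles, method = "euclidean",
                            linkage = "complete") {
  mats <- if (inherits(profiles, "PhylumProfiles")) list(profiles$profiles)
          else if (is.matrix(profiles)) list(profiles)
          else lapply(profiles, function(p)
            if (inherits(p, "PhylumProfiles")) p$profiles else as.matrix(p))
  phyla <- unique(unlist(lapply(mats, rownames)))
  full <- do.call(cbind, lapply(mats, function(m) {
    out <- matrix(0, length(phyla), ncol(m),
                  dimnames = list(phyla, colnames(m)))
    out[rownames(m), ] <- m
    out
  }))
  if (ncol(full) < 2) stop("need at least 2 samples to cluster")
  stats::hclust(stats::dist(t(full), method = method), method = linkage)
}

#' Write a dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree.
#' @param path output file.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' OTU sharing (intersection) counts between samples
#'
#' Presence/absence sharing summary at the table's feature level
#' (conventionally OTUs at 97% identity): per-sample feature sets,
#' all pairwise intersection and union cardinalities, and the
#' cardinalities of any requested sample-group intersections — the
#' quantities a Venn–Euler display encodes.
#'
#' @param table a [FeatureTable-class] on a shared (merged) OTU
#'   namespace.
#' @param groups optional named list of character vectors of sample
#'   ids; for each, the size of the intersection of those samples'
#'   feature sets is reported.
#' @return list of class `SharingSummary` with `setSizes`,
#'   `intersection` and `union` (sample x sample matrices), and
#'   `groups` (data.frame `group`, `size`).
#' @export
otuSharing <- function(table, groups = NULL) {
  stopifnot(is(table, "FeatureTable"))
  pres <- counts(table) >= 1
  ns <- ncol(pres)
  ids <- colnames(pres)
  inter <- crossprod(pres)           # pairwise intersection cardinalities
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  dimnames(inter) <- dimnames(uni) <- list(ids, ids)
  grp <- NULL
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      names(groups) <- vapply(groups, paste, character(1), collapse = "+")
    bad <- setdiff(unlist(groups), ids)
    if (length(bad))
      stop("unknown sample id(s) in groups: ", paste(bad, collapse = ", "))
    grp <- data.frame(
      group = names(groups),
      size = vapply(groups, function(g)
        sum(rowSums(pres[, g, drop = FALSE]) == length(g)), numeric(1)),
      row.names = NULL)
  }
  structure(list(setSizes = stats::setNames(as.numeric(sizes), ids),
                 intersection = inter, union = uni, groups = grp),
            class = "SharingSummary")
}
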