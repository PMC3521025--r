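test_that("de novo clustering is greedy, deterministic, and abundance-ordered", {
  s <- strrep("ACGT", 25)
  ten <- stats::setNames(rep(s, 10), paste0("q", 1:10))
  cl <- clusterOTUsDeNovo(ten)
  expect_equal(length(unique(cl$otu)), 1)
  expect_equal(sum(cl$centroid), 1)

  # 10 interior substitutions: 90% identity, well under the threshold
  b <- s
  for (p in seq(5, 95, by = 10))
    substr(b, p, p) <- chartr("ACGT", "CGTA", substr(b, p, p))
  expect_equal(sequenceIdentity(s, b), 0.90)
  expect_equal(length(unique(clusterOTUsDeNovo(c(a = s, b = b),
                                               threshold = 0.99)$otu)),
               2)
  expect_equal(nrow(clusterOTUsDeNovo(character())), 0)
})

test_that("planted centroids with unambiguous satellites are recovered exactly", {
  # three centroids pairwise < 90% identical; satellites differ from
  # exactly one centroid by a single substitution (99% at 100 bp)
  set.seed(11)
  base <- function() paste(sample(c("A", "C", "G", "T"), 100,
                                  replace = TRUE), collapse = "")
  mut <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos) {
      ch <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), ch), 1)
    }
    s
  }
  cents <- c(base(), base(), base())
  sats <- unlist(lapply(cents, function(cc) c(mut(cc, 1), mut(cc, 1))))
  seqs <- stats::setNames(c(cents, sats), paste0("s", 1:9))
  ab <- c(100, 90, 80, rep(1, 6))
  cl <- clusterOTUsDeNovo(seqs, ab, threshold = 0.99)
  expect_equal(length(unique(cl$otu)), 3)
  # oracle: independent all-pairs identity + the same greedy rule
  idm <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j)
    sequenceIdentity(seqs[i], seqs[j])))
  ord <- order(-ab, names(seqs))
  oracleAssign <- integer(9); centroids <- integer(0)
  for (i in ord) {
    hit <- which(vapply(centroids, function(k) idm[i, k] >= 0.99, TRUE))
    if (length(hit) == 0) {
      centroids <- c(centroids, i)
      oracleAssign[i] <- length(centroids)
    } else oracleAssign[i] <- hit[1]
  }
  expect_equal(as.integer(factor(cl$otu, levels = unique(cl$otu[ord]))),
               oracleAssign)
})

test_that("closed-reference assignment uses an inclusive 97% boundary", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  mut <- function(s, pos) {
    for (p in pos) {
      ch <- substr(s, p, p)
      substr(s, p, p) <- chartr("ACGT", "CGTA", ch)
    }
    s
  }
  exact <- ref
  borderline <- mut(ref, c(10, 50, 90))     # 97/100 matches: exactly 0.97
  below <- mut(ref, c(5, 20, 40, 60))       # 96%
  res <- assignClosedReference(
    c(q1 = exact, q2 = borderline, q3 = below), c(gg1 = ref))
  expect_equal(res$feature, c("gg1", "gg1", NA))
  # oracle: direct positional identity on equal-length, gap-free pairs
  direct <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b,
                                                                 "")[[1]])
  expect_equal(res$identity,
               c(direct(exact, ref), direct(borderline, ref),
                 direct(below, ref)))
  expect_error(assignClosedReference("ACGT", character()), "non-empty")
})

test_that("taxonomy collapsing conserves totals and composes across ranks", {
  tb <- randomTable(seed = 5)
  tm <- randomTaxmap(tb, seed = 5)
  sp <- collapseTaxonomy(tb, tm, "species")
  expect_equal(colSums(counts(sp)), colSums(counts(tb)))

  # two OTUs of one species collapse to a single row
  m <- matrix(c(3, 4, 1, 2), 2, 2,
              dimnames = list(c("o1", "o2"), c("s1", "s2")))
  tm2 <- c(o1 = "k__B; p__X; c__C; o__O; f__F; g__G; s__sp1",
           o2 = "k__B; p__X; c__C; o__O; f__F; g__G; s__sp1")
  out <- collapseTaxonomy(featureTable(m), tm2, "species")
  expect_equal(dim(out), c(1L, 2L))
  expect_equal(unname(counts(out)[1, ]), c(7, 3))

  # collapsing via genus then phylum equals collapsing straight to phylum
  viaGenus <- collapseTaxonomy(collapseTaxonomy(tb, tm, "genus"),
                               stats::setNames(
                                 rownames(collapseTaxonomy(tb, tm,
                                                           "genus")),
                                 rownames(collapseTaxonomy(tb, tm,
                                                           "genus"))),
                               "phylum")
  direct <- collapseTaxonomy(tb, tm, "phylum")
  expect_equal(counts(viaGenus)[rownames(counts(direct)), ],
               counts(direct))

  # unknown features pool into "Unassigned", conserving totals
  tm3 <- tm[-(1:2)]
  un <- collapseTaxonomy(tb, tm3, "species")
  expect_true("Unassigned" %in% rownames(counts(un)))
  expect_equal(colSums(counts(un)), colSums(counts(tb)))
})

test_that("merging tables unions taxa, conserves counts, and rejects duplicates", {
  a <- randomTable(nTaxa = 5, nSamples = 2, seed = 1)
  bM <- counts(randomTable(nTaxa = 4, nSamples = 2, seed = 2))
  rownames(bM) <- paste0("g", 1:4)
  colnames(bM) <- c("s3", "s4")
  b <- featureTable(bM)
  m <- mergeTables(list(a, b))
  expect_equal(nrow(m), nrow(a) + nrow(b))
  expect_equal(colSums(counts(m)), c(colSums(counts(a)),
                                     colSums(counts(b))))
  expect_equal(counts(mergeTables(list(a))), counts(a))
  expect_error(mergeTables(list(a, a)), "duplicate sample")
  expect_error(mergeTables(list(a, featureTable(bM, level = "species"))),
               "different levels")
})

test_that("rarefaction subsamples exactly and honors the shallow policy", {
  tb <- randomTable(nTaxa = 15, nSamples = 3, lambda = 30, seed = 7)
  tot <- colSums(counts(tb))
  r <- rarefyTable(tb, 100, seed = 1)
  expect_true(all(colSums(counts(r)) == 100))
  expect_true(all(counts(r) <= counts(tb)))

  same <- rarefyTable(tb, min(tot), seed = 2)
  expect_equal(colSums(counts(same)), pmin(tot, min(tot)))
  keepCol <- which.min(tot)
  expect_equal(counts(same)[, keepCol], counts(tb)[, keepCol])

  one <- rarefyTable(tb, 1, seed = 3)
  expect_true(all(colSums(counts(one)) == 1))

  expect_identical(counts(rarefyTable(tb, 50, seed = 9)),
                   counts(rarefyTable(tb, 50, seed = 9)))
  expect_error(rarefyTable(tb, 0), "depth")
  expect_error(rarefyTable(tb, max(tot) + 1, shallow = "error"), "below")
  dropped <- rarefyTable(tb, max(tot), shallow = "drop")
  expect_equal(ncol(dropped), sum(tot >= max(tot)))
})

test_that("richness curves match the hypergeometric closed form", {
  cnt <- c(40, 25, 10, 5, 3, 1, 1)
  names(cnt) <- paste0("t", seq_along(cnt))
  tb <- featureTable(matrix(cnt, ncol = 1,
                            dimnames = list(names(cnt), "s1")))
  # closed form cross-checked against vegan's independent implementation
  for (d in c(5, 20, 60))
    expect_equal(expectedRichness(cnt, d),
                 as.numeric(vegan::rarefy(cnt, d)), tolerance = 1e-8)

  rc <- richnessCurve(tb, depths = c(5, 20, 60, sum(cnt)), reps = 400,
                      seed = 2)
  expect_true(all(diff(rc$richness) >= 0))   # monotone in depth
  expect_equal(rc$richness[rc$depth == sum(cnt)], sum(cnt > 0))
  for (d in c(5, 20, 60)) {
    row <- rc[rc$depth == d, ]
    se <- row$sd / sqrt(400)
    expect_lt(abs(row$richness - expectedRichness(cnt, d)), 3 * se + 0.05)
  }

  single <- featureTable(matrix(9, 1, 1, dimnames = list("t1", "s")))
  rc1 <- richnessCurve(single, depths = c(1, 5, 9), reps = 10, seed = 1)
  expect_true(all(rc1$richness == 1))
})
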