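#' Read filtering configuration
#'
#' Encodes the inclusion criteria for raw amplicon reads: an exact
#' barcode match, exact forward-primer match, per-read quality strictly
#' over `qualityMin`, and post-trim length of at least `lengthMin`.
#'
#' @param barcodeMap named character: values are barcodes (unique,
#'   equal length), names are sample ids.
#' @param primerFwd forward primer sequence (required, matched exactly
#'   at the read start after barcode removal).
#' @param primerRev reverse primer sequence; if non-empty it is trimmed
#'   from the 3' end when present, but its absence alone does not
#'   reject a read (single-direction pyrosequencing reads often stop
#'   short of the distal primer).
#' @param qualityMin reads are kept iff their quality statistic is
#'   strictly greater than this (default 25).
#' @param lengthMin minimum length after barcode and primer removal
#'   (default 130).
#' @param qualityStat `"mean"` (default) or `"min"`: the per-read
#'   statistic compared against `qualityMin`.
#' @return A list of class `FilterConfig`.
#' @export
filterConfig <- function(barcodeMap, primerFwd, primerRev = "",
                         qualityMin = 25, lengthMin = 130,
                         qualityStat = c("mean", "min")) {
  qualityStat <- match.arg(qualityStat)
  if (length(barcodeMap) == 0 || is.null(names(barcodeMap)))
    stop("barcodeMap must be a named character vector (names = samples)")
  if (anyDuplicated(barcodeMap)) stop("barcodes must be unique")
  if (length(unique(nchar(barcodeMap))) != 1L)
    stop("barcodes must all have the same length")
  if (qualityMin < 0) stop("qualityMin must be >= 0")
  if (lengthMin < 1) stop("lengthMin must be >= 1")
  structure(list(barcodeMap = barcodeMap, primerFwd = toupper(primerFwd),
                 primerRev = toupper(primerRev), qualityMin = qualityMin,
                 lengthMin = as.integer(lengthMin),
                 qualityStat = qualityStat),
            class = "FilterConfig")
}

readQuals <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

subsetQSDSS <- function(reads, i) {
  # [ on QualityScaledDNAStringSet keeps qualities in step
  reads[i]
}

stripMcols <- function(x) {
  S4Vectors::mcols(x) <- NULL
  x
}

narrowQSDSS <- function(reads, start, end = NULL) {
  if (is.null(end)) end <- Biostrings::width(reads)
  Biostrings::QualityScaledDNAStringSet(
    stripMcols(Biostrings::subseq(as(reads, "DNAStringSet"),
                                  start = start, end = end)),
    Biostrings::PhredQuality(
      Biostrings::subseq(as(Biostrings::quality(reads), "BStringSet"),
                         start = start, end = end)))
}

#' Demultiplex reads by exact barcode match
#'
#' A read is assigned to a sample iff its leading bases exactly equal
#' that sample's barcode; the barcode is removed from retained reads.
#' Every input read appears exactly once across the outputs.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet-class].
#' @param config a [filterConfig()].
#' @return list with `assigned` (named list of per-sample read sets,
#'   barcodes stripped) and `rejected` (data.frame `read`, `reason`
#'   where reason is `"barcode"` or `"too_short"`).
#' @export
demultiplex <- function(reads, config) {
  stopifnot(inherits(config, "FilterConfig"))
  bl <- nchar(config$barcodeMap[[1]])
  n <- length(reads)
  if (n == 0)
    return(list(assigned = stats::setNames(list(), character()),
                rejected = data.frame(read = character(),
                                      reason = character())))
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  tooShort <- Biostrings::width(reads) < bl
  lead <- rep(NA_character_, n)
  lead[!tooShort] <- as.character(Biostrings::subseq(
    as(reads, "DNAStringSet")[!tooShort], start = 1, end = bl))
  sampleOf <- stats::setNames(names(config$barcodeMap), config$barcodeMap)
  hit <- sampleOf[lead]
  ok <- !tooShort & !is.na(hit)
  assigned <- lapply(names(config$barcodeMap), function(s) {
    idx <- which(ok & hit == s)
    narrowQSDSS(subsetQSDSS(reads, idx), start = bl + 1)
  })
  names(assigned) <- names(config$barcodeMap)
  reason <- ifelse(tooShort, "too_short", "barcode")[!ok]
  list(assigned = assigned,
       rejected = data.frame(read = ids[!ok], reason = reason,
                             stringsAsFactors = FALSE))
}

#' Trim primers from demultiplexed reads
#'
#' Retains a read iff the forward primer matches exactly at the read
#' start, and removes it; the reverse primer, if configured, is removed
#' when it matches exactly at the 3' end (best effort: its absence does
#' not reject).
#'
#' @param reads demultiplexed reads (barcode already removed).
#' @param config a [filterConfig()].
#' @return list with `kept` (trimmed reads) and `rejected`
#'   (data.frame `read`, `reason = "primer"` or `"too_short"`).
#' @export
trimPrimers <- function(reads, config) {
  stopifnot(inherits(config, "FilterConfig"))
  pf <- config$primerFwd
  pl <- nchar(pf)
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0)
    return(list(kept = reads,
                rejected = data.frame(read = character(),
                                      reason = character())))
  tooShort <- Biostrings::width(reads) < pl
  lead <- rep(NA_character_, n)
  lead[!tooShort] <- as.character(Biostrings::subseq(
    as(reads, "DNAStringSet")[!tooShort], start = 1, end = pl))
  ok <- !tooShort & !is.na(lead) & lead == pf
  kept <- narrowQSDSS(subsetQSDSS(reads, which(ok)), start = pl + 1)
  pr <- config$primerRev
  if (nzchar(pr) && length(kept)) {
    w <- Biostrings::width(kept)
    canEnd <- w >= nchar(pr)
    tail3 <- rep(NA_character_, length(kept))
    tail3[canEnd] <- as.character(Biostrings::subseq(
      as(kept, "DNAStringSet")[canEnd],
      start = w[canEnd] - nchar(pr) + 1L, end = w[canEnd]))
    hasRev <- !is.na(tail3) & tail3 == pr
    if (any(hasRev)) {
      newEnd <- ifelse(hasRev, w - nchar(pr), w)
      kept <- narrowQSDSS(kept, start = 1, end = newEnd)
    }
  }
  reason <- ifelse(tooShort[!ok], "too_short", "primer")
  list(kept = kept,
       rejected = data.frame(read = ids[!ok], reason = reason,
                             stringsAsFactors = FALSE))
}

#' Quality and length filter for trimmed reads
#'
#' Keeps a read iff its quality statistic (mean per-base Phred by
#' default) is strictly greater than `qualityMin` and its trimmed
#' length is at least `lengthMin`. A read whose mean quality equals the
#' threshold exactly is dropped (the rule is "over", not "at least").
#'
#' @param reads primer-trimmed reads.
#' @param config a [filterConfig()].
#' @return list with `kept` (reads), `decisions` (data.frame `read`,
#'   `keep`, `reason` in `{"", "quality", "length"}`).
#' @export
qualityLengthFilter <- function(reads, config) {
  stopifnot(inherits(config, "FilterConfig"))
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0)
    return(list(kept = reads,
                decisions = data.frame(read = character(), keep = logical(),
                                       reason = character())))
  q <- as.list(readQuals(reads))
  stat <- if (config$qualityStat == "mean")
    vapply(q, function(x) mean(as.numeric(x)), numeric(1))
  else
    vapply(q, function(x) suppressWarnings(min(as.numeric(x))), numeric(1))
  stat[!is.finite(stat)] <- -Inf   # zero-length reads cannot pass
  wid <- Biostrings::width(reads)
  qualOk <- stat > config$qualityMin
  lenOk <- wid >= config$lengthMin
  keep <- qualOk & lenOk
  reason <- rep("", n)
  reason[!qualOk] <- "quality"
  reason[qualOk & !lenOk] <- "length"
  list(kept = subsetQSDSS(reads, which(keep)),
       decisions = data.frame(read = ids, keep = keep, reason = reason,
                              stringsAsFactors = FALSE))
}

#' Run the full read QC chain
#'
#' Demultiplexes, trims primers, and applies the quality/length filter,
#' keeping per-read bookkeeping so that every input read is accounted
#' for exactly once as retained or rejected-with-reason.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet-class] of raw
#'   reads.
#' @param config a [filterConfig()].
#' @return list of class `ReadQC` with `kept` (named list of per-sample
#'   trimmed, filtered reads) and `log` (data.frame `read`, `sample`
#'   (`NA` for unassigned), `status` = `"retained"`/`"rejected"`,
#'   `reason`).
#' @export
runReadQC <- function(reads, config) {
  dm <- demultiplex(reads, config)
  log <- data.frame(read = dm$rejected$read,
                    sample = rep(NA_character_, nrow(dm$rejected)),
                    status = rep("rejected", nrow(dm$rejected)),
                    reason = dm$rejected$reason,
                    stringsAsFactors = FALSE)
  kept <- list()
  for (s in names(dm$assigned)) {
    tr <- trimPrimers(dm$assigned[[s]], config)
    fl <- qualityLengthFilter(tr$kept, config)
    kept[[s]] <- fl$kept
    if (nrow(tr$rejected))
      log <- rbind(log, data.frame(read = tr$rejected$read, sample = s,
                                   status = "rejected",
                                   reason = tr$rejected$reason))
    d <- fl$decisions
    if (nrow(d))
      log <- rbind(log, data.frame(
        read = d$read, sample = s,
        status = ifelse(d$keep, "retained", "rejected"),
        reason = d$reason))
  }
  structure(list(kept = kept, log = log), class = "ReadQC")
}

#' Per-sample QC report
#'
#' @param qc the result of [runReadQC()].
#' @return data.frame with one row per sample (plus `"<unassigned>"`):
#'   input, retained, and rejected counts broken down by reason;
#'   `retained + rejected == input` in every row.
#' @export
qcReport <- function(qc) {
  stopifnot(inherits(qc, "ReadQC"))
  log <- qc$log
  log$sample[is.na(log$sample)] <- "<unassigned>"
  samples <- unique(c(names(qc$kept), log$sample))
  reasons <- c("barcode", "too_short", "primer", "quality", "length")
  out <- data.frame(sample = samples, input = 0L, retained = 0L)
  for (r in reasons) out[[paste0("rejected_", r)]] <- 0L
  for (i in seq_along(samples)) {
    sub <- log[log$sample == samples[i], ]
    out$input[i] <- nrow(sub)
    out$retained[i] <- sum(sub$status == "retained")
    for (r in reasons)
      out[[paste0("rejected_", r)]][i] <-
        sum(sub$status == "rejected" & sub$reason == r)
  }
  out
}

#' Read and write FASTQ files (Phred+33)
#'
#' Thin wrappers over Biostrings' FASTQ support returning/accepting
#' [Biostrings::QualityScaledDNAStringSet-class] objects.
#'
#' @param path file path.
#' @param reads a `QualityScaledDNAStringSet`.
#' @export
readFastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  q <- Biostrings::PhredQuality(S4Vectors::mcols(reads)$qualities)
  Biostrings::QualityScaledDNAStringSet(stripMcols(reads), q)
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}
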