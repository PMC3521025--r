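mkReads <- function(seqs, quals = NULL) {
  if (is.null(quals))
    quals <- vapply(seqs, function(s)
      paste(rep("I", nchar(s)), collapse = ""), character(1))
  if (length(seqs)) names(seqs) <- paste0("r", seq_along(seqs))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(unname(quals)))
}

qcCfg <- function(...) filterConfig(qcBarcodes, qcPrimer, ...)

test_that("demultiplexing requires an exact barcode and conserves reads", {
  ins <- "ACGT"
  good <- paste0(qcBarcodes[["sampleA"]], ins)
  onemm <- paste0(sub("^A", "T", qcBarcodes[["sampleA"]]), ins)
  short <- "ACG"
  dm <- demultiplex(mkReads(c(good, onemm, short)), qcCfg())
  expect_equal(length(dm$assigned$sampleA), 1)
  expect_equal(as.character(dm$assigned$sampleA[[1]]), ins)  # barcode removed
  expect_equal(length(dm$assigned$sampleB), 0)
  expect_setequal(dm$rejected$reason, c("barcode", "too_short"))
  nOut <- sum(lengths(dm$assigned)) + nrow(dm$rejected)
  expect_equal(nOut, 3)

  empty <- demultiplex(mkReads(character()), qcCfg())
  expect_equal(sum(lengths(empty$assigned)), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("primer trimming requires an exact forward primer match", {
  ins <- "ACGTACGTACGTACGT"
  tr <- trimPrimers(mkReads(paste0(qcPrimer, ins)), qcCfg())
  expect_equal(as.character(tr$kept[[1]]), ins)

  mm <- sub("^C", "G", qcPrimer)
  tr2 <- trimPrimers(mkReads(paste0(mm, ins)), qcCfg())
  expect_equal(length(tr2$kept), 0)
  expect_equal(tr2$rejected$reason, "primer")

  tr3 <- trimPrimers(mkReads(substr(qcPrimer, 1, 5)), qcCfg())
  expect_equal(tr3$rejected$reason, "too_short")

  # reverse primer removed when present at the 3' end, kept read intact
  # otherwise
  cfgR <- filterConfig(qcBarcodes, qcPrimer, primerRev = "GGTTGG")
  withRev <- paste0(qcPrimer, ins, "GGTTGG")
  tr4 <- trimPrimers(mkReads(c(withRev, paste0(qcPrimer, ins))), cfgR)
  expect_equal(as.character(tr4$kept[[1]]), ins)
  expect_equal(as.character(tr4$kept[[2]]), ins)
})

test_that("quality/length filtering is strict at its boundaries", {
  qs <- function(n, q) paste(rep(rawToChar(as.raw(q + 33L)), n),
                             collapse = "")
  reads <- mkReads(
    c(strrep("A", 150), strrep("A", 150), strrep("A", 129),
      strrep("A", 130)),
    c(qs(150, 26), qs(150, 25), qs(129, 30), qs(130, 30)))
  fl <- qualityLengthFilter(reads, qcCfg())
  expect_equal(fl$decisions$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(fl$decisions$reason, c("", "quality", "length", ""))
})

test_that("QC decisions match planted fixture labels with zero discrepancies", {
  for (seed in 1:3) {
    fx <- genReadFixture(qcBarcodes, qcPrimer, nPass = 12, nFail = 8,
                         seed = seed)
    qc <- runReadQC(fx$reads, qcCfg())
    got <- merge(fx$truth, qc$log, by = "read")
    expect_equal(nrow(got), nrow(fx$truth))
    expect_true(all((got$label == "pass") == (got$status == "retained")))
    failed <- got[got$label != "pass", ]
    expect_equal(failed$reason, failed$label)
    # conservation: report totals recount to the input size
    rep <- qcReport(qc)
    expect_equal(sum(rep$input), length(fx$reads))
    expect_equal(rep$input,
                 rep$retained + rowSums(rep[, grep("^rejected_",
                                                   names(rep))]))
  }
  # all-pass fixture has zero rejections
  fx0 <- genReadFixture(qcBarcodes, qcPrimer, nPass = 6, nFail = 0,
                        seed = 1)
  rep0 <- qcReport(runReadQC(fx0$reads, qcCfg()))
  expect_equal(sum(rep0$retained), 6)
  expect_equal(sum(rep0[, grep("^rejected_", names(rep0))]), 0)
})

test_that("a read at mean quality exactly 25 is dropped under the strict rule", {
  fx <- genReadFixture(qcBarcodes, qcPrimer, nPass = 2, nFail = 1,
                       failReasons = "quality", failQuality = 25, seed = 2)
  qc <- runReadQC(fx$reads, qcCfg())
  bad <- fx$truth$read[fx$truth$label == "quality"]
  expect_equal(qc$log$status[qc$log$read == bad], "rejected")
  expect_equal(qc$log$reason[qc$log$read == bad], "quality")
})

test_that("FASTQ round-trips through Phred+33", {
  fx <- genReadFixture(qcBarcodes, qcPrimer, nPass = 4, nFail = 0,
                       seed = 3)
  f <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(fx$reads, f)
  back <- readFastq(f)
  expect_equal(as.character(back), as.character(fx$reads))
  expect_equal(as(Biostrings::quality(back), "IntegerList"),
               as(Biostrings::quality(fx$reads), "IntegerList"))
})
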