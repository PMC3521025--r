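#' Read and write feature tables
#'
#' The TSV dialect is: tab-separated, header row of sample ids, first
#' column the feature id, integer cells. `format = "biom"` reads/writes
#' BIOM JSON via the biomformat package (if installed).
#'
#' @param path file path.
#' @param level feature level to tag the table with (TSV carries no
#'   level metadata).
#' @param format `"tsv"` or `"biom"`.
#' @return `readFeatureTable`: a [FeatureTable-class];
#'   `writeFeatureTable`: the path, invisibly.
#' @export
readFeatureTable <- function(path, level = "otu",
                             format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    requireBiom()
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(featureTable(m, level = level))
  }
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(parts)
  if (any(width != width[1]))
    stop("ragged rows in ", path, ": row(s) ",
         paste(which(width != width[1]), collapse = ", "))
  samples <- parts[[1]][-1]
  if (length(parts) == 1L) {
    m <- matrix(0, 0, length(samples),
                dimnames = list(character(), samples))
    return(featureTable(m, level = level))
  }
  body <- parts[-1]
  taxa <- vapply(body, `[[`, character(1), 1)
  cells <- t(vapply(body, function(p) p[-1], character(length(samples))))
  if (length(samples) == 1L) cells <- matrix(cells, ncol = 1)
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = length(taxa)))
  bad <- which(apply(is.na(num) | num < 0 | num != round(num), 1, any))
  if (length(bad))
    stop("negative or non-integer counts in ", path, ": row(s) ",
         paste(bad + 1L, collapse = ", "))
  dimnames(num) <- list(taxa, samples)
  featureTable(num, level = level)
}

#' @rdname readFeatureTable
#' @param table a `FeatureTable`.
#' @export
writeFeatureTable <- function(table, path, format = c("tsv", "biom")) {
  stopifnot(is(table, "FeatureTable"))
  format <- match.arg(format)
  cts <- counts(table)
  if (format == "biom") {
    requireBiom()
    biomformat::write_biom(biomformat::make_biom(cts), path)
    return(invisible(path))
  }
  header <- paste(c("#FeatureID", colnames(cts)), collapse = "\t")
  rows <- if (nrow(cts))
    paste(rownames(cts),
          apply(format(cts, scientific = FALSE, trim = TRUE), 1, paste,
                collapse = "\t"), sep = "\t")
  else character()
  writeLines(c(header, rows), path)
  invisible(path)
}

requireBiom <- function() {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM I/O")
}

#' Read a taxonomy map
#'
#' Two-column TSV: feature id, Greengenes-style lineage string.
#'
#' @param path file path.
#' @return named character vector (names = feature ids).
#' @export
readTaxonomy <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2) stop("taxonomy file needs feature id and lineage")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Read sample metadata (source/sink roles)
#'
#' Expects a TSV with columns `SampleID`, `Env`, `SourceSink` (values
#' `source` or `sink`). Sources are grouped by environment; an `Env`
#' label on a sink row is ignored with a warning.
#'
#' @param path file path.
#' @return list with `sources` (data.frame `SampleID`, `Env`) and
#'   `sinks` (character vector of sample ids).
#' @export
readMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SampleID", "Env", "SourceSink")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$SampleID))
    stop("duplicate SampleID(s): ",
         paste(unique(md$SampleID[duplicated(md$SampleID)]), collapse = ", "))
  role <- tolower(md$SourceSink)
  bad <- !role %in% c("source", "sink")
  if (any(bad))
    stop("SourceSink must be 'source' or 'sink'; offending sample(s): ",
         paste(md$SampleID[bad], collapse = ", "))
  sinkHasEnv <- role == "sink" & !is.na(md$Env) & nzchar(md$Env)
  if (any(sinkHasEnv))
    warning("Env labels on sink sample(s) are ignored: ",
            paste(md$SampleID[sinkHasEnv], collapse = ", "))
  src <- md[role == "source", c("SampleID", "Env")]
  if (nrow(src) && any(is.na(src$Env) | !nzchar(src$Env)))
    stop("source sample(s) without an Env label: ",
         paste(src$SampleID[is.na(src$Env) | !nzchar(src$Env)],
               collapse = ", "))
  list(sources = src, sinks = md$SampleID[role == "sink"])
}

#' Write a mixture estimate (or several) as TSV and JSON
#'
#' @param estimates a [MixtureEstimate-class] or list of them.
#' @param prefix output path prefix; writes `<prefix>_proportions.tsv`
#'   (mean/SD per sink and environment) and `<prefix>_draws.json`
#'   (full draw matrices).
#' @return the TSV path, invisibly.
#' @export
writeMixtureEstimates <- function(estimates, prefix) {
  if (is(estimates, "MixtureEstimate")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, function(e)
    data.frame(sample = e@sinkId, env = names(mixtureProportions(e)),
               mean = unname(mixtureProportions(e)),
               sd = unname(mixtureSD(e)),
               lowConfidence = isLowConfidence(e))))
  tsv <- paste0(prefix, "_proportions.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  draws <- lapply(estimates, function(e)
    list(sample = e@sinkId, envs = colnames(mixtureDraws(e)),
         draws = unname(mixtureDraws(e)), order = e@drawOrder))
  names(draws) <- vapply(estimates, function(e) e@sinkId, character(1))
  jsonlite::write_json(draws, paste0(prefix, "_draws.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}
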