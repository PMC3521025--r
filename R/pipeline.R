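#' Read a pipeline run configuration
#'
#' A single YAML (or JSON) document drives [runPipeline()]; it
#' round-trips losslessly through [yaml::read_yaml()]. See
#' `system.file("extdata", "demo-config.yaml", package = "sourcemixr")`
#' for a complete worked example.
#'
#' @param path YAML/JSON config file.
#' @return validated config list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list built in code.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outputDir)) stop("config field 'outputDir' is required")
  if (is.null(cfg$stages)) cfg$stages <- list()
  simulate <- isTRUE(cfg$stages$simulate)
  if (!simulate && is.null(cfg$inputs$featureTable))
    stop("config needs either stages: simulate: true or ",
         "inputs: featureTable")
  if (!simulate && is.null(cfg$inputs$metadata))
    stop("config field 'inputs: metadata' is required with a real table")
  structure(cfg, class = "RunConfig")
}

md5OrNA <- function(paths) {
  out <- tools::md5sum(paths)
  names(out) <- basename(paths)
  out
}

stageRecord <- function(manifest, name, params, outputs = character()) {
  manifest$stages[[name]] <- list(
    status = "ok", params = params,
    outputs = as.list(md5OrNA(outputs)),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest
}

#' Run the full source-tracking pipeline
#'
#' Executes, in order: simulate (or load inputs) -> qc (when raw reads
#' are configured) -> taxonomy collapse/merge -> rarefy -> track, plus
#' the optional calibrate, robustness and compare stages. Each stage
#' writes its outputs under `outputDir` before the next starts, so a
#' partial failure leaves completed stage outputs intact and the
#' manifest names the failing stage.
#'
#' @param cfg a `RunConfig` (from [readRunConfig()] or
#'   [validateRunConfig()]), or a path to one.
#' @return the run manifest (list; also written as `manifest.json`):
#'   per-stage parameter record, output checksums, seed record and
#'   timestamps. Deterministic stages reproduce identical checksums
#'   under an identical config.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  if (!inherits(cfg, "RunConfig")) cfg <- validateRunConfig(cfg)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  seeds <- splitSeeds(cfg$seed, 6L)
  names(seeds) <- c("simulate", "qc", "rarefy", "track", "calibrate",
                    "robustness")
  manifest$stageSeeds <- as.list(seeds)
  fail <- function(stage, e) {
    manifest$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(e))
    manifest$failedStage <- stage
    jsonlite::write_json(manifest, file.path(cfg$outputDir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  sinksTab <- NULL; sources <- NULL; truths <- NULL; trainTab <- NULL
  trainEnvs <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    tryCatch({
      sp <- cfg$simulate
      sc <- simConfig(nTaxa = sp$nTaxa %||% 200,
                      nSources = sp$nSources %||% 5,
                      samplesPerSource = sp$samplesPerSource %||% 5,
                      concentration = sp$concentration %||% 0.5,
                      separation = sp$separation %||% 0.9,
                      depth = sp$depth %||% 10000,
                      seed = seeds[["simulate"]])
      # generate one extra profile over the same block partition: the
      # last one never enters training and serves as the out-of-training
      # unknown component (disjoint from every source at separation 1)
      scU <- sc; scU$nSources <- sc$nSources + 1L
      profAll <- genSourceProfiles(scU)
      prof <- profAll[seq_len(sc$nSources), , drop = FALSE]
      unknown <- profAll[nrow(profAll), ]
      tr <- genTrainingData(prof, sc)
      trainTab <- tr$table; trainEnvs <- tr$envs; sources <- tr$sources
      sinkSpecs <- sp$sinks
      if (is.null(sinkSpecs))
        sinkSpecs <- list(list(id = "sink1",
                               proportions = stats::setNames(
                                 list(1), rownames(prof)[1])))
      sinkSeeds <- splitSeeds(seeds[["simulate"]], length(sinkSpecs))
      sims <- lapply(seq_along(sinkSpecs), function(i) {
        ss <- sinkSpecs[[i]]
        genSink(unlist(ss$proportions), prof, unknownProfile = unknown,
                depth = ss$depth %||% sc$depth, seed = sinkSeeds[i],
                sinkId = ss$id %||% paste0("sink", i))
      })
      sinksTab <- mergeTables(lapply(sims, `[[`, "table"))
      truths <- lapply(sims, `[[`, "truth")
      writeFeatureTable(trainTab, file.path(cfg$outputDir, "training.tsv"))
      writeFeatureTable(sinksTab, file.path(cfg$outputDir, "sinks.tsv"))
      jsonlite::write_json(truths, file.path(cfg$outputDir,
                                             "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      md <- data.frame(
        SampleID = c(colnames(trainTab), colnames(sinksTab)),
        Env = c(trainEnvs, rep("", ncol(sinksTab))),
        SourceSink = c(rep("source", ncol(trainTab)),
                       rep("sink", ncol(sinksTab))))
      utils::write.table(md, file.path(cfg$outputDir, "metadata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- stageRecord(manifest, "simulate", sp,
        file.path(cfg$outputDir, c("training.tsv", "sinks.tsv",
                                   "ground_truth.json", "metadata.tsv")))
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      level <- cfg$inputs$level %||% "otu"
      tab <- readFeatureTable(cfg$inputs$featureTable, level = level)
      if (!is.null(cfg$inputs$taxonomy)) {
        taxmap <- readTaxonomy(cfg$inputs$taxonomy)
        tab <- collapseTaxonomy(tab, taxmap,
                                level = cfg$inputs$collapseLevel %||%
                                  "species")
      }
      md <- readMetadata(cfg$inputs$metadata)
      missing <- setdiff(c(md$sources$SampleID, md$sinks), colnames(tab))
      if (length(missing))
        stop("metadata sample(s) absent from the feature table: ",
             paste(missing, collapse = ", "))
      trainTab <- tab[, md$sources$SampleID]
      trainEnvs <- md$sources$Env
      sources <- sourceSet(trainTab, trainEnvs)
      sinksTab <- tab[, md$sinks]
      manifest <- stageRecord(manifest, "load",
                               cfg$inputs, character())
    }, error = function(e) fail("load", e))
  }

  rdepth <- cfg$rarefy$depth %||% 10000
  tryCatch({
    shallowPolicy <- cfg$rarefy$shallow %||% "keep"
    sinksTab <- rarefyTable(sinksTab, rdepth, seed = seeds[["rarefy"]],
                            shallow = shallowPolicy)
    writeFeatureTable(sinksTab, file.path(cfg$outputDir,
                                          "sinks_rarefied.tsv"))
    manifest <- stageRecord(manifest, "rarefy",
      list(depth = rdepth, shallow = shallowPolicy,
           shallowSamples = attr(sinksTab, "shallow")),
      file.path(cfg$outputDir, "sinks_rarefied.tsv"))
  }, error = function(e) fail("rarefy", e))

  gb <- do.call(gibbsConfig, cfg$gibbs %||% list())
  estimates <- NULL
  tryCatch({
    trackSeeds <- splitSeeds(seeds[["track"]], ncol(sinksTab))
    estimates <- lapply(seq_len(ncol(sinksTab)), function(j)
      fitMixture(sinksTab[, j], sources, gb, seed = trackSeeds[j]))
    names(estimates) <- colnames(sinksTab)
    writeMixtureEstimates(estimates, file.path(cfg$outputDir, "track"))
    if (!is.null(cfg$contaminants)) {
      cc <- contaminationCheck(estimates, cfg$contaminants,
                               threshold = cfg$contaminantThreshold %||%
                                 0.1)
      utils::write.table(cc, file.path(cfg$outputDir,
                                       "contamination.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- stageRecord(manifest, "track",
      list(alpha1 = gb@alpha1, alpha2 = gb@alpha2, beta = gb@beta,
           burnIn = gb@burnIn, restarts = gb@restarts),
      file.path(cfg$outputDir, c("track_proportions.tsv",
                                 "track_draws.json")))
  }, error = function(e) fail("track", e))

  if (isTRUE(cfg$stages$calibrate)) {
    tryCatch({
      cc <- calibrationConfig(
        grid = unlist(cfg$calibrate$grid) %||%
          calibrationConfig()$grid,
        epsilon = cfg$calibrate$epsilon %||% 0.05)
      cal <- calibrateAlpha2(sinksTab, sources, cc, gb,
                             seed = seeds[["calibrate"]])
      jsonlite::write_json(
        list(grid = cal@grid, chosen = cal@chosen,
             epsilon = cal@epsilon, pass = cal@pass),
        file.path(cfg$outputDir, "calibration.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE)
      manifest <- stageRecord(manifest, "calibrate",
        list(grid = cc$grid, epsilon = cc$epsilon,
             chosen = cal@chosen),
        file.path(cfg$outputDir, "calibration.json"))
    }, error = function(e) fail("calibrate", e))
  }

  if (isTRUE(cfg$stages$robustness)) {
    tryCatch({
      depths <- unlist(cfg$robustness$depths) %||% c(500, 1000, 2000, 5000)
      rb <- depthRobustness(sinksTab[, 1], sources, gb, depths = depths,
                            seed = seeds[["robustness"]])
      utils::write.table(rb, file.path(cfg$outputDir, "robustness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- stageRecord(manifest, "robustness",
        list(depths = depths),
        file.path(cfg$outputDir, "robustness.tsv"))
    }, error = function(e) fail("robustness", e))
  }

  if (isTRUE(cfg$stages$compare)) {
    tryCatch({
      all <- mergeTables(list(trainTab, sinksTab))
      prof <- phylumProfiles(all, taxmap = cfg$compare$taxmap,
                             minFreq = cfg$compare$minFreq %||% 0.05)
      hc <- clusterProfiles(prof,
                            linkage = cfg$compare$linkage %||% "complete")
      writeDendrogram(hc, file.path(cfg$outputDir, "dendrogram.nwk"))
      sh <- otuSharing(all)
      utils::write.table(sh$intersection,
                         file.path(cfg$outputDir, "otu_sharing.tsv"),
                         sep = "\t", quote = FALSE)
      manifest <- stageRecord(manifest, "compare",
        list(minFreq = prof$minFreq),
        file.path(cfg$outputDir, c("dendrogram.nwk", "otu_sharing.tsv")))
    }, error = function(e) fail("compare", e))
  }

  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
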