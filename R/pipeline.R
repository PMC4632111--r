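#' Assemble a pipeline configuration
#'
#' Collects every tunable of the workflow in one serializable list:
#' preprocessing (bin width, covered range, excluded regions,
#' normalization), the component-number sweep (kmax, ALS tolerance and
#' iteration cap), and the reliability clustering (AU level, bootstrap
#' size and scales, correlation cutoff, shuffle replicates, master seed).
#' Every random stage derives its seed from `seed`, so a configuration
#' reproduces a run exactly.
#'
#' @param input path to the input data (wide CSV of binned spectra, or
#'   long CSV of raw spectra when `inputFormat = "long"`); may be `NULL`
#'   when `data` is supplied programmatically to [runPipeline()].
#' @param outputDir artifact directory.
#' @param inputFormat `"wide"` (already binned) or `"long"` (raw points,
#'   to be binned).
#' @param binWidth,range binning parameters (used for `"long"` input).
#' @param exclude list of `c(lo, hi)` ppm regions to remove.
#' @param normalize apply total-intensity normalization.
#' @param kmax sweep bound (`NULL`: number of samples).
#' @param tol,maxIter ALS parameters.
#' @param alpha,nboot,scales,corrMin,nShuffle reliability parameters.
#' @param seed master seed.
#' @param k fixed component number for [runConventional()] (`NULL`:
#'   estimate by parallel analysis).
#' @return named list with class `"camcrConfig"`.
#' @export
pipelineConfig <- function(input = NULL, outputDir = "camcr-out",
                           inputFormat = c("wide", "long"),
                           binWidth = 0.04, range = c(0, 10),
                           exclude = list(), normalize = TRUE,
                           kmax = NULL, tol = 1e-8, maxIter = 200,
                           alpha = 0.95, nboot = 1000,
                           scales = seq(0.5, 1.4, by = 0.1),
                           corrMin = 0.6, nShuffle = 10, seed = 1,
                           k = NULL) {
  structure(list(
    input = input, outputDir = outputDir,
    inputFormat = match.arg(inputFormat),
    binWidth = binWidth, range = range, exclude = exclude,
    normalize = normalize, kmax = kmax, tol = tol, maxIter = maxIter,
    alpha = alpha, nboot = nboot, scales = scales, corrMin = corrMin,
    nShuffle = nShuffle, seed = seed, k = k), class = "camcrConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [readPipelineConfig()]: a `"camcrConfig"` list;
#'   [writePipelineConfig()]: `path`, invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (!is.null(cfg$exclude))
    cfg$exclude <- lapply(cfg$exclude, as.numeric)
  cfg$scales <- as.numeric(cfg$scales)
  cfg$range <- as.numeric(cfg$range)
  cfg
}

#' @rdname readPipelineConfig
#' @param config a `"camcrConfig"` list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

loadInput <- function(config, data = NULL) {
  if (!is.null(data)) {
    d <- if (is(data, "BinnedSpectra")) data
         else BinnedSpectra(as.matrix(data),
                            asDataMatrix(as.matrix(data))$binCenters)
    return(d)
  }
  if (is.null(config$input))
    stop("config has no input path and no data was supplied")
  if (!file.exists(config$input))
    stop("input file does not exist: ", config$input)
  if (config$inputFormat == "long") {
    binSpectra(readLongSpectra(config$input), binWidth = config$binWidth,
               range = config$range)
  } else {
    readBinnedSpectra(config$input)
  }
}

preprocessStage <- function(bs, config) {
  if (length(config$exclude)) bs <- excludeRegions(bs, config$exclude)
  if (isTRUE(config$normalize) && !bs@normalized) bs <- normalizeTotal(bs)
  bs
}

#' Run the full cluster-aided MCR-ALS pipeline
#'
#' Executes preprocess (bin / exclude / normalize), the component-number
#' sweep, AU clustering with the shuffle-based size threshold and
#' correlation refinement, and per-cluster summarization, writing every
#' intermediate and final table to `config$outputDir` together with a
#' provenance JSON (configuration, package version, seeds, stage timings,
#' and stage counts). Deterministic given identical configuration.
#'
#' @param config a `"camcrConfig"` list (see [pipelineConfig()]).
#' @param data optional [BinnedSpectra-class] (or matrix) supplied directly
#'   instead of `config$input`.
#' @return invisibly, a list with `data`, `pool`, `reliable`, `summaries`,
#'   `table`, and `provenance`.
#' @export
runPipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "camcrConfig"))
  bs <- loadInput(config, data)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config = config[!vapply(config, is.null, TRUE)],
               package = as.character(packageVersion("camcr")),
               timings = list(), counts = list())
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    prov$timings[[name]] <<- round(tic() - t0, 3)
    out
  }

  bs <- stage("preprocess", preprocessStage(bs, config))
  writeBinnedSpectra(bs, file.path(config$outputDir, "preprocessed.csv"))

  pool <- stage("sweep", runSweep(bs, kmax = config$kmax, tol = config$tol,
                                  maxIter = config$maxIter))
  prov$counts$pooledComponents <- nComponents(pool)
  writeComponentPool(pool, file.path(config$outputDir, "pool"))

  reliable <- stage("cluster",
    selectReliable(pool, alpha = config$alpha, corrMin = config$corrMin,
                   nShuffle = config$nShuffle, nboot = config$nboot,
                   scales = config$scales, seed = config$seed))
  prov$counts$selectedClusters <- reliable@params$nSelected
  prov$counts$reliableClusters <- length(reliable@clusters)
  prov$counts$rejectedClusters <- nrow(reliable@rejected)
  prov$counts$sizeThreshold <- reliable@threshold@value
  writeClusterMembership(reliable, pool,
                         file.path(config$outputDir, "clusters.csv"))

  summaries <- stage("summarize", summarizeClusters(pool, reliable))
  tab <- if (length(summaries)) summaryTable(summaries)
         else data.frame(clusterId = character(), size = integer(),
                         ssd = numeric(), topBins = character())
  write.csv(tab, file.path(config$outputDir, "cluster_summary.csv"),
            row.names = FALSE)
  for (s in summaries) {
    stemDir <- file.path(config$outputDir, paste0("cluster_", s@clusterId))
    dir.create(stemDir, showWarnings = FALSE)
    write.csv(data.frame(sample_id = s@sampleIds,
                         typical_concentration = s@typicalConcentration,
                         cv = s@cvMatrix[, which.max(s@typicalSpectrum)]),
              file.path(stemDir, "typical_concentration.csv"),
              row.names = FALSE)
    write.csv(data.frame(ppm = s@binCenters,
                         typical_spectrum = s@typicalSpectrum),
              file.path(stemDir, "typical_spectrum.csv"), row.names = FALSE)
    write.csv(data.frame(record_id = s@memberIds),
              file.path(stemDir, "members.csv"), row.names = FALSE)
  }

  jsonlite::write_json(prov, file.path(config$outputDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(data = bs, pool = pool, reliable = reliable,
                 summaries = summaries, table = tab, provenance = prov))
}

#' Run conventional MCR-ALS (single fixed k) as a comparison baseline
#'
#' Estimates the number of components (parallel analysis by default, or a
#' fixed `config$k`), runs one MCR-ALS at that k, and writes the resulting
#' concentration and spectral profiles in the same record schema as one
#' sweep run.
#'
#' @inheritParams runPipeline
#' @return invisibly, a list with `k`, `fit`, and the output `pool` of the
#'   single run.
#' @export
runConventional <- function(config, data = NULL) {
  stopifnot(inherits(config, "camcrConfig"))
  bs <- loadInput(config, data)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  bs <- preprocessStage(bs, config)
  k <- config$k
  if (is.null(k)) {
    k <- parallelAnalysis(bs, nRep = 100, seed = config$seed)
    if (k < 1) k <- 1L
  }
  fit <- mcrAls(bs, k, tol = config$tol, maxIter = config$maxIter)
  pool <- poolFromFit(fit)
  writeComponentPool(pool, file.path(config$outputDir, "conventional"))
  jsonlite::write_json(
    list(k = k, kSource = if (is.null(config$k)) "parallel_analysis"
                          else "fixed",
         residualSSE = fit@residualSSE, converged = fit@converged,
         seed = config$seed),
    file.path(config$outputDir, "conventional_provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(k = k, fit = fit, pool = pool))
}
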