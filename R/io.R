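#' Read raw spectra from a long-format CSV
#'
#' Expected columns: `ppm`, `intensity`, `sample_id`.
#'
#' @param path CSV file path.
#' @return named list of raw spectra (data.frames with `ppm`, `intensity`),
#'   suitable for [binSpectra()].
#' @export
readLongSpectra <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ppm", "intensity", "sample_id")
  if (!all(need %in% names(df)))
    stop("long-format CSV must have columns ppm, intensity, sample_id")
  split(df[, c("ppm", "intensity")], df$sample_id)
}

#' Read a binned matrix from a wide CSV
#'
#' Rows are samples; the first column (`sample_id`) holds sample
#' identifiers and the remaining column names are ppm bin labels.
#'
#' @param path CSV file path.
#' @return A [BinnedSpectra-class].
#' @export
readBinnedSpectra <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df) >= 2) stop("wide CSV needs a sample_id column plus bins")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  bc <- suppressWarnings(as.numeric(colnames(vals)))
  if (anyNA(bc)) stop("bin column names must be numeric ppm labels")
  rs <- rowSums(vals)
  BinnedSpectra(vals, bc, ids,
                normalized = all(abs(rs - 1) <= 1e-9))
}

#' Write a binned matrix as a wide CSV
#'
#' @param x a [BinnedSpectra-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeBinnedSpectra <- function(x, path) {
  stopifnot(is(x, "BinnedSpectra"))
  df <- data.frame(sample_id = x@sampleIds, x@values, check.names = FALSE)
  colnames(df) <- c("sample_id", formatPpm(x@binCenters))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a component pool as CSV files plus a provenance sidecar
#'
#' Writes `<stem>_concentrations.csv` (one row per record: id, run_k,
#' index_in_run, then one column per sample), `<stem>_spectra.csv`
#' (analogous, one column per bin), and `<stem>_provenance.json`.
#'
#' @param pool a [ComponentPool-class].
#' @param stem output path stem.
#' @return character vector of the files written, invisibly.
#' @export
writeComponentPool <- function(pool, stem) {
  stopifnot(is(pool, "ComponentPool"))
  meta <- data.frame(id = pool@ids, run_k = pool@runK,
                     index_in_run = pool@indexInRun)
  fc <- paste0(stem, "_concentrations.csv")
  fs <- paste0(stem, "_spectra.csv")
  fp <- paste0(stem, "_provenance.json")
  dfc <- cbind(meta, as.data.frame(pool@conc))
  colnames(dfc) <- c(names(meta), pool@sampleIds)
  write.csv(dfc, fc, row.names = FALSE)
  dfs <- cbind(meta, as.data.frame(pool@spec))
  colnames(dfs) <- c(names(meta), formatPpm(pool@binCenters))
  write.csv(dfs, fs, row.names = FALSE)
  jsonlite::write_json(
    c(pool@provenance,
      list(nRecords = nrow(pool@conc),
           nSamples = length(pool@sampleIds),
           nBins = length(pool@binCenters))),
    fp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fc, fs, fp))
}

#' Read a component pool written by [writeComponentPool()]
#'
#' @param stem path stem used when writing.
#' @return A [ComponentPool-class].
#' @export
readComponentPool <- function(stem) {
  dfc <- read.csv(paste0(stem, "_concentrations.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  dfs <- read.csv(paste0(stem, "_spectra.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  metaCols <- c("id", "run_k", "index_in_run")
  new("ComponentPool",
      conc = as.matrix(dfc[, setdiff(names(dfc), metaCols), drop = FALSE]),
      spec = as.matrix(dfs[, setdiff(names(dfs), metaCols), drop = FALSE]),
      runK = as.integer(dfc$run_k),
      indexInRun = as.integer(dfc$index_in_run),
      ids = as.character(dfc$id),
      sampleIds = setdiff(names(dfc), metaCols),
      binCenters = as.numeric(setdiff(names(dfs), metaCols)),
      provenance = list())
}

#' Per-node report of an AU clustering
#'
#' One row per internal dendrogram node: leaf count, AU p-value, fitted
#' (v, c), BP at every scale, and whether the node was selected at `alpha`.
#'
#' @param fit an [AUClusterFit-class].
#' @param alpha selection level used for the `selected` flag.
#' @return data.frame.
#' @export
auReport <- function(fit, alpha = 0.95) {
  stopifnot(is(fit, "AUClusterFit"))
  picks <- pickClusters(fit, alpha = alpha, maxOnly = TRUE)
  sel <- as.integer(names(picks))
  df <- data.frame(node = seq_along(fit@leafSets),
                   size = lengths(fit@leafSets),
                   au = fit@au, v = fit@fitV, c = fit@fitC,
                   selected = seq_along(fit@leafSets) %in% sel)
  cbind(df, as.data.frame(fit@bp))
}

#' Export the observed dendrogram as Newick with AU node labels
#'
#' @param fit an [AUClusterFit-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(fit, path) {
  stopifnot(is(fit, "AUClusterFit"))
  merge <- fit@hclust$merge
  height <- fit@hclust$height
  lab <- fit@labels
  au <- fit@au
  node <- function(i, parentH) {
    if (i < 0) {
      sprintf("%s:%.6g", lab[-i], parentH)
    } else {
      h <- height[i]
      sprintf("(%s,%s)%.3f:%.6g", node(merge[i, 1], h), node(merge[i, 2], h),
              au[i], parentH - h)
    }
  }
  m <- nrow(merge)
  txt <- paste0("(", node(merge[m, 1], height[m]), ",",
                node(merge[m, 2], height[m]), ")", sprintf("%.3f", au[m]),
                ";")
  writeLines(txt, path)
  invisible(path)
}

#' Write reliable-cluster membership as CSV
#'
#' Columns: `cluster_id`, `record_id`, `run_k`, `index_in_run`.
#'
#' @param reliable a [ReliableClusters-class].
#' @param pool the [ComponentPool-class] the cluster ids refer to.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterMembership <- function(reliable, pool, path) {
  stopifnot(is(reliable, "ReliableClusters"), is(pool, "ComponentPool"))
  rows <- lapply(names(reliable@clusters), function(cid) {
    ids <- reliable@clusters[[cid]]
    idx <- match(ids, pool@ids)
    data.frame(cluster_id = cid, record_id = ids,
               run_k = pool@runK[idx], index_in_run = pool@indexInRun[idx],
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(cluster_id = character(), record_id = character(),
                        run_k = integer(), index_in_run = integer())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
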