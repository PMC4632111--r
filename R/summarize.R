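#' Rank-one contribution of one component
#'
#' The outer product `concentration %o% spectrum` (C x St) of a pooled
#' component: a non-negative samples x bins matrix of rank at most one.
#' Summing the member products of one full run reconstructs that run's
#' fitted `C %*% t(S)`.
#'
#' @param pool a [ComponentPool-class].
#' @param id record id (e.g. `"k5_c2"`).
#' @return numeric samples x bins matrix.
#' @export
memberProduct <- function(pool, id) {
  stopifnot(is(pool, "ComponentPool"))
  i <- match(id, pool@ids)
  if (is.na(i)) stop("unknown record id: ", id)
  out <- outer(pool@conc[i, ], pool@spec[i, ])
  dimnames(out) <- list(pool@sampleIds, formatPpm(pool@binCenters))
  out
}

#' Element-wise statistics of a stack of member matrices
#'
#' Mean, sample standard deviation (n - 1 denominator; 0 for a single
#' member) and coefficient of variation (sd/mean where mean > 0, else 0)
#' computed element-wise across a list of equally-shaped matrices.
#'
#' @param members list of numeric matrices of identical shape (>= 1).
#' @return list with matrices `mean`, `sd`, `cv`.
#' @export
clusterStats <- function(members) {
  if (!length(members)) stop("at least one member is required")
  dims <- dim(members[[1]])
  arr <- array(unlist(members, use.names = FALSE),
               dim = c(dims, length(members)))
  mu <- apply(arr, c(1, 2), mean)
  sdm <- if (length(members) >= 2) apply(arr, c(1, 2), sd)
         else matrix(0, dims[1], dims[2])
  cv <- matrix(0, dims[1], dims[2])
  pos <- mu > 0
  cv[pos] <- sdm[pos] / mu[pos]
  dimnames(mu) <- dimnames(sdm) <- dimnames(cv) <- dimnames(members[[1]])
  list(mean = mu, sd = sdm, cv = cv)
}

#' Typical profiles of a cluster-mean matrix
#'
#' Locates the global maximum of the mean C x St matrix; the row through it
#' is the typical spectral profile (across bins) and the column through it
#' the typical concentration profile (across samples). Ties are broken by
#' the first occurrence in row-major order.
#'
#' @param meanMatrix numeric samples x bins matrix with at least one
#'   strictly positive entry.
#' @return list with `typicalSpectrum` (length = bins),
#'   `typicalConcentration` (length = samples), and the max position
#'   `c(row, col)`.
#' @export
typicalProfiles <- function(meanMatrix) {
  m <- as.matrix(meanMatrix)
  if (max(m) <= 0) stop("mean matrix has no positive entry")
  ## first occurrence in row-major order
  tm <- t(m)
  pos <- which.max(tm)
  col <- (pos - 1) %/% nrow(tm) + 1  # row index of m
  row <- pos - (col - 1) * nrow(tm)  # col index of m
  list(typicalSpectrum = m[col, ],
       typicalConcentration = m[, row],
       position = c(row = as.integer(col), col = as.integer(row)))
}

#' Sum of squared deviations of a profile
#'
#' `sum((x - mean(x))^2)`; used to rank clusters by amount of information.
#'
#' @param x numeric vector.
#' @return scalar, non-negative.
#' @export
clusterSSD <- function(x) {
  sum((x - mean(x))^2)
}

#' Summarize one reliable cluster
#'
#' Stacks the member C x St products, computes element-wise mean/sd/CV,
#' extracts the typical profiles and the SSD of the typical concentration
#' profile.
#'
#' @param pool a [ComponentPool-class].
#' @param memberIds record ids of the cluster members.
#' @param clusterId label for the result.
#' @return A [ClusterSummary-class].
#' @export
summarizeCluster <- function(pool, memberIds, clusterId = "cluster") {
  stopifnot(is(pool, "ComponentPool"), length(memberIds) >= 1)
  members <- lapply(memberIds, function(id) memberProduct(pool, id))
  st <- clusterStats(members)
  tp <- typicalProfiles(st$mean)
  new("ClusterSummary",
      clusterId = as.character(clusterId),
      memberIds = as.character(memberIds),
      meanMatrix = st$mean,
      sdMatrix = st$sd,
      cvMatrix = st$cv,
      typicalConcentration = tp$typicalConcentration,
      typicalSpectrum = tp$typicalSpectrum,
      ssd = clusterSSD(tp$typicalConcentration),
      sampleIds = pool@sampleIds,
      binCenters = pool@binCenters)
}

#' Summarize all reliable clusters
#'
#' @param pool a [ComponentPool-class].
#' @param reliable a [ReliableClusters-class] (or named list of id vectors).
#' @return named list of [ClusterSummary-class] objects.
#' @export
summarizeClusters <- function(pool, reliable) {
  clusters <- if (is(reliable, "ReliableClusters")) reliable@clusters
              else reliable
  out <- lapply(seq_along(clusters), function(i) {
    cid <- names(clusters)[i]
    if (is.null(cid) || !nzchar(cid)) cid <- as.character(i)
    summarizeCluster(pool, clusters[[i]], cid)
  })
  names(out) <- vapply(out, slot, "", "clusterId")
  out
}

#' Overview table of cluster summaries
#'
#' One row per cluster: id, size, SSD of the typical concentration profile
#' (the information ranking), and the top bins of the typical spectrum.
#'
#' @param summaries list of [ClusterSummary-class] (from
#'   [summarizeClusters()]).
#' @param topBins how many leading spectral bins to report.
#' @return data.frame sorted by decreasing SSD.
#' @export
summaryTable <- function(summaries, topBins = 3) {
  if (!length(summaries)) {
    return(data.frame(clusterId = character(), size = integer(),
                      ssd = numeric(), topBins = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(summaries, function(s) {
    ord <- order(s@typicalSpectrum, decreasing = TRUE)[seq_len(min(topBins,
                 length(s@typicalSpectrum)))]
    data.frame(clusterId = s@clusterId,
               size = length(s@memberIds),
               ssd = s@ssd,
               topBins = paste(formatPpm(s@binCenters[ord]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$ssd), , drop = FALSE]
}

#' Score compound detection against a known concentration design
#'
#' For each compound of a known design, finds the reliable cluster whose
#' typical concentration profile correlates best with the compound's true
#' concentration series. A compound is "correctly detected" when that best
#' Pearson correlation exceeds 0.8. One cluster may be the best match for
#' several compounds (concentration-confounded compounds share a cluster).
#'
#' @param summaries list of [ClusterSummary-class].
#' @param known numeric samples x compounds matrix of true concentrations,
#'   sample order aligned with the summaries' profiles.
#' @param cutoff detection cutoff on the correlation (default 0.8).
#' @return data.frame with one row per compound: `compound`, `bestCluster`,
#'   `bestCorrelation`, `detected`. Compounds with a constant series get
#'   `NA` correlation and `NA` detection.
#' @export
detectionScore <- function(summaries, known, cutoff = 0.8) {
  known <- as.matrix(known)
  if (!length(summaries)) {
    return(data.frame(compound = colnames(known),
                      bestCluster = NA_character_,
                      bestCorrelation = NA_real_,
                      detected = FALSE,
                      stringsAsFactors = FALSE))
  }
  profiles <- vapply(summaries, slot, numeric(nrow(known)),
                     "typicalConcentration")
  cn <- colnames(known)
  if (is.null(cn)) cn <- paste0("compound", seq_len(ncol(known)))
  rows <- lapply(seq_len(ncol(known)), function(j) {
    serie <- known[, j]
    if (var(serie) == 0) {
      return(data.frame(compound = cn[j], bestCluster = NA_character_,
                        bestCorrelation = NA_real_, detected = NA,
                        stringsAsFactors = FALSE))
    }
    cc <- suppressWarnings(as.numeric(cor(serie, profiles)))
    best <- which.max(cc)
    data.frame(compound = cn[j],
               bestCluster = vapply(summaries, slot, "", "clusterId")[best],
               bestCorrelation = cc[best],
               detected = is.finite(cc[best]) && cc[best] > cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
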