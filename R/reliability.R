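#' Shuffle a component pool to destroy its correlation structure
#'
#' Each record's concentration values are permuted independently across
#' sample positions (a separate permutation per record), preserving every
#' profile's marginal value multiset while destroying the inter-profile
#' correlation that the clustering detects. This is the null model behind
#' the cluster-size threshold.
#'
#' @param pool a [ComponentPool-class].
#' @param seed integer seed; reproducible.
#' @return A [ComponentPool-class] with shuffled concentration profiles
#'   (spectral profiles are untouched).
#' @export
shuffleProfiles <- function(pool, seed = 1) {
  stopifnot(is(pool, "ComponentPool"))
  if (nrow(pool@conc) < 2) stop("at least 2 records are required")
  n <- ncol(pool@conc)
  shuffled <- withSeed(seed, {
    t(apply(pool@conc, 1, function(row) row[sample.int(n)]))
  })
  out <- pool
  out@conc <- shuffled
  out@provenance <- c(pool@provenance, list(shuffledSeed = as.integer(seed)))
  out
}

#' Cluster-size threshold from randomized data
#'
#' Repeats the AU clustering and selection on independently shuffled copies
#' of the pool and records, per replicate, the size of the largest cluster
#' a chance pattern can produce (0 when none is selected). The threshold is
#' the maximum over replicates; a real cluster is considered reliable only
#' if its size is strictly greater than this value.
#'
#' With `corrMin` set (the default matches the pipeline's refinement
#' cutoff), each replicate applies the same correlation refinement as the
#' real analysis before taking the maximum, so the null statistic is the
#' size of a chance cluster that could actually be *accepted* — the same
#' statistic the threshold is compared against. `corrMin = NULL` records
#' the raw selected sizes instead.
#'
#' @param pool a [ComponentPool-class].
#' @param nReplicates shuffle replicates (default 10, as for the biological
#'   matrices; 5 was used for the standard mixtures; many more — 1000+ — are
#'   preferable when compute allows).
#' @param alpha AU selection level.
#' @param seed master seed; per-replicate shuffle and bootstrap seeds are
#'   derived from it deterministically.
#' @param nboot,scales bootstrap parameters passed to [auCluster()].
#' @param corrMin internal-correlation cutoff applied to the null
#'   replicates, mirroring the real pipeline; `NULL` to disable.
#' @param refineMethod refinement method passed to [refineCluster()].
#' @return A [SizeThreshold-class].
#' @export
sizeThreshold <- function(pool, nReplicates = 10, alpha = 0.95, seed = 1,
                          nboot = 1000, scales = seq(0.5, 1.4, by = 0.1),
                          corrMin = 0.6,
                          refineMethod = c("divisive", "au")) {
  refineMethod <- match.arg(refineMethod)
  stopifnot(is(pool, "ComponentPool"), nReplicates >= 1)
  seeds <- childSeeds(seed, 3 * nReplicates)
  shuffleSeeds <- seeds[seq_len(nReplicates)]
  bootSeeds <- seeds[nReplicates + seq_len(nReplicates)]
  refineSeeds <- seeds[2 * nReplicates + seq_len(nReplicates)]
  maxSizes <- integer(nReplicates)
  for (i in seq_len(nReplicates)) {
    sp <- shuffleProfiles(pool, shuffleSeeds[i])
    sp <- dropConstantRecords(sp)
    fit <- auCluster(sp, scales = scales, nboot = nboot, seed = bootSeeds[i])
    picks <- pickClusters(fit, alpha = alpha, maxOnly = TRUE)
    best <- 0L
    if (length(picks)) {
      if (is.null(corrMin)) {
        best <- max(lengths(picks))
      } else {
        subSeeds <- childSeeds(refineSeeds[i], length(picks))
        for (j in seq_along(picks)) {
          res <- refineCluster(picks[[j]], sp, corrMin = corrMin,
                               threshold = 0, alpha = alpha, nboot = nboot,
                               scales = scales, seed = subSeeds[j],
                               method = refineMethod)
          if (length(res$accepted)) {
            best <- max(best, max(lengths(res$accepted)))
          }
        }
      }
    }
    maxSizes[i] <- best
  }
  new("SizeThreshold",
      value = max(maxSizes),
      perReplicateMax = maxSizes,
      nReplicates = as.integer(nReplicates),
      seed = as.integer(seed),
      shuffleSeeds = shuffleSeeds,
      bootSeeds = bootSeeds,
      refineSeeds = refineSeeds,
      alpha = alpha)
}

## Records whose concentration profile is exactly constant cannot enter a
## correlation-based clustering; drop them (they carry no pattern).
dropConstantRecords <- function(pool) {
  v <- apply(pool@conc, 1, var)
  keep <- which(is.finite(v) & v > 0)
  if (length(keep) == nrow(pool@conc)) return(pool)
  subsetPool(pool, pool@ids[keep])
}

#' Recursively refine a cluster by internal correlation
#'
#' Computes the full pairwise Pearson correlation matrix of the member
#' concentration profiles. A cluster whose minimum pairwise correlation
#' exceeds `corrMin` (and whose size exceeds the threshold) is accepted
#' as-is; otherwise undesired elements are removed by re-clustering the
#' members alone and recursing into the resulting sub-clusters until every
#' surviving group is internally coherent or too small.
#'
#' Two re-clustering methods are available. The default, `"divisive"`,
#' rebuilds the members' own correlation-distance UPGMA dendrogram and
#' divides at its top split — a deterministic recursion with no resampling
#' noise. `"au"` re-runs the full AU clustering ([auCluster()] +
#' [pickClusters()]) on the members, recurses into each selected
#' sub-cluster, re-examines the unselected remainder once as its own
#' group, and falls back to the top split when no sub-cluster is
#' significant. Sub-clusters at or below the size threshold are discarded
#' as `too_small`; irreducible low-correlation pairs as
#' `low_correlation_unresolvable`. Each recursion level deals with
#' strictly smaller clusters, so the process terminates.
#'
#' @param memberIds character record ids of the cluster.
#' @param pool the [ComponentPool-class] the ids refer to.
#' @param corrMin minimum acceptable pairwise correlation (default 0.6).
#' @param threshold integer size threshold (accept only sizes strictly
#'   greater).
#' @param alpha AU selection level for `"au"` re-clustering.
#' @param nboot,scales bootstrap parameters for `"au"` re-clustering.
#' @param seed seed for the `"au"` re-clustering bootstrap.
#' @param clusterId label used to derive sub-cluster ids (underscore
#'   paths).
#' @param method `"divisive"` (deterministic, default) or `"au"`.
#' @return list with `accepted` (named list of id vectors), `rejected`
#'   (data.frame: clusterId, size, reason), `audit` (data.frame of
#'   refinement events).
#' @export
refineCluster <- function(memberIds, pool, corrMin = 0.6, threshold = 0,
                          alpha = 0.95, nboot = 1000,
                          scales = seq(0.5, 1.4, by = 0.1), seed = 1,
                          clusterId = "1",
                          method = c("divisive", "au")) {
  method <- match.arg(method)
  accepted <- list()
  rejected <- data.frame(clusterId = character(), size = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  audit <- data.frame(clusterId = character(), size = integer(),
                      minCorrelation = numeric(), action = character(),
                      stringsAsFactors = FALSE)
  recurse <- function(ids, cid, seed) {
    size <- length(ids)
    if (size < 2 || size <= threshold) {
      rejected[nrow(rejected) + 1L, ] <<- list(cid, size, "too_small")
      return(invisible())
    }
    X <- pool@conc[match(ids, pool@ids), , drop = FALSE]
    minCor <- min(cor(t(X)))
    if (minCor > corrMin) {
      audit[nrow(audit) + 1L, ] <<- list(cid, size, minCor, "accepted")
      accepted[[cid]] <<- ids
      return(invisible())
    }
    if (size < 3) {
      ## two mutually uncorrelated members cannot be subdivided further
      audit[nrow(audit) + 1L, ] <<- list(cid, size, minCor, "discarded")
      rejected[nrow(rejected) + 1L, ] <<-
        list(cid, size, "low_correlation_unresolvable")
      return(invisible())
    }
    audit[nrow(audit) + 1L, ] <<- list(cid, size, minCor, "split")
    if (method == "divisive") {
      hc <- hclustAverage(correlationDistance(X))
      memb <- stats::cutree(hc, k = 2)
      subSeeds <- childSeeds(seed, 2)
      for (g in 1:2) {
        recurse(ids[memb == g], paste0(cid, "_", g), subSeeds[g])
      }
      return(invisible())
    }
    sub <- subsetPool(pool, ids)
    fit <- auCluster(sub, scales = scales, nboot = nboot, seed = seed)
    picks <- pickClusters(fit, alpha = alpha, maxOnly = TRUE)
    if (!length(picks)) {
      ## no significant sub-cluster: divide at the top split of the
      ## members' own dendrogram rather than discarding a possibly
      ## coherent core outright
      m <- length(ids)
      merge <- fit@hclust$merge
      topSets <- lapply(1:2, function(s) {
        v <- merge[m - 1, s]
        if (v < 0) fit@labels[-v] else fit@labels[fit@leafSets[[v]]]
      })
      subSeeds <- childSeeds(seed, 2)
      for (j in 1:2) {
        recurse(topSets[[j]], paste0(cid, "_", letters[j]), subSeeds[j])
      }
      return(invisible())
    }
    remainder <- setdiff(ids, unlist(picks))
    subSeeds <- childSeeds(seed, length(picks) + 1)
    for (j in seq_along(picks)) {
      recurse(picks[[j]], paste0(cid, "_", j), subSeeds[j])
    }
    ## unselected members get re-examined as their own group instead of
    ## being discarded wholesale
    if (length(remainder) >= 2 && length(remainder) < size) {
      recurse(remainder, paste0(cid, "_r"), subSeeds[length(picks) + 1])
    } else if (length(remainder)) {
      rejected[nrow(rejected) + 1L, ] <<-
        list(paste0(cid, "_r"), length(remainder), "too_small")
    }
    invisible()
  }
  recurse(memberIds, clusterId, seed)
  list(accepted = accepted, rejected = rejected, audit = audit)
}

#' Select reliable clusters from a component pool
#'
#' The full reliability pipeline on pooled concentration profiles:
#' AU clustering of the pool, selection of non-nested clusters with
#' `AU > alpha`, rejection of clusters at or below the randomized-data size
#' threshold, and recursive refinement of clusters whose minimum internal
#' pairwise correlation does not exceed `corrMin`. Accepted clusters are
#' pairwise disjoint, strictly larger than the threshold, and internally
#' correlated above `corrMin`.
#'
#' @param pool a [ComponentPool-class].
#' @param alpha AU selection level (default 0.95).
#' @param corrMin internal correlation cutoff (default 0.6). Set to `-1`
#'   to disable refinement.
#' @param nShuffle shuffle replicates for the size threshold (default 10).
#' @param nboot,scales bootstrap parameters.
#' @param seed master seed; threshold, clustering, and refinement seeds are
#'   derived from it.
#' @param threshold optional pre-computed [SizeThreshold-class] (or bare
#'   integer); when supplied, the shuffle step is skipped.
#' @param bootSeed,refineSeed optional explicit seeds for the clustering
#'   bootstrap and the refinement of the observed pool (by default derived
#'   from `seed`); useful for matched-seed null experiments where the
#'   pipeline input is itself one of the threshold's shuffle replicates.
#' @param refineMethod refinement method passed to [refineCluster()]
#'   (deterministic `"divisive"` by default).
#' @return A [ReliableClusters-class].
#' @export
#' @examples
#' \donttest{
#' d <- standardMixturePreset(nSamples = 12, seed = 1)
#' pool <- runSweep(d@data, kmax = 8)
#' rc <- selectReliable(pool, nboot = 100, nShuffle = 2, seed = 1)
#' rc
#' }
selectReliable <- function(pool, alpha = 0.95, corrMin = 0.6, nShuffle = 10,
                           nboot = 1000, scales = seq(0.5, 1.4, by = 0.1),
                           seed = 1, threshold = NULL, bootSeed = NULL,
                           refineSeed = NULL,
                           refineMethod = c("divisive", "au")) {
  stopifnot(is(pool, "ComponentPool"))
  refineMethod <- match.arg(refineMethod)
  seeds <- childSeeds(seed, 3)
  if (is.null(bootSeed)) bootSeed <- seeds[2]
  if (is.null(refineSeed)) refineSeed <- seeds[3]
  if (is.null(threshold)) {
    threshold <- sizeThreshold(pool, nReplicates = nShuffle, alpha = alpha,
                               seed = seeds[1], nboot = nboot,
                               scales = scales, corrMin = corrMin,
                               refineMethod = refineMethod)
  } else if (is.numeric(threshold)) {
    threshold <- new("SizeThreshold", value = as.integer(threshold),
                     perReplicateMax = as.integer(threshold),
                     nReplicates = 1L, seed = NA_integer_,
                     shuffleSeeds = NA_integer_, bootSeeds = NA_integer_,
                     refineSeeds = NA_integer_, alpha = alpha)
  }
  stopifnot(is(threshold, "SizeThreshold"))
  thr <- threshold@value

  cleaned <- dropConstantRecords(pool)
  fit <- auCluster(cleaned, scales = scales, nboot = nboot, seed = bootSeed)
  picks <- pickClusters(fit, alpha = alpha, maxOnly = TRUE)

  clusters <- list()
  rejected <- data.frame(clusterId = character(), size = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  audit <- data.frame(clusterId = character(), size = integer(),
                      minCorrelation = numeric(), action = character(),
                      stringsAsFactors = FALSE)
  refineSeeds <- childSeeds(refineSeed, max(1, length(picks)))
  for (i in seq_along(picks)) {
    res <- refineCluster(picks[[i]], cleaned, corrMin = corrMin,
                         threshold = thr, alpha = alpha, nboot = nboot,
                         scales = scales, seed = refineSeeds[i],
                         clusterId = as.character(i),
                         method = refineMethod)
    clusters <- c(clusters, res$accepted)
    rejected <- rbind(rejected, res$rejected)
    audit <- rbind(audit, res$audit)
  }
  new("ReliableClusters",
      clusters = clusters,
      rejected = rejected,
      threshold = threshold,
      params = list(alpha = alpha, corrMin = corrMin, nboot = nboot,
                    scales = scales, seed = seed,
                    nSelected = length(picks)),
      audit = audit)
}
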