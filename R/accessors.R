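#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("intensities", "BinnedSpectra", function(x) {
  m <- x@values
  dimnames(m) <- list(x@sampleIds, formatPpm(x@binCenters))
  m
})

#' @rdname accessors
setMethod("binCenters", "BinnedSpectra", function(x) x@binCenters)

#' @rdname accessors
setMethod("sampleIds", "BinnedSpectra", function(x) x@sampleIds)

#' @rdname accessors
setMethod("binCenters", "ComponentPool", function(x) x@binCenters)

#' @rdname accessors
setMethod("sampleIds", "ComponentPool", function(x) x@sampleIds)

#' @rdname accessors
setMethod("concProfiles", "MCRFit", function(x) {
  m <- x@C
  dimnames(m) <- list(x@sampleIds, paste0("c", seq_len(ncol(m))))
  m
})

#' @rdname accessors
setMethod("specProfiles", "MCRFit", function(x) {
  m <- x@S
  dimnames(m) <- list(formatPpm(x@binCenters), paste0("c", seq_len(ncol(m))))
  m
})

#' @rdname accessors
setMethod("concProfiles", "ComponentPool", function(x) {
  m <- x@conc
  dimnames(m) <- list(x@ids, x@sampleIds)
  m
})

#' @rdname accessors
setMethod("specProfiles", "ComponentPool", function(x) {
  m <- x@spec
  dimnames(m) <- list(x@ids, formatPpm(x@binCenters))
  m
})

#' @rdname accessors
setMethod("componentIds", "ComponentPool", function(x) x@ids)

#' @rdname accessors
setMethod("nComponents", "MCRFit", function(x) ncol(x@C))

#' @rdname accessors
setMethod("nComponents", "ComponentPool", function(x) nrow(x@conc))

#' @rdname accessors
setMethod("auValues", "AUClusterFit", function(x) x@au)

#' @rdname accessors
setMethod("reliableClusters", "ReliableClusters", function(x) x@clusters)

setMethod("show", "BinnedSpectra", function(object) {
  cat(sprintf("BinnedSpectra: %d samples x %d bins\n",
              nrow(object@values), ncol(object@values)))
  if (length(object@binCenters)) {
    cat(sprintf("  ppm range: %.3f .. %.3f\n",
                min(object@binCenters), max(object@binCenters)))
  }
  cat(sprintf("  normalized: %s\n", object@normalized))
})

setMethod("show", "MCRFit", function(object) {
  cat(sprintf("MCRFit: k = %d (%d samples x %d bins)\n",
              object@kRequested, nrow(object@C), nrow(object@S)))
  cat(sprintf("  residual SSE %.4g after %d iterations (converged: %s)\n",
              object@residualSSE, object@nIter, object@converged))
})

setMethod("show", "ComponentPool", function(object) {
  kk <- if (length(object@runK)) range(object@runK) else c(NA, NA)
  cat(sprintf("ComponentPool: %d components from runs k = %s..%s\n",
              nrow(object@conc), kk[1], kk[2]))
  cat(sprintf("  %d samples, %d bins\n",
              length(object@sampleIds), length(object@binCenters)))
})

setMethod("show", "AUClusterFit", function(object) {
  cat(sprintf("AUClusterFit: %d leaves, %d internal nodes\n",
              length(object@labels), length(object@leafSets)))
  cat(sprintf("  nboot = %d per scale, %d scales (%.2g..%.2g)\n",
              object@nboot, length(object@scales),
              min(object@scales), max(object@scales)))
  n95 <- sum(object@au > 0.95, na.rm = TRUE)
  cat(sprintf("  nodes with AU > 0.95: %d\n", n95))
})

setMethod("show", "SizeThreshold", function(object) {
  cat(sprintf("SizeThreshold: %d (max over %d shuffle replicates: %s)\n",
              object@value, object@nReplicates,
              paste(object@perReplicateMax, collapse = ", ")))
})

setMethod("show", "ReliableClusters", function(object) {
  cat(sprintf("ReliableClusters: %d accepted, %d rejected (threshold > %d)\n",
              length(object@clusters), nrow(object@rejected),
              object@threshold@value))
  if (length(object@clusters)) {
    sz <- vapply(object@clusters, length, 0L)
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
  }
})

setMethod("show", "ClusterSummary", function(object) {
  cat(sprintf("ClusterSummary '%s': %d members, SSD %.4g\n",
              object@clusterId, length(object@memberIds), object@ssd))
})

setMethod("show", "EigSpectrum", function(object) {
  cat(sprintf("EigSpectrum: %d eigenvalues (%s), %d samples x %d variables\n",
              length(object@values),
              if (object@standardized) "correlation" else "covariance",
              object@nSamples, object@nVars))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d samples x %d bins, %d compounds, noise sd %.4g, seed %d\n",
              nrow(object@data@values), ncol(object@data@values),
              ncol(object@concentrations), object@noiseSd, object@seed))
})
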