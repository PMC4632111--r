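#' @import methods
NULL

#' BinnedSpectra: a samples-by-bins NMR intensity matrix
#'
#' Container for binned 1D NMR spectra: a non-negative `samples x bins`
#' intensity matrix together with the ppm positions of the bin centers and
#' the sample identifiers. This is the data matrix D of the bilinear model
#' `D = C %*% t(S) + E` that all downstream analysis consumes.
#'
#' @slot values numeric matrix, samples x bins, non-negative.
#' @slot binCenters numeric vector of bin-center chemical shifts (ppm),
#'   strictly monotone.
#' @slot sampleIds character vector of sample identifiers.
#' @slot normalized logical; `TRUE` after total-intensity normalization
#'   (each row sums to one).
#'
#' @seealso [binSpectra()], [excludeRegions()], [normalizeTotal()]
#' @exportClass BinnedSpectra
setClass("BinnedSpectra",
  representation(
    values = "matrix",
    binCenters = "numeric",
    sampleIds = "character",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

setValidity("BinnedSpectra", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (ncol(v) != length(object@binCenters))
    msg <- c(msg, "ncol(values) must equal length(binCenters)")
  if (nrow(v) != length(object@sampleIds))
    msg <- c(msg, "nrow(values) must equal length(sampleIds)")
  if (length(v) && min(v) < 0)
    msg <- c(msg, "intensities must be non-negative")
  bc <- object@binCenters
  if (length(bc) > 1) {
    d <- diff(bc)
    if (!(all(d > 0) || all(d < 0)))
      msg <- c(msg, "binCenters must be strictly monotone")
  }
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (isTRUE(object@normalized) && nrow(v)) {
    if (max(abs(rowSums(v) - 1)) > 1e-9)
      msg <- c(msg, "normalized flag set but row sums differ from 1")
  }
  if (length(msg)) msg else TRUE
})

#' MCRFit: one non-negativity constrained MCR-ALS factorization
#'
#' @slot C numeric matrix, samples x k, non-negative concentration profiles.
#' @slot S numeric matrix, bins x k, non-negative spectral profiles
#'   (`t(S)` is the k x bins matrix of the bilinear model).
#' @slot residualSSE sum of squared residuals of `D - C %*% t(S)`.
#' @slot sseTrace residual sum of squares after each full ALS alternation.
#' @slot nIter number of full alternations performed.
#' @slot converged logical; relative residual change fell below tolerance.
#' @slot kRequested number of components requested.
#' @slot dataMax maximum entry of the fitted data matrix (used for the
#'   default zero-component tolerance).
#' @slot sampleIds,binCenters labels carried over from the data.
#'
#' @seealso [alsFit()], [mcrAls()], [dropZeroComponents()]
#' @exportClass MCRFit
setClass("MCRFit",
  representation(
    C = "matrix",
    S = "matrix",
    residualSSE = "numeric",
    sseTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    kRequested = "integer",
    dataMax = "numeric",
    sampleIds = "character",
    binCenters = "numeric"
  )
)

setValidity("MCRFit", function(object) {
  msg <- character()
  if (ncol(object@C) != ncol(object@S))
    msg <- c(msg, "C and S must have the same number of columns")
  if (length(object@C) && min(object@C) < 0)
    msg <- c(msg, "C must be non-negative")
  if (length(object@S) && min(object@S) < 0)
    msg <- c(msg, "S must be non-negative")
  if (length(object@residualSSE) != 1 || object@residualSSE < 0)
    msg <- c(msg, "residualSSE must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' ComponentPool: pooled MCR-ALS components across a component-number sweep
#'
#' Each record is one component from one MCR-ALS run: its concentration
#' profile (length = number of samples), its spectral profile (length =
#' number of bins), the component number of the run it came from (`runK`)
#' and its index within that run. Records are identified as
#' `"k<runK>_c<indexInRun>"`. The pooled concentration profiles are the
#' dataset on which the reliability clustering operates.
#'
#' @slot conc numeric matrix, records x samples.
#' @slot spec numeric matrix, records x bins.
#' @slot runK integer vector; components requested in the originating run.
#' @slot indexInRun integer vector; column index within the originating run.
#' @slot ids character record identifiers.
#' @slot sampleIds,binCenters labels carried over from the data.
#' @slot provenance list of sweep parameters.
#'
#' @seealso [runSweep()], [selectReliable()]
#' @exportClass ComponentPool
setClass("ComponentPool",
  representation(
    conc = "matrix",
    spec = "matrix",
    runK = "integer",
    indexInRun = "integer",
    ids = "character",
    sampleIds = "character",
    binCenters = "numeric",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("ComponentPool", function(object) {
  m <- nrow(object@conc)
  msg <- character()
  if (nrow(object@spec) != m || length(object@runK) != m ||
      length(object@indexInRun) != m || length(object@ids) != m)
    msg <- c(msg, "record counts of conc, spec, runK, indexInRun, ids must agree")
  if (ncol(object@conc) != length(object@sampleIds))
    msg <- c(msg, "ncol(conc) must equal length(sampleIds)")
  if (ncol(object@spec) != length(object@binCenters))
    msg <- c(msg, "ncol(spec) must equal length(binCenters)")
  if (length(object@conc) && min(object@conc) < 0)
    msg <- c(msg, "concentration profiles must be non-negative")
  if (length(object@spec) && min(object@spec) < 0)
    msg <- c(msg, "spectral profiles must be non-negative")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "record ids must be unique")
  if (length(msg)) msg else TRUE
})

#' AUClusterFit: average-linkage clustering with multiscale-bootstrap AU values
#'
#' Result of clustering pooled concentration profiles with a correlation
#' distance and UPGMA linkage, plus bootstrap probabilities (BP) at several
#' resampling scales and the approximately unbiased (AU) p-value of every
#' internal dendrogram node.
#'
#' @slot hclust the `stats::hclust` object of the observed data.
#' @slot labels leaf labels (record ids) in the row order of the clustered
#'   matrix.
#' @slot leafSets list of integer vectors; leaves under each internal node.
#' @slot bp numeric matrix, nodes x scales, bootstrap probabilities.
#' @slot au,fitV,fitC per-node AU p-value and fitted signed
#'   distance/curvature parameters.
#' @slot scales nominal resampling scales r.
#' @slot realizedScales realized scales `round(n * r) / n` used in the fit.
#' @slot nboot bootstrap replicates per scale.
#' @slot seed seed of the bootstrap stream.
#'
#' @seealso [auCluster()], [pickClusters()]
#' @exportClass AUClusterFit
setClass("AUClusterFit",
  representation(
    hclust = "list",
    labels = "character",
    leafSets = "list",
    bp = "matrix",
    au = "numeric",
    fitV = "numeric",
    fitC = "numeric",
    scales = "numeric",
    realizedScales = "numeric",
    nboot = "integer",
    seed = "integer"
  )
)

setValidity("AUClusterFit", function(object) {
  m <- length(object@leafSets)
  msg <- character()
  if (nrow(object@bp) != m || length(object@au) != m)
    msg <- c(msg, "bp and au must have one entry per internal node")
  if (length(object@bp) && (min(object@bp) < 0 || max(object@bp) > 1))
    msg <- c(msg, "bp values must lie in [0, 1]")
  okau <- object@au[is.finite(object@au)]
  if (length(okau) && (min(okau) < 0 || max(okau) > 1))
    msg <- c(msg, "au values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SizeThreshold: randomized-data cluster-size threshold
#'
#' The largest AU-selected cluster size observed across repeated clusterings
#' of randomly shuffled pools; a cluster of real data counts as reliable only
#' if its size is strictly greater than this value.
#'
#' @slot value the threshold (max over replicates).
#' @slot perReplicateMax largest selected-cluster size per replicate
#'   (0 when nothing was selected).
#' @slot nReplicates number of shuffle replicates.
#' @slot seed master seed.
#' @slot shuffleSeeds,bootSeeds,refineSeeds derived per-replicate seeds.
#' @slot alpha AU selection level used.
#'
#' @seealso [sizeThreshold()]
#' @exportClass SizeThreshold
setClass("SizeThreshold",
  representation(
    value = "integer",
    perReplicateMax = "integer",
    nReplicates = "integer",
    seed = "integer",
    shuffleSeeds = "integer",
    bootSeeds = "integer",
    refineSeeds = "integer",
    alpha = "numeric"
  )
)

setValidity("SizeThreshold", function(object) {
  msg <- character()
  if (length(object@perReplicateMax) != object@nReplicates)
    msg <- c(msg, "perReplicateMax must have one entry per replicate")
  if (length(object@perReplicateMax) &&
      object@value != max(object@perReplicateMax))
    msg <- c(msg, "value must equal max(perReplicateMax)")
  if (length(msg)) msg else TRUE
})

#' ReliableClusters: accepted clusters of reproducible components
#'
#' @slot clusters named list of character vectors of record ids; every
#'   accepted cluster exceeds the size threshold and has minimum internal
#'   pairwise concentration correlation above the cutoff.
#' @slot rejected data.frame with columns `clusterId`, `size`, `reason`
#'   (`"too_small"` or `"low_correlation_unresolvable"`).
#' @slot threshold the [SizeThreshold-class] used (or a bare integer wrapped
#'   in one).
#' @slot params list of selection parameters (alpha, corrMin, nboot, scales,
#'   seed).
#' @slot audit data.frame tracing refinement splits.
#'
#' @seealso [selectReliable()], [refineCluster()]
#' @exportClass ReliableClusters
setClass("ReliableClusters",
  representation(
    clusters = "list",
    rejected = "data.frame",
    threshold = "SizeThreshold",
    params = "list",
    audit = "data.frame"
  )
)

#' ClusterSummary: interpretable summary of one reliable cluster
#'
#' Each member component contributes the rank-one matrix
#' `concentration %o% spectrum` (C x St); the summary holds the element-wise
#' mean, standard deviation, and coefficient of variation across that stack,
#' the typical concentration and spectral profiles (the column and row of
#' the mean matrix through its global maximum), and the sum of squared
#' deviations (SSD) of the typical concentration profile.
#'
#' @slot clusterId cluster identifier.
#' @slot memberIds record ids of the member components.
#' @slot meanMatrix,sdMatrix,cvMatrix element-wise statistics of the
#'   samples x bins member stack.
#' @slot typicalConcentration,typicalSpectrum representative profiles.
#' @slot ssd sum of squared deviations of the typical concentration profile.
#' @slot sampleIds,binCenters labels.
#'
#' @seealso [summarizeClusters()], [detectionScore()]
#' @exportClass ClusterSummary
setClass("ClusterSummary",
  representation(
    clusterId = "character",
    memberIds = "character",
    meanMatrix = "matrix",
    sdMatrix = "matrix",
    cvMatrix = "matrix",
    typicalConcentration = "numeric",
    typicalSpectrum = "numeric",
    ssd = "numeric",
    sampleIds = "character",
    binCenters = "numeric"
  )
)

#' EigSpectrum: ordered eigenvalue spectrum of a data matrix
#'
#' Eigenvalues of the covariance (or correlation) matrix of the
#' column-centered data, as used by all number-of-components estimators.
#'
#' @slot values descending non-negative eigenvalues.
#' @slot standardized logical; `TRUE` when computed from the correlation
#'   matrix.
#' @slot nSamples,nVars dimensions of the source matrix.
#'
#' @seealso [eigSpectrum()], [estimateComponents()]
#' @exportClass EigSpectrum
setClass("EigSpectrum",
  representation(
    values = "numeric",
    standardized = "logical",
    nSamples = "integer",
    nVars = "integer"
  )
)

setValidity("EigSpectrum", function(object) {
  v <- object@values
  msg <- character()
  if (length(v) && min(v) < -1e-8) msg <- c(msg, "eigenvalues must be non-negative")
  if (length(v) > 1 && any(diff(v) > 1e-8))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: simulated mixture spectra with known ground truth
#'
#' @slot data the simulated [BinnedSpectra-class] (`true C x true St` plus
#'   truncated Gaussian noise).
#' @slot concentrations true samples x compounds concentration design.
#' @slot groups sample group labels.
#' @slot spectra true compounds x bins spectral profiles.
#' @slot noiseSd standard deviation of the additive noise.
#' @slot seed simulation seed.
#'
#' @seealso [simulateDataset()], [standardMixturePreset()]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(
    data = "BinnedSpectra",
    concentrations = "matrix",
    groups = "character",
    spectra = "matrix",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (nrow(object@concentrations) != nrow(object@data@values))
    msg <- c(msg, "concentration design must have one row per sample")
  if (ncol(object@concentrations) != nrow(object@spectra))
    msg <- c(msg, "design columns must match the compound library")
  if (ncol(object@spectra) != ncol(object@data@values))
    msg <- c(msg, "true spectra must be on the data's bin grid")
  if (length(object@concentrations) && min(object@concentrations) < 0)
    msg <- c(msg, "concentrations must be non-negative")
  if (length(object@spectra) && min(object@spectra) < 0)
    msg <- c(msg, "true spectra must be non-negative")
  if (length(msg)) msg else TRUE
})
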