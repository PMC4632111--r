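#' Component-number sweep: pool MCR-ALS components across all k
#'
#' Runs one MCR-ALS fit for every component number `k = 1, ..., kmax` and
#' pools all resulting components into one dataset of concentration (and
#' spectral) profiles. The raw pool holds exactly `kmax * (kmax + 1) / 2`
#' records (e.g. 210 for `kmax = 20`, 4005 for `kmax = 89`); with
#' `dropZeros = TRUE` components whose concentration or spectral column is
#' entirely zero are removed afterwards. The runs are independent and the
#' procedure is deterministic (PCA initialization with a fixed sign
#' convention, no randomness in the ALS).
#'
#' @param D a [BinnedSpectra-class] or non-negative numeric matrix.
#' @param kmax largest component number; defaults to the number of samples
#'   (the largest k for which PCA scores can initialize the fit).
#' @param tol,maxIter ALS parameters passed to [alsFit()].
#' @param dropZeros remove all-zero components after the sweep.
#' @param zeroTol zero tolerance for [dropZeroComponents()]; default
#'   `1e-12 * max(D)`.
#' @return A [ComponentPool-class]; its `provenance` records the sweep
#'   parameters and per-run convergence.
#' @export
#' @examples
#' d <- standardMixturePreset(nSamples = 12, seed = 1)
#' pool <- runSweep(d@data, kmax = 5)
#' nComponents(pool)  # <= 15, == 15 before zero-removal
runSweep <- function(D, kmax = NULL, tol = 1e-8, maxIter = 200,
                     dropZeros = TRUE, zeroTol = NULL) {
  d <- asDataMatrix(D)
  n <- nrow(d$values)
  if (is.null(kmax)) kmax <- n
  if (!is.numeric(kmax) || length(kmax) != 1 || kmax < 1 || kmax > n)
    stop("kmax must be between 1 and the number of samples")
  kmax <- as.integer(kmax)
  pools <- vector("list", kmax)
  conv <- logical(kmax)
  for (k in seq_len(kmax)) {
    fit <- tryCatch(
      mcrAls(d$values, k, tol = tol, maxIter = maxIter),
      error = function(e) stop(sprintf("MCR-ALS failed at k = %d: %s",
                                       k, conditionMessage(e)), call. = FALSE))
    conv[k] <- fit@converged
    fit@sampleIds <- d$sampleIds
    fit@binCenters <- d$binCenters
    pools[[k]] <- if (dropZeros) dropZeroComponents(fit, zeroTol)
                  else poolFromFit(fit)
  }
  pool <- bindPools(pools)
  pool@provenance <- list(kmax = kmax, tol = tol, maxIter = maxIter,
                          dropZeros = dropZeros,
                          rawCount = kmax * (kmax + 1L) / 2L,
                          converged = conv)
  pool
}

## rbind a list of ComponentPool objects sharing the same axes
bindPools <- function(pools) {
  pools <- pools[vapply(pools, nComponents, 0L) > 0]
  if (!length(pools)) stop("no components survived the sweep")
  first <- pools[[1]]
  new("ComponentPool",
      conc = do.call(rbind, lapply(pools, slot, "conc")),
      spec = do.call(rbind, lapply(pools, slot, "spec")),
      runK = do.call(c, lapply(pools, slot, "runK")),
      indexInRun = do.call(c, lapply(pools, slot, "indexInRun")),
      ids = do.call(c, lapply(pools, slot, "ids")),
      sampleIds = first@sampleIds,
      binCenters = first@binCenters,
      provenance = list())
}

#' Subset a component pool by record id
#'
#' @param pool a [ComponentPool-class].
#' @param ids character record ids to keep (order preserved).
#' @return A [ComponentPool-class] with the selected records.
#' @export
subsetPool <- function(pool, ids) {
  stopifnot(is(pool, "ComponentPool"))
  idx <- match(ids, pool@ids)
  if (anyNA(idx)) stop("unknown record id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  new("ComponentPool",
      conc = pool@conc[idx, , drop = FALSE],
      spec = pool@spec[idx, , drop = FALSE],
      runK = pool@runK[idx],
      indexInRun = pool@indexInRun[idx],
      ids = pool@ids[idx],
      sampleIds = pool@sampleIds,
      binCenters = pool@binCenters,
      provenance = pool@provenance)
}
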