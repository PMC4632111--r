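#' PCA-score initialization for the concentration matrix
#'
#' Returns the first `k` principal-component scores of the column-mean
#' centered data (no scaling), the conventional starting point for the
#' concentration matrix of an MCR-ALS fit. Each column's sign is fixed
#' deterministically: the column is flipped, if necessary, so that it
#' projects positively on the samples' total intensities (so the
#' initialization points toward, not away from, the non-negative data —
#' with the opposite orientation the first constrained half-step can
#' annihilate a component outright); columns orthogonal to the totals fall
#' back to making the largest-magnitude entry positive.
#'
#' @param D a [BinnedSpectra-class] or numeric samples x bins matrix.
#' @param k number of components, `1 <= k <= nrow(D)`.
#' @return numeric samples x k matrix of scores (may contain negatives).
#' @export
pcaScoresInit <- function(D, k) {
  d <- asDataMatrix(D)
  n <- nrow(d$values)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n)
    stop("k must be between 1 and the number of samples")
  k <- as.integer(k)
  pc <- prcomp(d$values, center = TRUE, scale. = FALSE)
  sc <- pc$x
  if (ncol(sc) < k) {
    sc <- cbind(sc, matrix(0, n, k - ncol(sc)))
  }
  sc <- sc[, seq_len(k), drop = FALSE]
  totals <- rowSums(d$values)
  for (j in seq_len(k)) {
    col <- sc[, j]
    if (any(col != 0)) {
      proj <- sum(col * totals)
      s <- if (abs(proj) > 1e-12 * max(abs(col)) * max(totals)) {
        sign(proj)
      } else {
        sign(col[which.max(abs(col))])
      }
      sc[, j] <- col * s
    }
  }
  unname(sc)
}

#' Non-negativity constrained alternating least squares
#'
#' Fits the bilinear model `D = C %*% t(S) + E` with `C >= 0`, `S >= 0` by
#' alternating exact non-negative least squares: solve S given C (one NNLS
#' problem per bin), then C given S (one per sample), until the relative
#' change of the residual sum of squares falls below `tol` or `maxIter`
#' alternations are reached. Because every subproblem is solved exactly,
#' the residual is non-increasing across iterations. The initial
#' concentration matrix may contain negative entries (PCA scores); the
#' first S-step absorbs them and all subsequent iterates are non-negative.
#'
#' @param D a [BinnedSpectra-class] or non-negative numeric matrix
#'   (samples x bins).
#' @param Cinit samples x k initial concentration matrix (e.g. from
#'   [pcaScoresInit()]).
#' @param Sinit bins x k initial spectral matrix; default all ones.
#' @param tol relative residual-change tolerance (default 1e-8).
#' @param maxIter maximum number of full alternations (default 200).
#' @return An [MCRFit-class].
#' @export
#' @examples
#' set.seed(1)
#' C0 <- matrix(runif(20), 10, 2); S0 <- matrix(runif(12), 6, 2)
#' fit <- alsFit(C0 %*% t(S0), pcaScoresInit(C0 %*% t(S0), 2))
#' fit@residualSSE
alsFit <- function(D, Cinit, Sinit = NULL, tol = 1e-8, maxIter = 200) {
  d <- asDataMatrix(D)
  X <- d$values
  if (!all(is.finite(X))) stop("D contains non-finite values")
  if (min(X) < 0) stop("D must be non-negative")
  Cinit <- as.matrix(Cinit)
  if (!all(is.finite(Cinit))) stop("Cinit contains non-finite values")
  k <- ncol(Cinit)
  if (k < 1) stop("at least one component is required (k = 0)")
  if (nrow(Cinit) != nrow(X))
    stop("Cinit must have one row per sample")
  if (is.null(Sinit)) Sinit <- matrix(1, ncol(X), k)
  Sinit <- as.matrix(Sinit)
  if (nrow(Sinit) != ncol(X) || ncol(Sinit) != k)
    stop("Sinit must be bins x k")
  res <- .alsEngine(X, Cinit, Sinit, tol, as.integer(maxIter))
  ## Class= named explicitly: a bare `C =` argument would partially match it
  new(Class = "MCRFit",
      C = res$C, S = res$S,
      residualSSE = res$residualSSE,
      sseTrace = as.numeric(res$sseTrace),
      nIter = as.integer(res$nIter),
      converged = isTRUE(res$converged),
      kRequested = as.integer(k),
      dataMax = max(X),
      sampleIds = d$sampleIds,
      binCenters = d$binCenters)
}

#' MCR-ALS with PCA-score initialization
#'
#' Convenience wrapper: [pcaScoresInit()] for the concentration matrix, all
#' ones for the spectral matrix, then [alsFit()].
#'
#' @inheritParams alsFit
#' @param k number of components.
#' @return An [MCRFit-class].
#' @export
mcrAls <- function(D, k, tol = 1e-8, maxIter = 200) {
  alsFit(D, pcaScoresInit(D, k), tol = tol, maxIter = maxIter)
}

#' Drop all-zero components from an MCR-ALS fit
#'
#' A component is dropped iff the largest absolute entry of its
#' concentration column or of its spectral column is at most `zeroTol`.
#' Survivors keep their original run size and within-run index.
#'
#' @param fit an [MCRFit-class].
#' @param zeroTol zero tolerance; default `1e-12 * max(D)`.
#' @return A [ComponentPool-class] holding the surviving components of this
#'   single run.
#' @export
dropZeroComponents <- function(fit, zeroTol = NULL) {
  stopifnot(is(fit, "MCRFit"))
  if (is.null(zeroTol)) zeroTol <- 1e-12 * fit@dataMax
  cmax <- apply(abs(fit@C), 2, max)
  smax <- apply(abs(fit@S), 2, max)
  keep <- which(cmax > zeroTol & smax > zeroTol)
  poolFromFit(fit, keep)
}

## Build a ComponentPool from (a subset of) one fit's components.
poolFromFit <- function(fit, keep = seq_len(ncol(fit@C))) {
  k <- fit@kRequested
  new("ComponentPool",
      conc = t(fit@C[, keep, drop = FALSE]),
      spec = t(fit@S[, keep, drop = FALSE]),
      runK = rep(k, length(keep)),
      indexInRun = as.integer(keep),
      ids = sprintf("k%d_c%d", k, keep),
      sampleIds = fit@sampleIds,
      binCenters = fit@binCenters,
      provenance = list())
}
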