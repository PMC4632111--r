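#' Eigenvalue spectrum of a data matrix
#'
#' Eigenvalues of the covariance (default) or correlation
#' (`standardize = TRUE`) matrix of the column-centered data, in descending
#' order — the shared input of the number-of-components estimators.
#'
#' @param D a [BinnedSpectra-class] or numeric samples x variables matrix.
#' @param standardize use the correlation matrix (unit-variance scaling).
#' @return An [EigSpectrum-class].
#' @export
eigSpectrum <- function(D, standardize = FALSE) {
  d <- asDataMatrix(D)
  X <- d$values
  if (nrow(X) < 2) stop("at least 2 samples are required")
  if (standardize) {
    v <- apply(X, 2, var)
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  new("EigSpectrum",
      values = as.numeric(pc$sdev^2),
      standardized = isTRUE(standardize),
      nSamples = nrow(X),
      nVars = ncol(X))
}

asEigValues <- function(spec) {
  if (is(spec, "EigSpectrum")) spec@values else as.numeric(spec)
}

#' Kaiser criterion
#'
#' Retains components with eigenvalue greater than 1.0. Meaningful on a
#' standardized (correlation-matrix) spectrum, where the average eigenvalue
#' is 1; a warning is issued otherwise.
#'
#' @param spec an [EigSpectrum-class] (or numeric eigenvalues).
#' @return integer count.
#' @export
kaiserRule <- function(spec) {
  if (is(spec, "EigSpectrum") && !spec@standardized)
    warning("Kaiser criterion expects a correlation-matrix (standardized) spectrum")
  sum(asEigValues(spec) > 1.0)
}

#' Horn's parallel analysis
#'
#' Compares the observed eigenvalue spectrum position-by-position to the
#' spectrum of size-matched random standard-normal matrices; the retained
#' count is the number of leading positions where the observed eigenvalue
#' exceeds the reference (the mean of the random eigenvalues by default, or
#' a quantile such as 0.95).
#'
#' @param D a [BinnedSpectra-class] or numeric matrix.
#' @param nRep random replicates (default 100).
#' @param probs `NULL` for the classic mean reference, or a single
#'   probability for a quantile reference.
#' @param standardize compare correlation-matrix spectra (default `TRUE`).
#' @param seed integer seed.
#' @return integer count of retained components.
#' @export
parallelAnalysis <- function(D, nRep = 100, probs = NULL,
                             standardize = TRUE, seed = 1) {
  if (nRep < 1) stop("nRep must be at least 1")
  d <- asDataMatrix(D)
  n <- nrow(d$values); p <- ncol(d$values)
  obs <- eigSpectrum(d$values, standardize = standardize)@values
  L <- length(obs)
  rand <- withSeed(seed, {
    vapply(seq_len(nRep), function(b) {
      R <- matrix(rnorm(n * p), n, p)
      ev <- eigSpectrum(R, standardize = standardize)@values
      length(ev) <- L
      ev
    }, numeric(L))
  })
  rand[is.na(rand)] <- 0
  ref <- if (is.null(probs)) rowMeans(rand)
         else apply(rand, 1, quantile, probs = probs)
  above <- obs > ref
  if (!above[1]) return(0L)
  fail <- which(!above)
  if (!length(fail)) L else as.integer(fail[1] - 1)
}

#' Cattell-Nelson-Gorsuch (CNG) test
#'
#' Slides a six-eigenvalue window over the spectrum: at each position the
#' slope of a line fitted to the first three eigenvalues is compared with
#' the slope fitted to the next three; the retained count corresponds to
#' the window with the largest slope change (window start + 2, the last
#' component before the scree flattens).
#'
#' @param spec an [EigSpectrum-class] (or numeric eigenvalues, >= 6).
#' @return integer count.
#' @export
cngTest <- function(spec) {
  ev <- asEigValues(spec)
  L <- length(ev)
  if (L < 6) stop("the CNG test needs at least 6 eigenvalues")
  slope3 <- function(y) {
    x <- seq_along(y)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  diffs <- vapply(seq_len(L - 5), function(i) {
    slope3(ev[(i + 3):(i + 5)]) - slope3(ev[i:(i + 2)])
  }, 0)
  as.integer(which.max(diffs) + 2L)
}

#' Multiple-regression (extended CNG) test
#'
#' For every candidate split point k, fits one regression line to the
#' leading eigenvalues (1..k) and one to the trailing ones (k+1..L) and
#' scores the split by the slope difference normalized by the pooled
#' residual standard error; the retained count is the argmax split.
#'
#' @param spec an [EigSpectrum-class] (or numeric eigenvalues, >= 6).
#' @return integer count.
#' @export
mregTest <- function(spec) {
  ev <- asEigValues(spec)
  L <- length(ev)
  if (L < 6) stop("the multiple-regression test needs at least 6 eigenvalues")
  idx <- seq_len(L)
  fitLine <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    a <- my - b * mx
    list(slope = b, rss = sum((y - a - b * x)^2), n = length(x))
  }
  ks <- 2:(L - 2)
  eps <- .Machine$double.eps
  scores <- vapply(ks, function(k) {
    f1 <- fitLine(idx[1:k], ev[1:k])
    f2 <- fitLine(idx[(k + 1):L], ev[(k + 1):L])
    df <- (f1$n - 2) + (f2$n - 2)
    se <- if (df > 0) sqrt((f1$rss + f2$rss) / df) else 0
    (f2$slope - f1$slope) / max(se, eps)
  }, 0)
  as.integer(ks[which.max(scores)])
}

#' Generalized cross-validation for the PCA rank
#'
#' For each rank k, `GCV(k) = RSS(k) / (n*p*(1 - df(k)/(n*p))^2)` with
#' `RSS(k)` the residual sum of squares of the rank-k reconstruction of the
#' centered data and `df(k) = p + k*(n + p - k - 1)` the degrees of freedom
#' of the rank-k PCA fit (column means plus scores and loadings, less the
#' rotational redundancy). Returns the argmin over `k = 0..kmax`.
#'
#' @param D a [BinnedSpectra-class] or numeric matrix.
#' @param kmax largest rank to consider; must be below `min(n, p)`.
#' @return integer rank estimate (possibly 0).
#' @export
gcvComponents <- function(D, kmax = NULL) {
  d <- asDataMatrix(D)
  X <- scale(d$values, center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  maxRank <- min(n - 1, p)
  if (is.null(kmax)) kmax <- maxRank - 1
  if (kmax < 1 || kmax >= min(n, p)) stop("kmax out of range")
  kmax <- min(kmax, maxRank)
  sv <- svd(X, nu = 0, nv = 0)$d
  tot <- sum(sv^2)
  rssk <- c(tot, tot - cumsum(sv^2))[seq_len(kmax + 1)]  # k = 0..kmax
  ks <- 0:kmax
  df <- p + ks * (n + p - ks - 1)
  ok <- df < n * p
  gcv <- rep(Inf, length(ks))
  gcv[ok] <- rssk[ok] / (n * p * (1 - df[ok] / (n * p))^2)
  as.integer(ks[which.min(gcv)])
}

#' Smoothing (approximate leave-one-out) rank selection
#'
#' An approximate-PRESS criterion: for each rank k the residuals of the
#' rank-k reconstruction are inflated by the approximate cell leverages
#' `h_ij = h_i + h_j - h_i * h_j` (row leverage from the scores including
#' the centering term, column leverage from the loadings), and the rank
#' minimizing the resulting sum of squared smoothed residuals is returned.
#'
#' @inheritParams gcvComponents
#' @return integer rank estimate (possibly 0).
#' @export
smoothComponents <- function(D, kmax = NULL) {
  d <- asDataMatrix(D)
  X <- scale(d$values, center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  maxRank <- min(n - 1, p)
  if (is.null(kmax)) kmax <- maxRank - 1
  if (kmax < 1 || kmax >= min(n, p)) stop("kmax out of range")
  kmax <- min(kmax, maxRank)
  sv <- svd(X)
  press <- numeric(kmax + 1)
  for (k in 0:kmax) {
    if (k == 0) {
      E <- X
      hr <- rep(1 / n, n)
      hc <- rep(0, p)
    } else {
      U <- sv$u[, seq_len(k), drop = FALSE]
      V <- sv$v[, seq_len(k), drop = FALSE]
      Dk <- U %*% (sv$d[seq_len(k)] * t(V))
      E <- X - Dk
      hr <- 1 / n + rowSums(U^2)
      hc <- rowSums(V^2)
    }
    H <- outer(hr, hc, function(a, b) a + b - a * b)
    H <- pmin(H, 0.99)
    press[k + 1] <- sum((E / (1 - H))^2)
  }
  as.integer(which.min(press) - 1L)
}

#' Cumulative contribution rate
#'
#' The smallest k whose cumulative eigenvalue share strictly exceeds
#' `level` (default 90%).
#'
#' @param spec an [EigSpectrum-class] (or numeric eigenvalues).
#' @param level contribution level in (0, 1].
#' @return integer count.
#' @export
cumulativeContribution <- function(spec, level = 0.90) {
  ev <- asEigValues(spec)
  tot <- sum(ev)
  if (tot <= 0) stop("spectrum has zero total variance")
  share <- cumsum(ev) / tot
  hit <- which(share > level)
  if (length(hit)) as.integer(hit[1]) else length(ev)
}

#' Scree table
#'
#' The eigenvalues paired with their component index, for external
#' plotting; the scree test itself is a visual judgement (the point before
#' the plot levels off) and is deliberately not automated.
#'
#' @param spec an [EigSpectrum-class] (or numeric eigenvalues).
#' @return data.frame with columns `component`, `eigenvalue`.
#' @export
screeTable <- function(spec) {
  ev <- asEigValues(spec)
  data.frame(component = seq_along(ev), eigenvalue = ev)
}

#' Run all conventional number-of-components estimators
#'
#' The eight-method comparison panel: Kaiser criterion, scree (exported as
#' a table; reported here via the acceleration factor, the largest drop in
#' slope, as a numeric stand-in for the visual judgement), parallel
#' analysis, CNG, multiple regression, generalized cross-validation,
#' smoothing-based cross-validation, and cumulative contribution.
#'
#' @param D a [BinnedSpectra-class] or numeric matrix.
#' @param kmax rank bound for the cross-validation criteria.
#' @param nRep,seed parallel-analysis parameters.
#' @param level cumulative-contribution level.
#' @return data.frame with columns `method` and `k`.
#' @export
estimateComponents <- function(D, kmax = NULL, nRep = 100, seed = 1,
                               level = 0.90) {
  d <- asDataMatrix(D)
  spec <- eigSpectrum(d$values, standardize = TRUE)
  specCov <- eigSpectrum(d$values, standardize = FALSE)
  scree <- if (length(spec@values) >= 3) {
    acc <- diff(diff(spec@values))
    as.integer(which.max(acc) + 1L)
  } else NA_integer_
  data.frame(
    method = c("kaiser", "scree_acceleration", "parallel_analysis", "cng",
               "multiple_regression", "cv_gcv", "cv_smooth",
               "cumulative_contribution"),
    k = c(kaiserRule(spec),
          scree,
          parallelAnalysis(d$values, nRep = nRep, seed = seed),
          cngTest(specCov),
          mregTest(specCov),
          gcvComponents(d$values, kmax),
          smoothComponents(d$values, kmax),
          cumulativeContribution(specCov, level)),
    stringsAsFactors = FALSE)
}
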