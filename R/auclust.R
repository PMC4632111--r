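#' Correlation-based distance matrix
#'
#' `d(i, j) = 1 - r(row_i, row_j)` with Pearson correlation across columns;
#' symmetric, zero diagonal, range `[0, 2]`. Rows with zero variance have
#' undefined correlations and are rejected.
#'
#' @param X numeric records x samples matrix (at least 2 rows).
#' @return records x records numeric distance matrix.
#' @export
correlationDistance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least 2 records are required")
  v <- apply(X, 1, var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad)) {
    ids <- rownames(X)[bad]
    if (is.null(ids)) ids <- as.character(bad)
    stop("constant record(s) have undefined correlation: ",
         paste(ids, collapse = ", "))
  }
  d <- 1 - cor(t(X))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Thin wrapper over `stats::hclust(..., method = "average")`: the distance
#' between two clusters is the unweighted mean of all cross-pair
#' dissimilarities. Deterministic for a given input.
#'
#' @param d distance matrix (full symmetric matrix or `dist` object).
#' @return A `stats::hclust` object.
#' @export
hclustAverage <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  hclust(d, method = "average")
}

## distance used inside bootstrap replicates: undefined correlations
## (a record constant within the replicate) get the maximal distance 2.
bootDistance <- function(X) {
  r <- suppressWarnings(cor(t(X)))
  r[!is.finite(r)] <- -1
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Multiscale bootstrap probabilities for dendrogram nodes
#'
#' For each scale `r`, draws `nboot` bootstrap datasets by resampling
#' `n' = round(n * r)` sample-columns of `X` with replacement (the sample is
#' the observation unit of a concentration profile), reclusters each with
#' the same correlation distance and UPGMA linkage, and records for every
#' internal node of the observed dendrogram the fraction of bootstrap trees
#' containing its exact leaf set (the bootstrap probability, BP). Records
#' that become constant within a replicate are handled by assigning the
#' maximal distance 2 to their pairs for that replicate.
#'
#' @param X numeric records x samples matrix.
#' @param scales numeric vector of resampling scales `r > 0`; scales with
#'   `round(n * r) < 2` are dropped with a warning.
#' @param nboot bootstrap replicates per scale (>= 1).
#' @param seed integer seed; the replicate stream is drawn sequentially
#'   from this seed, so results are reproducible.
#' @return list with `tree` (observed `hclust`), `leafSets`, `bp`
#'   (nodes x scales matrix), `scales` (nominal), `realizedScales`
#'   (`round(n*r)/n`), and `nboot`.
#' @export
multiscaleBootstrap <- function(X, scales = seq(0.5, 1.4, by = 0.1),
                                nboot = 1000, seed = 1) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (nboot < 1) stop("nboot must be at least 1")
  if (any(scales <= 0)) stop("scales must be positive")
  nPrime <- round(n * scales)
  usable <- nPrime >= 2
  if (!any(usable)) stop("every scale yields fewer than 2 resampled columns")
  if (!all(usable)) {
    warning(sprintf("dropping %d scale(s) with fewer than 2 resampled columns",
                    sum(!usable)))
    scales <- scales[usable]
    nPrime <- nPrime[usable]
  }
  tree <- hclustAverage(correlationDistance(X))
  refSigs <- .treeSignatures(tree$merge)
  leafSets <- .treeLeafSets(tree$merge)
  counts <- matrix(0L, length(refSigs), length(scales))
  withSeed(seed, {
    for (si in seq_along(scales)) {
      np <- nPrime[si]
      for (b in seq_len(nboot)) {
        idx <- sample.int(n, np, replace = TRUE)
        hb <- hclust(as.dist(bootDistance(X[, idx, drop = FALSE])),
                     method = "average")
        hit <- refSigs %in% .treeSignatures(hb$merge)
        counts[, si] <- counts[, si] + hit
      }
    }
  })
  bp <- counts / nboot
  colnames(bp) <- sprintf("r%.2f", scales)
  list(tree = tree, leafSets = leafSets, bp = bp, scales = scales,
       realizedScales = nPrime / n, nboot = as.integer(nboot))
}

#' Approximately unbiased p-value from multiscale bootstrap probabilities
#'
#' Transforms the interior bootstrap probabilities (`0 < BP < 1`) to
#' `z_r = qnorm(1 - BP_r)`, fits `z_r ~ v * sqrt(r) + c / sqrt(r)` by least
#' squares weighted with the (delta-method) binomial variance of each BP,
#' and returns `AU = 1 - pnorm(v - c)` together with the fitted signed
#' distance `v` and curvature `c`. Scales where BP is exactly 0 or 1 carry
#' no curve information and are excluded from the fit. The two-parameter
#' fit is only attempted when it has positive residual degrees of freedom,
#' i.e. at least three interior scales; with fewer the node is degenerate
#' and AU is 1 (present in essentially every bootstrap tree) or 0
#' (essentially never), by the sign of the mean BP. Without this guard an
#' exact two-point fit can extrapolate a node with near-zero support at
#' every scale to AU = 1. BP values entering the fit are additionally
#' capped into `[1/(nboot+1), nboot/(nboot+1)]`.
#'
#' @param bp numeric vector of bootstrap probabilities, one per scale, or a
#'   nodes x scales matrix.
#' @param scales resampling scales (use the realized scales `round(n*r)/n`).
#' @param nboot bootstrap replicates per scale.
#' @return For a vector: named numeric `c(au, v, c)`. For a matrix: a
#'   data.frame with columns `au`, `v`, `c`, one row per node.
#' @export
#' @examples
#' auFromBp(rep(0.5, 10), seq(0.5, 1.4, 0.1), nboot = 1000)[["au"]]  # 0.5
auFromBp <- function(bp, scales, nboot) {
  if (is.matrix(bp)) {
    out <- t(apply(bp, 1, auFromBp, scales = scales, nboot = nboot))
    return(data.frame(au = out[, "au"], v = out[, "v"], c = out[, "c"]))
  }
  if (length(bp) != length(scales))
    stop("bp and scales must have equal length")
  ok <- is.finite(bp) & bp > 0 & bp < 1
  if (sum(ok) < 3) {
    ## degenerate: the node is (almost) always or (almost) never observed,
    ## so the scale curve carries no information. A node observed in every
    ## bootstrap tree at (nearly) every scale is maximally supported.
    known <- bp[is.finite(bp)]
    if (!length(known)) return(c(au = NA_real_, v = NA_real_, c = NA_real_))
    au <- if (mean(known) >= 0.5) 1 else 0
    return(c(au = au, v = NA_real_, c = NA_real_))
  }
  lo <- 1 / (nboot + 1)
  r <- scales[ok]
  b <- pmin(pmax(bp[ok], lo), 1 - lo)
  z <- qnorm(1 - b)
  M <- cbind(sqrt(r), 1 / sqrt(r))
  w <- dnorm(z)^2 * nboot / (b * (1 - b))
  fit <- lm.wfit(M, z, w)
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  if (!is.finite(v) || !is.finite(cc))
    return(c(au = NA_real_, v = NA_real_, c = NA_real_))
  c(au = 1 - pnorm(v - cc), v = v, c = cc)
}

#' Cluster pooled concentration profiles with AU p-values
#'
#' End-to-end clustering step: correlation distance on the pooled
#' concentration profiles, UPGMA dendrogram, multiscale bootstrap BP at
#' each scale, and the AU p-value of every internal node.
#'
#' @param pool a [ComponentPool-class], or a numeric records x samples
#'   matrix with row names as record ids.
#' @param scales resampling scales (default `seq(0.5, 1.4, 0.1)`).
#' @param nboot bootstrap replicates per scale (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An [AUClusterFit-class].
#' @export
auCluster <- function(pool, scales = seq(0.5, 1.4, by = 0.1),
                      nboot = 1000, seed = 1) {
  X <- if (is(pool, "ComponentPool")) concProfiles(pool) else as.matrix(pool)
  if (is.null(rownames(X))) rownames(X) <- paste0("r", seq_len(nrow(X)))
  mb <- multiscaleBootstrap(X, scales = scales, nboot = nboot, seed = seed)
  fitTab <- auFromBp(mb$bp, mb$realizedScales, mb$nboot)
  new("AUClusterFit",
      hclust = unclass(mb$tree),
      labels = rownames(X),
      leafSets = mb$leafSets,
      bp = mb$bp,
      au = fitTab$au,
      fitV = fitTab$v,
      fitC = fitTab$c,
      scales = mb$scales,
      realizedScales = mb$realizedScales,
      nboot = mb$nboot,
      seed = as.integer(seed))
}

#' Pick significant, non-nested clusters
#'
#' Selects the internal dendrogram nodes with `AU > alpha`. The root (the
#' full leaf set, which is contained in every bootstrap tree by
#' construction) is never a candidate. With `maxOnly = TRUE`, nested
#' selections are resolved by keeping only the maximal cluster, so the
#' returned leaf sets are pairwise disjoint. Singletons are never returned
#' (leaves are not internal nodes).
#'
#' @param fit an [AUClusterFit-class].
#' @param alpha AU threshold (default 0.95; selection is strict, `AU > alpha`).
#' @param maxOnly keep only maximal clusters among nested selections.
#' @return list of character vectors of leaf labels (possibly empty), named
#'   by dendrogram node index.
#' @export
pickClusters <- function(fit, alpha = 0.95, maxOnly = TRUE) {
  stopifnot(is(fit, "AUClusterFit"))
  m <- length(fit@leafSets)
  if (m == 0) return(list())
  nLeaves <- length(fit@labels)
  sizes <- lengths(fit@leafSets)
  cand <- which(!is.na(fit@au) & fit@au > alpha & sizes < nLeaves)
  if (!length(cand)) return(list())
  if (maxOnly) {
    ## among UPGMA nodes, two leaf sets are either nested or disjoint;
    ## drop any selected node contained in a larger selected node
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
      si <- fit@leafSets[[cand[i]]]
      keep[i] <- !any(vapply(cand[-i], function(j) {
        sj <- fit@leafSets[[j]]
        length(sj) > length(si) && all(si %in% sj)
      }, TRUE))
    }
    cand <- cand[keep]
  }
  out <- lapply(cand, function(i) fit@labels[fit@leafSets[[i]]])
  names(out) <- as.character(cand)
  out
}
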