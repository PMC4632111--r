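# Shared fixtures, all generated in code.

# Small exact bilinear dataset: k well-separated non-negative components.
# Spectra occupy disjoint blocks of the variable axis and each
# concentration column has a few true zeros, so the factorization is
# essentially unique (well-conditioned in the MCR sense).
makeBilinear <- function(n = 10, p = 40, k = 3, seed = 1, noiseSd = 0) {
  set.seed(seed)
  C <- matrix(rlnorm(n * k, sdlog = 0.7), n, k)
  for (j in seq_len(k)) {
    C[sample.int(n, max(2, round(n / 4))), j] <- 0
  }
  # guard against degenerate all-zero rows/columns
  C[1, ] <- pmax(C[1, ], 0.5)
  S <- matrix(0, p, k)
  block <- floor(p / k)
  for (j in seq_len(k)) {
    lo <- (j - 1) * block + 2
    nBumps <- if (block >= 8) 2 else 1
    centers <- lo + sample.int(max(block - 3, 1), nBumps)
    for (ct in centers) {
      S[, j] <- S[, j] + exp(-((seq_len(p) - ct)^2) / 6)
    }
  }
  D <- C %*% t(S)
  if (noiseSd > 0) D <- pmax(D + matrix(rnorm(n * p, sd = noiseSd), n, p), 0)
  list(D = D, C = C, S = S)
}

# Rows with planted block structure for clustering tests:
# `sizes` blocks, each a noisy copy of its own base profile.
makeBlocks <- function(sizes, nSamples = 15, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    base <- rnorm(nSamples)
    t(vapply(seq_len(sizes[b]), function(i) base + rnorm(nSamples, sd = sd),
             numeric(nSamples)))
  }))
  rownames(X) <- paste0("r", seq_len(nrow(X)))
  X
}

# Brute-force UPGMA oracle: literal average-linkage agglomeration on the
# original dissimilarities, O(n^3), independent of stats::hclust.
upgmaOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  heights <- numeric(n - 1)
  avgDist <- function(a, b) mean(d[a, b])
  current <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(current)) {
      for (j in seq_len(i - 1)) {
        dd <- avgDist(members[[current[i]]], members[[current[j]]])
        if (dd < bestD) { bestD <- dd; best <- c(current[j], current[i]) }
      }
    }
    newId <- n + step
    members[[newId]] <- sort(c(members[[best[1]]], members[[best[2]]]))
    heights[step] <- bestD
    current <- c(setdiff(current, best), newId)
  }
  heights
}

# Build a tiny ComponentPool directly from a profile matrix (records x samples).
poolFromMatrix <- function(X, spec = NULL) {
  m <- nrow(X); n <- ncol(X)
  if (is.null(spec)) spec <- matrix(1, m, 4)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("k1_c", seq_len(m))
  new("ComponentPool",
      conc = unname(as.matrix(X)), spec = spec,
      runK = rep(1L, m), indexInRun = seq_len(m), ids = ids,
      sampleIds = paste0("s", seq_len(n)),
      binCenters = as.numeric(seq_len(ncol(spec))),
      provenance = list())
}
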