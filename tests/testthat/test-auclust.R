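test_that("correlation distance matches the pairwise formula", {
  set.seed(11)
  X <- matrix(rnorm(50), 5, 10)
  d <- correlationDistance(X)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], 1 - cor(X[i, ], X[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(d), rep(0, 5))
  expect_equal(d, t(d))
  # identical rows -> 0, anti-correlated rows -> 2
  Y <- rbind(1:10, 1:10, 10:1)
  dy <- correlationDistance(Y)
  expect_equal(dy[1, 2], 0)
  expect_equal(dy[1, 3], 2)
  # constant rows are rejected by id
  Z <- rbind(a = rnorm(10), b = rep(1, 10))
  expect_error(correlationDistance(Z), "b")
  expect_error(correlationDistance(X[1, , drop = FALSE]), "at least 2")
})

test_that("UPGMA reproduces a forced merge order", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hclustAverage(d)
  expect_equal(hc$height, c(1, 4))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
})

test_that("UPGMA merge heights match a brute-force oracle on random instances", {
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(6 * 8), 6, 8)
    d <- correlationDistance(X)
    hc <- hclustAverage(d)
    expect_equal(hc$height, upgmaOracle(d), tolerance = 1e-10,
                 info = paste("case", s))
  }
})

test_that("UPGMA with tied distances is reproducible", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  a <- hclustAverage(d)
  b <- hclustAverage(d)
  expect_identical(a$merge, b$merge)
  expect_equal(a$height, rep(1, 3))
})

test_that("bootstrap probabilities separate planted groups", {
  X <- makeBlocks(c(5, 5), nSamples = 15, sd = 0.1, seed = 12)
  mb <- multiscaleBootstrap(X, nboot = 200, seed = 5)
  sizes <- lengths(mb$leafSets)
  groupNodes <- which(sizes == 5)
  expect_length(groupNodes, 2)
  for (g in groupNodes) {
    expect_true(all(mb$bp[g, ] >= 0.95))
  }
})

test_that("bootstrap contracts: shapes, single-draw BP, reproducibility", {
  X <- makeBlocks(c(3, 3), nSamples = 10, sd = 0.2, seed = 13)
  # nboot = 1: every BP is 0 or 1
  mb1 <- multiscaleBootstrap(X, nboot = 1, seed = 1)
  expect_true(all(mb1$bp %in% c(0, 1)))
  # at r = 1 the resampled dataset keeps all records (shape contract)
  mbr1 <- multiscaleBootstrap(X, scales = 1, nboot = 5, seed = 1)
  expect_equal(nrow(mbr1$bp), nrow(X) - 1)  # one BP per internal node
  expect_equal(mbr1$realizedScales, 1)
  # same seed -> identical BP tables
  a <- multiscaleBootstrap(X, nboot = 20, seed = 7)
  b <- multiscaleBootstrap(X, nboot = 20, seed = 7)
  expect_identical(a$bp, b$bp)
  # scales yielding n' < 2 are dropped with a warning
  expect_warning(multiscaleBootstrap(X, scales = c(0.05, 1), nboot = 5,
                                     seed = 1), "fewer than 2")
})

test_that("AU is exactly 0.5 when BP is 0.5 at every scale", {
  r <- seq(0.5, 1.4, by = 0.1)
  out <- auFromBp(rep(0.5, 10), r, nboot = 1000)
  expect_equal(out[["au"]], 0.5)
  expect_equal(out[["v"]], 0, tolerance = 1e-12)
  expect_equal(out[["c"]], 0, tolerance = 1e-12)
})

test_that("the weighted fit recovers synthesized (v, c) pairs", {
  r <- seq(0.5, 1.4, by = 0.1)
  for (vc in list(c(0.7, 0.3), c(-0.5, 0.4), c(1.2, -0.2), c(0.1, 0.9))) {
    a <- vc[1]; b <- vc[2]
    bp <- pnorm(-(a * sqrt(r) + b / sqrt(r)))
    out <- auFromBp(bp, r, nboot = 10000)
    expect_equal(out[["v"]], a, tolerance = 0.02)
    expect_equal(out[["c"]], b, tolerance = 0.02)
    expect_equal(out[["au"]], 1 - pnorm(a - b), tolerance = 0.02)
  }
})

test_that("saturated BP values give extreme, finite AU", {
  r <- seq(0.5, 1.4, by = 0.1)
  top <- auFromBp(rep(1, 10), r, nboot = 100)
  expect_true(is.finite(top[["au"]]))
  expect_gte(top[["au"]], 0.99)
  bottom <- auFromBp(rep(0, 10), r, nboot = 100)
  expect_equal(bottom[["au"]], 0)
  # no finite values at all: AU undefined
  expect_true(is.na(auFromBp(c(NA_real_, NA_real_), c(0.5, 1), 100)[["au"]]))
  # a single interior scale is degenerate: AU collapses to 0 or 1
  expect_equal(auFromBp(c(NA, 0.6), c(0.5, 1), 100)[["au"]], 1)
  expect_equal(auFromBp(c(NA, 0.3), c(0.5, 1), 100)[["au"]], 0)
})

test_that("lowering every BP lowers AU (monotonicity of the fit)", {
  r <- seq(0.5, 1.4, by = 0.1)
  bp <- pnorm(-(0.3 * sqrt(r) - 0.2 / sqrt(r)))
  auHigh <- auFromBp(bp, r, 1000)[["au"]]
  auLow <- auFromBp(pnorm(qnorm(bp) - 0.3), r, 1000)[["au"]]
  expect_lt(auLow, auHigh)
})

test_that("cluster picking prefers maximal nested clusters and stays disjoint", {
  X <- makeBlocks(c(4, 4, 3), nSamples = 20, sd = 0.08, seed = 14)
  fit <- auCluster(X, nboot = 200, seed = 3)
  picks <- pickClusters(fit, alpha = 0.95, maxOnly = TRUE)
  # pairwise disjoint
  all <- unlist(picks)
  expect_equal(anyDuplicated(all), 0)
  # no singletons, never the full set
  expect_true(all(lengths(picks) >= 2))
  expect_true(all(lengths(picks) < nrow(X)))
  # maxOnly: no selected set is contained in another selected set
  if (length(picks) > 1) {
    for (i in seq_along(picks)) for (j in seq_along(picks)) {
      if (i != j) expect_false(all(picks[[i]] %in% picks[[j]]))
    }
  }
  # planted blocks are recovered exactly
  expect_setequal(
    lapply(picks, sort),
    list(sort(paste0("r", 1:4)), sort(paste0("r", 5:8)),
         sort(paste0("r", 9:11))))
  # alpha above every AU -> empty
  expect_length(pickClusters(fit, alpha = 1), 0)
})
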