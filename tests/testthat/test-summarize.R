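test_that("member products are outer products reconstructing the run fit", {
  pool <- poolFromMatrix(rbind(a = c(1, 2), b = c(2, 1)),
                         spec = rbind(c(3, 0, 1), c(0, 1, 2)))
  expect_equal(unname(memberProduct(pool, "a")),
               rbind(c(3, 0, 1), c(6, 0, 2)))
  # zero spectrum -> zero matrix
  poolz <- poolFromMatrix(rbind(a = c(1, 2)), spec = rbind(c(0, 0, 0)))
  expect_equal(unname(memberProduct(poolz, "a")), matrix(0, 2, 3))
  expect_error(memberProduct(pool, "nope"), "unknown record")

  # sum of member products over one full run equals that run's C St
  bl <- makeBilinear(n = 8, p = 20, k = 3, seed = 21)
  sweep <- runSweep(bl$D, kmax = 3, dropZeros = FALSE)
  run3 <- subsetPool(sweep, sweep@ids[sweep@runK == 3])
  total <- Reduce(`+`, lapply(run3@ids, function(id) memberProduct(run3, id)))
  fit <- mcrAls(bl$D, 3)
  expect_equal(unname(total), fit@C %*% t(fit@S), tolerance = 1e-10)
})

test_that("cluster statistics match hand and brute-force values", {
  m1 <- matrix(1, 2, 3); m3 <- matrix(3, 2, 3)
  st <- clusterStats(list(m1, m3))
  expect_equal(st$mean, matrix(2, 2, 3))
  expect_equal(st$sd, matrix(sqrt(2), 2, 3))
  expect_equal(st$cv, matrix(sqrt(2) / 2, 2, 3))
  # identical members -> cv all zero; single member -> sd 0
  expect_equal(clusterStats(list(m1, m1))$cv, matrix(0, 2, 3))
  expect_equal(clusterStats(list(m3))$sd, matrix(0, 2, 3))
  # random stack vs direct per-cell computation
  set.seed(22)
  stack <- lapply(1:4, function(i) matrix(runif(12), 3, 4))
  st2 <- clusterStats(stack)
  for (r in 1:3) for (cc in 1:4) {
    cell <- vapply(stack, function(m) m[r, cc], 0)
    expect_equal(st2$mean[r, cc], mean(cell))
    expect_equal(st2$sd[r, cc], sd(cell))
    expect_equal(st2$cv[r, cc], sd(cell) / mean(cell))
  }
})

test_that("typical profiles are the row and column through the global maximum", {
  m <- matrix(0, 3, 4)
  m[2, 3] <- 5
  tp <- typicalProfiles(m)
  expect_equal(tp$typicalSpectrum, m[2, ])
  expect_equal(tp$typicalConcentration, m[, 3])
  # rank-1 outer product: profiles proportional to the factors
  a <- c(1, 3, 2); b <- c(2, 1, 4, 1)
  tp2 <- typicalProfiles(a %o% b)
  expect_equal(tp2$typicalSpectrum / max(tp2$typicalSpectrum), b / max(b))
  expect_equal(tp2$typicalConcentration / max(tp2$typicalConcentration),
               a / max(a))
  # random matrix with unique max agrees with exhaustive argmax
  set.seed(23)
  r <- matrix(runif(30), 5, 6)
  pos <- which(r == max(r), arr.ind = TRUE)
  tp3 <- typicalProfiles(r)
  expect_equal(tp3$typicalSpectrum, r[pos[1], ])
  expect_equal(tp3$typicalConcentration, r[, pos[2]])
  # row-major tie break: first occurrence
  tie <- matrix(c(0, 7, 7, 0), 2, 2)  # max at (2,1) and (1,2)
  tpt <- typicalProfiles(tie)
  expect_equal(tpt$position, c(row = 1L, col = 2L))
  expect_error(typicalProfiles(matrix(0, 2, 2)), "no positive")
})

test_that("SSD follows the variance identity and its invariances", {
  expect_equal(clusterSSD(c(5, 5, 5)), 0)
  expect_equal(clusterSSD(c(0, 2)), 2)
  set.seed(24)
  x <- rnorm(17)
  expect_equal(clusterSSD(x), 16 * var(x))
  expect_equal(clusterSSD(x + 3), clusterSSD(x))
  expect_equal(clusterSSD(2 * x), 4 * clusterSSD(x))
})

test_that("detection scoring applies the correlation > 0.8 rule", {
  set.seed(25)
  n <- 10
  known <- cbind(a = rlnorm(n), b = rlnorm(n), flat = rep(1, n))
  pool <- poolFromMatrix(rbind(k1_c1 = known[, "a"] + 0.001,
                               k1_c2 = abs(rnorm(n))),
                         spec = matrix(c(1, 0, 0, 1), 2, 2))
  sm <- summarizeClusters(pool, list(A = "k1_c1", B = "k1_c2"))
  ds <- detectionScore(sm, known)
  expect_equal(ds$detected[ds$compound == "a"], TRUE)
  expect_gt(ds$bestCorrelation[ds$compound == "a"], 0.999)
  # constant series: missing
  expect_true(is.na(ds$bestCorrelation[ds$compound == "flat"]))
  expect_true(is.na(ds$detected[ds$compound == "flat"]))
  # no clusters at all: nothing detected
  ds0 <- detectionScore(list(), known)
  expect_true(all(!ds0$detected))
})

test_that("summaries expose cluster size, SSD ranking, and top bins", {
  X <- makeBlocks(c(3, 3), nSamples = 8, sd = 0.05, seed = 26)
  pool <- poolFromMatrix(abs(X) + 0.01,
                         spec = matrix(runif(6 * 5), 6, 5))
  sm <- summarizeClusters(pool, list(c1 = rownames(X)[1:3],
                                     c2 = rownames(X)[4:6]))
  expect_named(sm, c("c1", "c2"))
  tab <- summaryTable(sm, topBins = 2)
  expect_equal(sort(tab$clusterId), c("c1", "c2"))
  expect_equal(tab$size, c(3, 3))
  expect_equal(tab$ssd, sort(tab$ssd, decreasing = TRUE))
  # cv is scale-invariant under joint rescaling of all members
  pool2 <- pool
  pool2@conc <- pool@conc * 7
  sm2 <- summarizeClusters(pool2, list(c1 = rownames(X)[1:3]))
  expect_equal(sm2$c1@cvMatrix, sm$c1@cvMatrix, tolerance = 1e-12)
})
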