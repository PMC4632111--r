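test_that("shuffling preserves each profile's values but destroys correlation", {
  X <- makeBlocks(c(6, 6), nSamples = 20, sd = 0.05, seed = 15)
  pool <- poolFromMatrix(abs(X))
  sh <- shuffleProfiles(pool, seed = 2)
  # multiset conservation per record
  for (i in seq_len(nComponents(pool))) {
    expect_equal(sort(sh@conc[i, ]), sort(pool@conc[i, ]))
  }
  # two identical records generally diverge after shuffling
  pool2 <- poolFromMatrix(rbind(a = abs(X[1, ]), b = abs(X[1, ])))
  sh2 <- shuffleProfiles(pool2, seed = 3)
  expect_false(identical(sh2@conc[1, ], sh2@conc[2, ]))
  # planted structure: mean |correlation| collapses
  before <- abs(cor(t(pool@conc)))
  after <- abs(cor(t(sh@conc)))
  expect_lt(mean(after[upper.tri(after)]),
            0.5 * mean(before[upper.tri(before)]))
  # reproducible
  expect_identical(shuffleProfiles(pool, seed = 2)@conc, sh@conc)
})

test_that("the size threshold is the max over replicate maxima", {
  X <- makeBlocks(c(4, 4), nSamples = 12, sd = 0.3, seed = 16)
  pool <- poolFromMatrix(abs(X) + 0.1)
  th <- sizeThreshold(pool, nReplicates = 3, seed = 5, nboot = 50)
  expect_s4_class(th, "SizeThreshold")
  expect_equal(th@value, max(th@perReplicateMax))
  expect_length(th@perReplicateMax, 3)
  # deterministic given the seed
  th2 <- sizeThreshold(pool, nReplicates = 3, seed = 5, nboot = 50)
  expect_identical(th@perReplicateMax, th2@perReplicateMax)
})

test_that("refinement accepts coherent clusters and splits mixed ones", {
  # two planted blocks glued into one candidate cluster
  X <- makeBlocks(c(5, 5), nSamples = 20, sd = 0.05, seed = 17)
  pool <- poolFromMatrix(abs(X) + 0.05)
  ids <- componentIds(pool)

  # coherent subset: accepted unchanged
  res <- refineCluster(ids[1:5], pool, corrMin = 0.6, threshold = 2,
                       nboot = 100, seed = 1)
  expect_length(res$accepted, 1)
  expect_setequal(res$accepted[[1]], ids[1:5])

  # mixed cluster: split into the two blocks
  res2 <- refineCluster(ids, pool, corrMin = 0.6, threshold = 2,
                        nboot = 100, seed = 1)
  expect_length(res2$accepted, 2)
  expect_setequal(lapply(res2$accepted, sort),
                  list(sort(ids[1:5]), sort(ids[6:10])))
  expect_true(any(res2$audit$action == "split"))

  # low-correlation pair that cannot be subdivided is discarded with reason
  pair <- poolFromMatrix(rbind(a = abs(rnorm(20)) + 0.01,
                               b = abs(rnorm(20)) + 0.01))
  res3 <- refineCluster(c("a", "b"), pair, corrMin = 0.99, threshold = 0,
                        nboot = 50, seed = 1)
  expect_length(res3$accepted, 0)
  expect_equal(res3$rejected$reason, "low_correlation_unresolvable")

  # clusters at or below the threshold are rejected as too small
  res4 <- refineCluster(ids[1:3], pool, corrMin = 0.6, threshold = 3,
                        nboot = 50, seed = 1)
  expect_length(res4$accepted, 0)
  expect_equal(res4$rejected$reason, "too_small")
})

test_that("accepted clusters obey the reliability invariants", {
  X <- makeBlocks(c(6, 6, 5), nSamples = 20, sd = 0.08, seed = 18)
  pool <- poolFromMatrix(abs(X) + 0.05)
  rc <- selectReliable(pool, nboot = 100, nShuffle = 3, seed = 4)
  cl <- reliableClusters(rc)
  thr <- rc@threshold@value
  # disjoint
  expect_equal(anyDuplicated(unlist(cl)), 0)
  for (ids in cl) {
    expect_gt(length(ids), thr)
    M <- pool@conc[match(ids, pool@ids), , drop = FALSE]
    expect_gt(min(cor(t(M))), 0.6)
  }
})

test_that("corrMin = -1 disables refinement", {
  X <- makeBlocks(c(5, 4), nSamples = 15, sd = 0.2, seed = 19)
  pool <- poolFromMatrix(abs(X) + 0.05)
  rc <- selectReliable(pool, corrMin = -1, nboot = 100, nShuffle = 2,
                       seed = 6)
  # every accepted cluster equals a picked cluster above the threshold:
  # with refinement disabled nothing is ever split
  expect_true(all(rc@audit$action != "split"))
  expect_true(all(vapply(reliableClusters(rc), length, 0L) >
                  rc@threshold@value))
})

test_that("a pre-supplied integer threshold larger than all clusters empties the result", {
  X <- makeBlocks(c(4, 4), nSamples = 15, sd = 0.1, seed = 20)
  pool <- poolFromMatrix(abs(X) + 0.05)
  rc <- selectReliable(pool, threshold = 50, nboot = 100, seed = 7)
  expect_length(reliableClusters(rc), 0)
  expect_true(all(rc@rejected$reason == "too_small"))
})
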