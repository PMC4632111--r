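test_that("binning 0-10 ppm yields the standard 250 and 500 variable layouts", {
  sp <- data.frame(ppm = seq(0.001, 9.999, by = 0.002), intensity = 1)
  expect_length(binSpectrum(sp, 0.04, c(0, 10))$values, 250)
  expect_length(binSpectrum(sp, 0.02, c(0, 10))$values, 500)
})

test_that("bin values are sums of the points falling in each half-open bin", {
  # 10 evenly spaced unit points per 0.1-wide bin
  sp <- data.frame(ppm = seq(0.005, 0.995, by = 0.01), intensity = 1)
  b <- binSpectrum(sp, 0.1, c(0, 1))
  expect_equal(b$values, rep(10, 10))
  # total intensity conserved over the covered range
  expect_equal(sum(b$values), sum(sp$intensity))
  # a point exactly on an interior edge belongs to the right-hand bin
  sp2 <- data.frame(ppm = c(0.05, 0.1, 0.15), intensity = c(1, 2, 4))
  b2 <- binSpectrum(sp2, 0.1, c(0, 0.2))
  expect_equal(b2$values, c(1, 6))
})

test_that("binning rejects bad input", {
  sp <- data.frame(ppm = c(1, 2), intensity = c(1, 1))
  expect_error(binSpectrum(sp, 0, c(0, 10)), "positive")
  expect_error(binSpectrum(sp, 0.1, c(5, 6)), "no spectral points")
  expect_error(binSpectrum(data.frame(ppm = c(1, 1, 2), intensity = 1:3),
                           0.1, c(0, 3)), "monotone")
})

test_that("region exclusion removes exactly the bins whose centers fall inside", {
  vals <- matrix(1, 2, 250)
  centers <- seq(0.02, by = 0.04, length.out = 250)
  bs <- BinnedSpectra(vals, centers)
  # oracle: enumerate centers and apply the closed-interval rule directly
  regions <- defaultExclusionRegions("urine")
  inside <- (centers >= 0 & centers <= 0.277) |
            (centers >= 4.5 & centers <= 6.25)
  out <- excludeRegions(bs, regions)
  expect_equal(length(binCenters(out)), sum(!inside))
  expect_equal(binCenters(out), centers[!inside])
  # no regions -> identity
  expect_equal(binCenters(excludeRegions(bs, list())), centers)
  # removing everything is an error
  expect_error(excludeRegions(bs, list(c(0, 10))), "every bin")
})

test_that("total-intensity normalization divides rows by their sums", {
  bs <- BinnedSpectra(rbind(c(2, 2), c(1, 3)), c(1, 2))
  nn <- normalizeTotal(bs)
  expect_equal(nn@values, rbind(c(0.5, 0.5), c(0.25, 0.75)))
  expect_true(nn@normalized)
  # idempotent
  expect_equal(normalizeTotal(nn)@values, nn@values)
  # random positive matrix: all row sums 1 within 1e-12
  set.seed(1)
  bigg <- BinnedSpectra(matrix(runif(300) + 0.01, 6, 50), seq_len(50))
  expect_equal(rowSums(normalizeTotal(bigg)@values), rep(1, 6),
               tolerance = 1e-12)
  # zero-sum row is rejected with the sample id
  bad <- BinnedSpectra(rbind(c(1, 1), c(0, 0)), c(1, 2),
                       sampleIds = c("good", "empty"))
  expect_error(normalizeTotal(bad), "empty")
})

test_that("exclusion-then-normalization keeps row sums at 1 over retained bins", {
  set.seed(2)
  centers <- seq(0.02, by = 0.04, length.out = 250)
  bs <- BinnedSpectra(matrix(runif(500) + 0.1, 2, 250), centers)
  out <- normalizeTotal(excludeRegions(bs, defaultExclusionRegions("urine")))
  expect_equal(rowSums(out@values), rep(1, 2), tolerance = 1e-12)
})

test_that("wide CSV round-trips a binned matrix", {
  set.seed(3)
  bs <- normalizeTotal(BinnedSpectra(matrix(runif(60) + 0.1, 3, 20),
                                     seq(0.02, by = 0.04, length.out = 20),
                                     sampleIds = c("a", "b", "c")))
  f <- withr::local_tempfile(fileext = ".csv")
  writeBinnedSpectra(bs, f)
  back <- readBinnedSpectra(f)
  expect_equal(back@sampleIds, bs@sampleIds)
  expect_equal(back@binCenters, bs@binCenters, tolerance = 1e-3)
  expect_equal(back@values, bs@values, tolerance = 1e-6)
  expect_true(back@normalized)
})

test_that("long-format reader feeds binSpectra", {
  df <- data.frame(ppm = rep(seq(0.01, 0.99, by = 0.01), 2),
                   intensity = c(rep(1, 99), rep(2, 99)),
                   sample_id = rep(c("u1", "u2"), each = 99))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  spectra <- readLongSpectra(f)
  bs <- binSpectra(spectra, binWidth = 0.1, range = c(0, 1))
  expect_equal(sampleIds(bs), c("u1", "u2"))
  expect_equal(dim(bs@values), c(2, 10))
  expect_equal(sum(bs@values[1, ]), 99)
})
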