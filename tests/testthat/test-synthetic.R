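test_that("rendered spectra peak at the grid point nearest each center", {
  grid <- seq(0.02, by = 0.04, length.out = 250)
  tpl <- compoundTemplate("x", data.frame(center = 3.26, width = 0.02,
                                          height = 5))
  y <- renderSpectrum(tpl, grid)
  expect_true(all(y >= 0))
  expect_equal(which.max(y), which.min(abs(grid - 3.26)))
  expect_gt(max(y), 0.99 * 5)  # on-grid center reaches nearly full height
})

test_that("templates without peaks or with out-of-range centers are rejected", {
  expect_error(compoundTemplate("empty",
    data.frame(center = numeric(), width = numeric(), height = numeric())),
    "at least one peak")
  expect_error(compoundTemplate("badw",
    data.frame(center = 1, width = 0, height = 1)), "width")
  tpl <- compoundTemplate("out", data.frame(center = 12, width = 0.02,
                                            height = 1))
  expect_error(renderSpectrum(tpl, seq(0, 10, by = 0.04)), "outside")
})

test_that("two far-apart unit peaks integrate to twice one peak", {
  # fine grid so that trapezoidal quadrature is accurate
  grid <- seq(0, 10, by = 0.001)
  one <- compoundTemplate("one", data.frame(center = 3, width = 0.02,
                                            height = 1))
  two <- compoundTemplate("two", data.frame(center = c(3, 7), width = 0.02,
                                            height = 1))
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  i1 <- trapz(grid, renderSpectrum(one, grid))
  i2 <- trapz(grid, renderSpectrum(two, grid))
  expect_equal(i2, 2 * i1, tolerance = 0.01)
})

test_that("noise-free simulation is exactly bilinear with matching rank", {
  lib <- standardCompoundLibrary()[1:3]
  set.seed(5)
  design <- matrix(rlnorm(10 * 3), 10, 3)
  grid <- seq(0.02, by = 0.04, length.out = 250)
  ds <- simulateDataset(lib, design, grid, noiseSd = 0, seed = 1)
  expect_equal(ds@data@values,
               unname(ds@concentrations %*% ds@spectra))
  expect_equal(qr(ds@data@values)$rank, 3)
})

test_that("simulation is reproducible given the seed", {
  lib <- standardCompoundLibrary()[1:4]
  set.seed(2)
  design <- matrix(rlnorm(8 * 4), 8, 4)
  grid <- seq(0.02, by = 0.04, length.out = 250)
  a <- simulateDataset(lib, design, grid, noiseSd = 0.05, seed = 42)
  b <- simulateDataset(lib, design, grid, noiseSd = 0.05, seed = 42)
  c3 <- simulateDataset(lib, design, grid, noiseSd = 0.05, seed = 43)
  expect_identical(a@data@values, b@data@values)
  expect_false(identical(a@data@values, c3@data@values))
})

test_that("low-noise 8-compound data is captured by 8 singular values", {
  lib <- standardCompoundLibrary()[1:8]
  set.seed(3)
  design <- matrix(rlnorm(20 * 8), 20, 8)
  grid <- seq(0.02, by = 0.04, length.out = 250)
  ds <- simulateDataset(lib, design, grid, noiseSd = 1e-4, seed = 9)
  sv <- svd(ds@data@values)$d
  expect_gte(sum(sv[1:8]^2) / sum(sv^2), 0.99)
})

test_that("simulateDataset rejects design/library shape mismatches", {
  lib <- standardCompoundLibrary()[1:3]
  grid <- seq(0.02, by = 0.04, length.out = 50)
  expect_error(simulateDataset(lib, matrix(1, 5, 2), grid),
               "one column per library compound")
})

test_that("standard mixture preset meets its design contracts", {
  d <- standardMixturePreset(nSamples = 20, seed = 7)
  expect_s4_class(d, "SyntheticDataset")
  # 15 named compounds plus the fixed trace-signal set
  expect_equal(dim(d@concentrations), c(20, 15 + 25))
  expect_equal(colnames(d@concentrations)[1:3],
               c("alanine", "lactate", "butyrate"))
  expect_true(all(d@concentrations >= 0))
  expect_true(all(d@data@values >= 0))
  # distinct compounds: pairwise design correlation bounded away from 1
  distinct <- d@concentrations[, 1:7]
  cc <- cor(distinct)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.7)
  # confounded trio: pairwise correlation at least 0.9
  trio <- cor(d@concentrations[, 8:10])
  expect_gte(min(trio), 0.9)
  # seeds: same -> identical, different -> different noise, same library
  a <- standardMixturePreset(nSamples = 12, seed = 1)
  b <- standardMixturePreset(nSamples = 12, seed = 1)
  c3 <- standardMixturePreset(nSamples = 12, seed = 2)
  expect_identical(a@data@values, b@data@values)
  expect_false(identical(a@data@values, c3@data@values))
  expect_identical(a@spectra, c3@spectra)  # library is fixed across seeds
  expect_error(standardMixturePreset(nSamples = 5), "at least 10")
})
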