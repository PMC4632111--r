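test_that("eigenvalue spectra match the SVD oracle", {
  set.seed(27)
  X <- matrix(rnorm(12 * 20), 12, 20)
  spec <- eigSpectrum(X)
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  expect_equal(spec@values[1:11], (sv^2 / 11)[1:11], tolerance = 1e-10)
  # rank-1 data: exactly one non-negligible eigenvalue
  r1 <- eigSpectrum((1:6) %o% runif(15))
  expect_lt(r1@values[2] / r1@values[1], 1e-10)
  # standardized spectrum sums to the number of variables (trace identity)
  sp <- eigSpectrum(X, standardize = TRUE)
  expect_equal(sum(sp@values), 20, tolerance = 1e-8)
  expect_true(sp@standardized)
})

test_that("the Kaiser criterion counts eigenvalues above 1", {
  sp <- new("EigSpectrum", values = c(3, 1.2, 0.9, 0.5),
            standardized = TRUE, nSamples = 10L, nVars = 4L)
  expect_equal(kaiserRule(sp), 2)
  sp0 <- new("EigSpectrum", values = c(0.9, 0.5), standardized = TRUE,
             nSamples = 10L, nVars = 2L)
  expect_equal(kaiserRule(sp0), 0)
  spc <- new("EigSpectrum", values = c(3, 0.5), standardized = FALSE,
             nSamples = 10L, nVars = 2L)
  expect_warning(kaiserRule(spc), "standardized")
})

test_that("parallel analysis retains planted components and rejects noise", {
  set.seed(28)
  # pure noise: essentially nothing retained
  noise <- matrix(rnorm(20 * 50), 20, 50)
  expect_lte(parallelAnalysis(noise, nRep = 100, seed = 1), 1)
  # three strong planted components
  bl <- makeBilinear(n = 20, p = 50, k = 3, seed = 29, noiseSd = 0.05)
  expect_equal(parallelAnalysis(bl$D, nRep = 100, seed = 1), 3)
  expect_error(parallelAnalysis(noise, nRep = 0), "at least 1")
  # reproducible given the seed
  expect_equal(parallelAnalysis(bl$D, nRep = 50, seed = 9),
               parallelAnalysis(bl$D, nRep = 50, seed = 9))
})

test_that("CNG finds the elbow from the three-by-three slope windows", {
  # sharp elbow after position 3
  ev <- c(6, 4, 2, 0.5, 0.48, 0.46, 0.44, 0.42, 0.40)
  # window-scan oracle computed directly
  slope3 <- function(y) coef(lm(y ~ seq_along(y)))[2]
  diffs <- vapply(1:(length(ev) - 5), function(i)
    slope3(ev[(i + 3):(i + 5)]) - slope3(ev[i:(i + 2)]), 0)
  expect_equal(cngTest(ev), unname(which.max(diffs) + 2))
  expect_equal(cngTest(ev), 3)
  # constant-slope spectrum: all differences ~0, first window wins
  expect_equal(cngTest(seq(10, 1, length.out = 10)), 3)
  expect_error(cngTest(c(3, 2, 1, 0.5, 0.2)), "at least 6")
})

test_that("the multiple-regression split detects a two-line breakpoint", {
  # perfect two-line spectrum with breakpoint at 4
  ev <- c(10 - 2 * (1:4), 1.0 - 0.05 * (1:8))
  expect_equal(mregTest(ev), 4)
  # constant spectrum: zero slopes everywhere, first split returned
  expect_equal(mregTest(rep(1, 8)), 2)
  expect_error(mregTest(c(1, 2, 3)), "at least 6")
})

test_that("GCV and smoothing cross-validation recover a planted rank", {
  bl <- makeBilinear(n = 15, p = 40, k = 3, seed = 30, noiseSd = 0.02)
  expect_equal(gcvComponents(bl$D, kmax = 8), 3)
  expect_equal(smoothComponents(bl$D, kmax = 8), 3)
  # pure noise: smallest models win
  set.seed(31)
  noise <- matrix(rnorm(15 * 40), 15, 40)
  expect_lte(gcvComponents(noise, kmax = 8), 1)
  # rank-1 data
  r1 <- (seq(1, 2, length.out = 10) %o% runif(25)) + 1e-6
  expect_equal(smoothComponents(r1, kmax = 5), 1)
  expect_error(gcvComponents(bl$D, kmax = 0), "out of range")
  # degenerate tiny input does not crash
  expect_no_error(smoothComponents(matrix(c(1, 2, 3, 5), 2, 2), kmax = 1))
})

test_that("cumulative contribution returns the smallest k strictly above the level", {
  ev <- c(0.6, 0.25, 0.1, 0.05)
  expect_equal(cumulativeContribution(ev, 0.90), 3)
  expect_equal(cumulativeContribution(c(0.95, 0.05), 0.90), 1)
  expect_equal(cumulativeContribution(ev, 1.0), 4)  # boundary: full length
  expect_error(cumulativeContribution(c(0, 0)), "zero total")
})

test_that("the scree table round-trips through CSV", {
  set.seed(32)
  sp <- eigSpectrum(matrix(rnorm(80), 8, 10))
  tab <- screeTable(sp)
  expect_equal(nrow(tab), length(sp@values))
  expect_equal(tab$eigenvalue, sort(tab$eigenvalue, decreasing = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$eigenvalue, tab$eigenvalue, tolerance = 1e-12)
  expect_equal(back$component, tab$component)
})

test_that("the eight-method panel runs and may disagree on noisy data", {
  bl <- makeBilinear(n = 15, p = 30, k = 3, seed = 33, noiseSd = 0.4)
  tab <- estimateComponents(bl$D, kmax = 8, nRep = 50, seed = 2)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$k >= 0 & tab$k <= 30, na.rm = TRUE))
  # the motivating observation: estimators need not agree
  expect_gte(length(unique(tab$k)), 2)
})
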