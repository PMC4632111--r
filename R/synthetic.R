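#' Define a compound spectral template
#'
#' A compound is a set of Lorentzian peaks; `width` is the half-width at
#' half-maximum (HWHM) in ppm, `height` the relative intensity of the peak
#' maximum.
#'
#' @param name compound name.
#' @param peaks data.frame with numeric columns `center` (ppm), `width`
#'   (ppm, > 0), `height` (>= 0); at least one row.
#' @return A `compoundTemplate` (list with class attribute).
#' @export
#' @examples
#' ala <- compoundTemplate("alanine",
#'   data.frame(center = c(1.48, 3.78), width = 0.015, height = c(3, 1)))
compoundTemplate <- function(name, peaks) {
  peaks <- as.data.frame(peaks)
  need <- c("center", "width", "height")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns center, width, height")
  if (nrow(peaks) < 1) stop("a compound template needs at least one peak")
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$height < 0)) stop("peak heights must be non-negative")
  structure(list(name = as.character(name),
                 peaks = peaks[, need, drop = FALSE]),
            class = "compoundTemplate")
}

#' Render a compound template on a ppm grid
#'
#' Evaluates the sum of the template's Lorentzian peaks,
#' `h * w^2 / ((ppm - center)^2 + w^2)`, at each grid point.
#'
#' @param template a [compoundTemplate()].
#' @param ppmGrid strictly increasing ppm values (typically bin centers).
#' @return non-negative intensity vector, one value per grid point.
#' @export
renderSpectrum <- function(template, ppmGrid) {
  if (!inherits(template, "compoundTemplate"))
    stop("'template' must be a compoundTemplate")
  ppmGrid <- as.numeric(ppmGrid)
  if (length(ppmGrid) < 1 || (length(ppmGrid) > 1 && any(diff(ppmGrid) <= 0)))
    stop("ppmGrid must be strictly increasing")
  lo <- ppmGrid[1]; hi <- ppmGrid[length(ppmGrid)]
  p <- template$peaks
  if (any(p$center < lo | p$center > hi))
    stop(sprintf("peak center outside the grid range for compound '%s'",
                 template$name))
  y <- numeric(length(ppmGrid))
  for (i in seq_len(nrow(p))) {
    y <- y + p$height[i] * p$width[i]^2 /
      ((ppmGrid - p$center[i])^2 + p$width[i]^2)
  }
  y
}

#' Simulate a binned mixture dataset from a compound library
#'
#' Builds `D0 = design %*% spectra` from the rendered library spectra, adds
#' i.i.d. Gaussian noise with standard deviation `noiseSd` and truncates at
#' zero (MCR-ALS assumes non-negative data). With `noiseSd = 0` the data
#' matrix is exactly the bilinear product, so its rank is at most the number
#' of compounds.
#'
#' @param library list of [compoundTemplate()]s.
#' @param design numeric samples x compounds matrix of non-negative
#'   concentrations (arbitrary units); column order follows the library. An
#'   optional `"groups"` attribute supplies sample group labels.
#' @param ppmGrid strictly increasing ppm grid (bin centers).
#' @param noiseSd standard deviation of the additive noise (>= 0).
#' @param seed integer simulation seed.
#' @return A [SyntheticDataset-class].
#' @export
simulateDataset <- function(library, design, ppmGrid, noiseSd = 0, seed = 1) {
  design <- as.matrix(design)
  if (ncol(design) != length(library))
    stop("design must have one column per library compound")
  if (nrow(design) < 2) stop("at least 2 samples are required")
  if (any(design < 0)) stop("concentrations must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  spectra <- do.call(rbind, lapply(library, renderSpectrum, ppmGrid = ppmGrid))
  rownames(spectra) <- vapply(library, `[[`, "", "name")
  colnames(design) <- rownames(spectra)
  if (is.null(rownames(design)))
    rownames(design) <- paste0("s", seq_len(nrow(design)))
  groups <- attr(design, "groups")
  if (is.null(groups)) groups <- rep("all", nrow(design))
  D0 <- design %*% spectra
  D <- if (noiseSd > 0) {
    withSeed(seed, pmax(D0 + matrix(rnorm(length(D0), sd = noiseSd),
                                    nrow(D0), ncol(D0)), 0))
  } else D0
  bs <- BinnedSpectra(D, ppmGrid, rownames(design))
  design2 <- design
  attr(design2, "groups") <- NULL
  new("SyntheticDataset", data = bs,
      concentrations = design2, groups = as.character(groups),
      spectra = spectra, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Built-in compound library for the standard-mixture preset
#'
#' Fifteen compounds with Lorentzian signatures at chemical shifts typical
#' of amino acids, short-chain fatty acids, and sugars observed in urine
#' and feces. The seven pattern-distinct major compounds each have a
#' multi-peak signature or at least one resonance in an uncrowded region
#' (as real standard-mixture compounds do); the concentration-confounded
#' glucose/trehalose/ethanol trio crowds the 3.2-3.9 ppm sugar region to
#' exercise overlapping signals; and five minor compounds at roughly a
#' fifth of the major intensities give the mixture the spectral complexity
#' of a real multi-compound standard, so that factorizations with more
#' components than major compounds absorb minor signals instead of
#' splitting major profiles.
#'
#' @return list of [compoundTemplate()]s; majors 1-7, confounded trio
#'   8-10, minors 11-15.
#' @export
standardCompoundLibrary <- function() {
  mk <- function(name, center, height, width = 0.015)
    compoundTemplate(name, data.frame(center = center, width = width,
                                      height = height))
  list(
    mk("alanine",    c(1.42, 1.46), c(2, 2)),
    mk("lactate",    c(1.26, 1.30, 4.10), c(2, 2, 1)),
    mk("butyrate",   c(0.86, 0.90, 2.14), c(2, 2, 2)),
    mk("formate",    c(8.46), c(2.5)),
    mk("citrate",    c(2.50, 2.62), c(2, 2)),
    mk("creatinine", c(3.06, 4.06), c(2.5, 1.5)),
    mk("hippurate",  c(3.94, 7.54, 7.66, 7.82), c(2, 2, 1, 2), 0.02),
    mk("glucose",    c(3.22, 3.38, 3.70, 3.82), c(1, 2, 2, 1), 0.02),
    mk("trehalose",  c(3.46, 3.62, 3.78, 3.86), c(1.5, 2, 2, 1), 0.02),
    mk("ethanol",    c(1.18, 3.66), c(3, 2)),
    mk("taurine",    c(3.26, 3.42), c(0.4, 0.4)),
    mk("succinate",  c(2.42), c(0.5)),
    mk("glycine",    c(3.58), c(0.4)),
    mk("fumarate",   c(6.54), c(0.4)),
    mk("methanol",   c(3.34), c(0.4))
  )
}

#' Trace impurity signals for the standard-mixture preset
#'
#' A fixed set of low-intensity single-peak signals at scattered chemical
#' shifts, emulating the impurities, satellites, and unassigned trace
#' signals of a real standard mixture. They give the simulated data the
#' gradually decaying variance spectrum of real spectra, so that
#' factorizations with many components absorb trace variation instead of
#' splitting major-compound profiles. The set is deterministic: it is part
#' of the preset's design and identical for every simulation seed.
#'
#' @param n number of trace signals.
#' @return list of [compoundTemplate()]s named `trace01`, `trace02`, ...
#' @export
traceSignalLibrary <- function(n = 25) {
  withSeed(20201, {
    centers <- round(runif(n, 0.5, 9.5), 2)
    heights <- runif(n, 0.2, 0.5)
    lapply(seq_len(n), function(i) {
      compoundTemplate(sprintf("trace%02d", i),
                       data.frame(center = centers[i], width = 0.015,
                                  height = heights[i]))
    })
  })
}

#' Standard-mixture preset: known mixtures at varied concentrations
#'
#' Emulates a model-sample design: fifteen compounds (see
#' [standardCompoundLibrary()]) at varied concentrations across samples on
#' a 250-bin 0-10 ppm grid. The first seven (major) compounds receive
#' mutually distinct concentration patterns (pairwise design correlation
#' below 0.3, enforced by rejection sampling); compounds 8-10 — glucose,
#' trehalose, ethanol — share a nearly common pattern (pairwise correlation
#' at least 0.9) to reproduce the concentration-confounded case in which
#' one cluster serves several compounds; compounds 11-15 are low-intensity
#' minor constituents with their own patterns. Noise defaults to 1% of the
#' mean noise-free signal.
#'
#' @param nSamples number of samples (>= 10).
#' @param noiseSd noise standard deviation; `NULL` for 1% of the mean
#'   noise-free intensity.
#' @param seed integer seed (design and noise).
#' @param nTraces number of fixed low-intensity trace signals appended to
#'   the compound library (see [traceSignalLibrary()]).
#' @return A [SyntheticDataset-class].
#' @export
standardMixturePreset <- function(nSamples = 20, noiseSd = NULL, seed = 1,
                                  nTraces = 25) {
  if (nSamples < 10) stop("the preset needs at least 10 samples")
  lib <- c(standardCompoundLibrary(), traceSignalLibrary(nTraces))
  nC <- length(lib)
  nDistinct <- 7L
  nNamed <- 15L
  design <- withSeed(seed, {
    ## One concentration series: moderate log-normal variation
    ## (sdlog = 0.8) with the compound deliberately absent from a fixed
    ## number of samples (4 of 20, scaled proportionally) — the designed
    ## dilution series of a standard mixture in which not every compound
    ## is present in every sample. The guaranteed absences are what make
    ## the non-negative factorization essentially unique (with an
    ## everywhere-positive design an exact continuum of rotated solutions
    ## exists even when every compound has selective spectral bins), while
    ## the otherwise continuous light-tailed marginal keeps the
    ## randomized-data null well behaved.
    nAbsent <- max(2L, round(nSamples / 5))
    drawSeries <- function() {
      x <- rlnorm(nSamples, meanlog = 0, sdlog = 0.8)
      x[sample.int(nSamples, nAbsent)] <- 0
      x
    }
    okSeries <- function(cand, others) {
      if (length(others) == 0) return(TRUE)
      isTRUE(max(abs(cor(cand, others))) < 0.3)
    }
    M <- matrix(0, nSamples, nC)
    ## distinct compounds: redraw until the new series is nearly
    ## independent of all earlier ones
    for (j in seq_len(nDistinct)) {
      repeat {
        cand <- drawSeries()
        if (okSeries(cand, M[, seq_len(j - 1), drop = FALSE])) break
      }
      M[, j] <- cand
    }
    ## confounded trio: one base pattern (itself nearly independent of the
    ## distinct set) plus small multiplicative jitter
    repeat {
      base <- drawSeries()
      if (okSeries(base, M[, seq_len(nDistinct), drop = FALSE])) break
    }
    for (j in nDistinct + 1:3) {
      repeat {
        cand <- base * exp(rnorm(nSamples, sd = 0.05))
        if (isTRUE(min(cor(cand, cbind(base, M[, nDistinct + 1:3][,
              seq_len(j - nDistinct - 1), drop = FALSE]))) >= 0.9)) break
      }
      M[, j] <- cand
    }
    ## minor compounds: independent series, loosely decorrelated from the
    ## majors so they cannot shadow a scored compound
    for (j in (nDistinct + 4):nNamed) {
      repeat {
        cand <- drawSeries()
        if (isTRUE(max(abs(cor(cand,
              M[, seq_len(nDistinct + 3), drop = FALSE]))) < 0.5)) break
      }
      M[, j] <- cand
    }
    ## trace signals: unconstrained independent series
    if (nC > nNamed) {
      for (j in (nNamed + 1):nC) M[, j] <- drawSeries()
    }
    M
  })
  rownames(design) <- sprintf("s%02d", seq_len(nSamples))
  attr(design, "groups") <- rep(c("A", "B"), length.out = nSamples)
  grid <- seq(0.02, by = 0.04, length.out = 250)
  if (is.null(noiseSd)) {
    spectra <- do.call(rbind, lapply(lib, renderSpectrum, ppmGrid = grid))
    noiseSd <- 0.01 * mean(design %*% spectra)
  }
  simulateDataset(lib, design, grid, noiseSd = noiseSd,
                  seed = childSeeds(seed, 1))
}
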