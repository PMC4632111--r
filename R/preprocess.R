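#' Construct a BinnedSpectra object
#'
#' @param values numeric samples x bins matrix, non-negative.
#' @param binCenters numeric vector of bin-center chemical shifts (ppm).
#' @param sampleIds character sample identifiers; defaults to the row names
#'   of `values` or `"s1", "s2", ...`.
#' @param normalized logical, whether rows already sum to one.
#' @return A [BinnedSpectra-class] object.
#' @export
#' @examples
#' bs <- BinnedSpectra(matrix(1:6, 2, 3), binCenters = c(1, 2, 3))
#' bs
BinnedSpectra <- function(values, binCenters, sampleIds = NULL,
                          normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds)) {
    sampleIds <- rownames(values)
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(values)))
  }
  new("BinnedSpectra", values = unname(values),
      binCenters = as.numeric(binCenters),
      sampleIds = as.character(sampleIds),
      normalized = isTRUE(normalized))
}

#' Bin a raw 1D spectrum onto a fixed chemical-shift grid
#'
#' Splits the interval `range = c(lo, hi)` into `ceiling((hi - lo)/binWidth)`
#' half-open bins `[lo + i*w, lo + (i+1)*w)` and sums the intensities of the
#' raw points falling into each bin, so binning conserves the total
#' intensity over the covered range. With the 0-10 ppm range this yields the
#' standard 250-variable (0.04 ppm) and 500-variable (0.02 ppm) layouts used
#' for urine and fecal spectra.
#'
#' @param spectrum a data.frame (or list) with numeric elements `ppm` and
#'   `intensity` of equal length; `ppm` must be strictly monotone.
#' @param binWidth bin width in ppm (> 0).
#' @param range length-2 numeric, the covered ppm interval.
#' @return list with `centers` (bin-center ppm values, ascending) and
#'   `values` (summed intensities per bin).
#' @export
#' @examples
#' sp <- data.frame(ppm = seq(0, 9.99, by = 0.01), intensity = 1)
#' b <- binSpectrum(sp, binWidth = 0.04, range = c(0, 10))
#' length(b$values)  # 250
binSpectrum <- function(spectrum, binWidth, range = c(0, 10)) {
  ppm <- as.numeric(spectrum$ppm)
  intensity <- as.numeric(spectrum$intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length")
  if (length(ppm) > 1) {
    d <- diff(ppm)
    if (!(all(d > 0) || all(d < 0)))
      stop("ppm axis must be strictly monotone")
  }
  if (!is.numeric(binWidth) || length(binWidth) != 1 || binWidth <= 0)
    stop("binWidth must be a single positive number")
  lo <- min(range); hi <- max(range)
  nBins <- ceiling((hi - lo) / binWidth)
  if (nBins < 1) stop("range must span at least one bin")
  idx <- floor((ppm - lo) / binWidth) + 1
  keep <- idx >= 1 & idx <= nBins & ppm >= lo
  if (!any(keep))
    stop("no spectral points fall inside the requested range")
  values <- numeric(nBins)
  agg <- rowsum(intensity[keep], idx[keep])
  values[as.integer(rownames(agg))] <- agg[, 1]
  centers <- lo + (seq_len(nBins) - 0.5) * binWidth
  list(centers = centers, values = values)
}

#' Bin a set of raw spectra into a BinnedSpectra matrix
#'
#' @param spectra named list of raw spectra (each with `ppm`, `intensity`);
#'   names become sample ids.
#' @inheritParams binSpectrum
#' @return A [BinnedSpectra-class] with one row per input spectrum.
#' @export
binSpectra <- function(spectra, binWidth, range = c(0, 10)) {
  if (!length(spectra)) stop("no spectra supplied")
  binned <- lapply(spectra, binSpectrum, binWidth = binWidth, range = range)
  centers <- binned[[1]]$centers
  values <- do.call(rbind, lapply(binned, `[[`, "values"))
  ids <- names(spectra)
  if (is.null(ids)) ids <- paste0("s", seq_along(spectra))
  BinnedSpectra(values, centers, ids)
}

#' Remove chemical-shift regions from a binned matrix
#'
#' A bin is removed iff its center lies inside any of the given closed
#' intervals. Typical use is excluding the internal-standard (DSS) region
#' and the water/urea region (for urine: 0-0.277 ppm and 4.5-6.25 ppm)
#' before normalization.
#'
#' @param x a [BinnedSpectra-class].
#' @param regions list of length-2 numeric vectors `c(lo, hi)` (or a 2-column
#'   matrix), in ppm.
#' @return A [BinnedSpectra-class] with the surviving bins; labels preserved.
#' @export
excludeRegions <- function(x, regions) {
  stopifnot(is(x, "BinnedSpectra"))
  if (is.matrix(regions)) regions <- split(regions, row(regions)[, 1])
  if (!length(regions)) return(x)
  drop <- rep(FALSE, length(x@binCenters))
  for (rg in regions) {
    if (length(rg) != 2 || !is.numeric(rg)) stop("each region must be c(lo, hi)")
    lo <- min(rg); hi <- max(rg)
    drop <- drop | (x@binCenters >= lo & x@binCenters <= hi)
  }
  if (all(drop)) stop("excluding these regions would remove every bin")
  BinnedSpectra(x@values[, !drop, drop = FALSE], x@binCenters[!drop],
                x@sampleIds, normalized = FALSE)
}

#' Total-intensity normalization
#'
#' Divides each spectrum (row) by its own total so that every row sums to
#' one. Applied after region exclusion, so normalization is over the
#' retained bins.
#'
#' @param x a [BinnedSpectra-class]; every row must have a positive sum.
#' @return A normalized [BinnedSpectra-class].
#' @export
normalizeTotal <- function(x) {
  stopifnot(is(x, "BinnedSpectra"))
  rs <- rowSums(x@values)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("cannot normalize sample(s) with non-positive total intensity: ",
         paste(x@sampleIds[bad], collapse = ", "))
  BinnedSpectra(x@values / rs, x@binCenters, x@sampleIds, normalized = TRUE)
}

#' Default exclusion regions
#'
#' Convenience constants for the urinary (0.04 ppm bins) and fecal
#' (0.02 ppm bins) processing conventions: the DSS internal-standard region
#' and, for urine, the water/urea region.
#'
#' @param matrixType `"urine"` or `"feces"`.
#' @return list of `c(lo, hi)` ppm intervals.
#' @export
defaultExclusionRegions <- function(matrixType = c("urine", "feces")) {
  matrixType <- match.arg(matrixType)
  if (matrixType == "urine") {
    list(c(0, 0.277), c(4.5, 6.25))
  } else {
    list(c(0, 0.48))
  }
}
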