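#' @include AllClasses.R
NULL

#' Accessors for camcr classes
#'
#' Small accessor generics shared by the package's S4 containers:
#' `intensities()` returns the samples x bins matrix of a
#' [BinnedSpectra-class]; `binCenters()` and `sampleIds()` return its axis
#' labels; `concProfiles()` and `specProfiles()` return the profile matrices
#' of an [MCRFit-class] or [ComponentPool-class]; `componentIds()` returns
#' record identifiers; `nComponents()` counts components/records;
#' `auValues()` returns per-node AU p-values of an [AUClusterFit-class];
#' `reliableClusters()` returns the accepted membership list of a
#' [ReliableClusters-class].
#'
#' @param x object.
#' @return See above; vectors or matrices with dimension labels.
#' @name accessors
#' @aliases intensities binCenters sampleIds concProfiles specProfiles
#'   componentIds nComponents auValues reliableClusters
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("concProfiles", function(x) standardGeneric("concProfiles"))

#' @rdname accessors
#' @export
setGeneric("specProfiles", function(x) standardGeneric("specProfiles"))

#' @rdname accessors
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("auValues", function(x) standardGeneric("auValues"))

#' @rdname accessors
#' @export
setGeneric("reliableClusters", function(x) standardGeneric("reliableClusters"))
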