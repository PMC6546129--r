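#' @title Generics for pjresbin classes
#' @name pjresbin-generics
#' @description Accessor generics shared by \linkS4class{SpectraSet},
#'   \linkS4class{BinnedSet} and \linkS4class{CorrelationSpectrum}.
#' @param x an object of a pjresbin class.
#' @keywords internal
NULL

#' @describeIn pjresbin-generics chemical-shift axis (ppm), strictly increasing.
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' @describeIn pjresbin-generics intensity matrix, samples in rows and
#'   spectral variables (or clusters) in columns.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @describeIn pjresbin-generics sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn pjresbin-generics logical vector flagging pooled QC samples.
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @describeIn pjresbin-generics per-window (or per-cluster) average
#'   correlation.
#' @export
setGeneric("rBar", function(x) standardGeneric("rBar"))

#' @describeIn pjresbin-generics ppm of each sliding window's first
#'   (lowest-ppm) variable.
#' @export
setGeneric("ppmAnchor", function(x) standardGeneric("ppmAnchor"))

#' @describeIn pjresbin-generics cluster table (DataFrame) of a
#'   \linkS4class{BinnedSet}.
#' @export
setGeneric("clusterInfo", function(x) standardGeneric("clusterInfo"))

#' @describeIn pjresbin-generics binning method label ("JBA", "SRV" or "SB").
#' @export
setGeneric("binMethod", function(x) standardGeneric("binMethod"))

#' @describeIn pjresbin-generics parameter record used to produce a
#'   \linkS4class{BinnedSet}.
#' @export
setGeneric("binParams", function(x) standardGeneric("binParams"))

#' @describeIn pjresbin-generics number of spectral variables (columns of the
#'   sample-by-variable matrix).
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' @describeIn pjresbin-generics number of samples.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
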