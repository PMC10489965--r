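#' Number of histogram bins
#' @param x a VariantLUT, FeatureHistogram or VolumeFeature
#' @return integer bin count
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Per-bin occurrence counts
#' @param x a FeatureHistogram or VolumeFeature
#' @return numeric vector of counts
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Saturation flag
#'
#' TRUE iff a saturating counter clamped and dropped at least one
#' increment while the object was accumulated.
#' @param x a FeatureHistogram or VolumeFeature
#' @return logical scalar
#' @export
setGeneric("isSaturated", function(x) standardGeneric("isSaturated"))

#' Total number of pixels described by an object
#'
#' For an OCTVolume this is S * H * W over the stored slices; for a
#' SyntheticSpec it is computed from the geometry alone, without
#' materialising any pixel data.
#' @param x an OCTVolume or SyntheticSpec
#' @return numeric pixel count
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))

#' Slices of a volume
#' @param x an OCTVolume
#' @return list of integer matrices
#' @export
setGeneric("volumeSlices", function(x) standardGeneric("volumeSlices"))

#' Class label of a volume
#' @param x an OCTVolume
#' @return "normal", "amd" or NA
#' @export
setGeneric("volumeLabel", function(x) standardGeneric("volumeLabel"))

#' Model weight vector
#' @param x a LinearSVMModel or QuantizedModel
#' @return numeric weights
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' Model bias
#' @param x a LinearSVMModel or QuantizedModel
#' @return numeric scalar
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

#' Feature values
#' @param x a VolumeFeature
#' @return numeric vector
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
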