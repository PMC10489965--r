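#' @describeIn nBins bins of a lookup table
#' @export
setMethod("nBins", "VariantLUT", function(x) x@nBins)

#' @describeIn nBins bins of a histogram
#' @export
setMethod("nBins", "FeatureHistogram", function(x) length(x@counts))

#' @describeIn nBins per-slice bin count of a volume feature
#' @export
setMethod("nBins", "VolumeFeature", function(x) x@nBins)

#' @describeIn binCounts counts of a histogram
#' @export
setMethod("binCounts", "FeatureHistogram", function(x) x@counts)

#' @describeIn binCounts values of a volume feature
#' @export
setMethod("binCounts", "VolumeFeature", function(x) x@values)

#' @describeIn isSaturated histogram flag
#' @export
setMethod("isSaturated", "FeatureHistogram", function(x) x@saturated)

#' @describeIn isSaturated propagated volume-feature flag
#' @export
setMethod("isSaturated", "VolumeFeature", function(x) x@saturated)

#' @describeIn featureValues values of a volume feature
#' @export
setMethod("featureValues", "VolumeFeature", function(x) x@values)

#' @describeIn pixelCount pixels actually stored in the volume
#' @export
setMethod("pixelCount", "OCTVolume", function(x) {
  d <- dim(x@slices[[1]])
  length(x@slices) * as.numeric(d[1]) * as.numeric(d[2])
})

#' @describeIn pixelCount pixels implied by the generator geometry
#' @export
setMethod("pixelCount", "SyntheticSpec", function(x) {
  as.numeric(x@S) * as.numeric(x@H) * as.numeric(x@W)
})

#' @describeIn volumeSlices slice list
#' @export
setMethod("volumeSlices", "OCTVolume", function(x) x@slices)

#' @describeIn volumeLabel stored label
#' @export
setMethod("volumeLabel", "OCTVolume", function(x) x@classLabel)

#' @describeIn modelWeights weights of a float model
#' @export
setMethod("modelWeights", "LinearSVMModel", function(x) x@weights)

#' @describeIn modelWeights weights of the model inside a quantized wrapper
#' @export
setMethod("modelWeights", "QuantizedModel", function(x) x@model@weights)

#' @describeIn modelBias bias of a float model
#' @export
setMethod("modelBias", "LinearSVMModel", function(x) x@bias)

#' @describeIn modelBias bias of the model inside a quantized wrapper
#' @export
setMethod("modelBias", "QuantizedModel", function(x) x@model@bias)

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("OCTVolume '%s': %d slice(s) of %d x %d, label %s\n",
              object@id, length(object@slices), d[1], d[2],
              ifelse(is.na(object@classLabel), "<none>", object@classLabel)))
})

setMethod("show", "VariantLUT", function(object) {
  cat(sprintf("VariantLUT: variant '%s', 256 codes -> %d bins\n",
              object@variant, object@nBins))
})

setMethod("show", "FeatureHistogram", function(object) {
  cat(sprintf("FeatureHistogram: %d bins, total %s, counterWidth %s%s\n",
              length(object@counts), format(sum(object@counts)),
              ifelse(is.finite(object@counterWidth),
                     format(object@counterWidth), "unlimited"),
              ifelse(object@saturated, " [SATURATED]", "")))
})

setMethod("show", "ConnectionMethod", function(object) {
  extra <- if (object@tag == "slice_threshold")
    sprintf(" (threshold %s)", format(object@threshold)) else ""
  cat(sprintf("ConnectionMethod: %s%s\n", object@tag, extra))
})

setMethod("show", "VolumeFeature", function(object) {
  cat(sprintf("VolumeFeature: length %d (%s, K = %d)%s\n",
              length(object@values), object@method@tag, object@nBins,
              ifelse(object@saturated, " [SATURATED]", "")))
})

setMethod("show", "DualSolution", function(object) {
  cat(sprintf("DualSolution: %d support point(s), %d feature(s)\n",
              nrow(object@samples), ncol(object@samples)))
})

setMethod("show", "LinearSVMModel", function(object) {
  cat(sprintf(
    "LinearSVMModel: %d weight(s), bias %.6g; positive = '%s', negative = '%s'\n",
    length(object@weights), object@bias,
    object@labelMap[["positive"]], object@labelMap[["negative"]]))
  if (!is.na(object@variant))
    cat(sprintf("  provenance: variant '%s', method '%s'\n",
                object@variant, object@method))
})

setMethod("show", "FixedPointFormat", function(object) {
  cat(sprintf("FixedPointFormat: %s, %d integer + %d fraction bit(s), %s/%s\n",
              ifelse(object@signed, "signed", "unsigned"),
              object@integerBits, object@fractionBits,
              object@overflow, object@rounding))
})

setMethod("show", "QuantizedModel", function(object) {
  cat("QuantizedModel over:\n  ")
  show(object@model)
  for (nm in c("featureFormat", "weightFormat", "biasFormat",
               "accumulatorFormat")) {
    cat(sprintf("  %s: ", nm)); show(slot(object, nm))
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d x %d, separation %.2f, noiseSd %.1f, %d normal + %d amd, seed %d\n",
    object@S, object@H, object@W, object@separation, object@noiseSd,
    object@nNormal, object@nAmd, object@seed))
})
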