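# Volume-level feature aggregation: slice-chain, slice-sum and the
# slice-threshold vote rule.

#' Connection method constructor
#'
#' @param tag "slice_chain", "slice_threshold" or "slice_sum"
#' @param threshold positive-slice vote threshold for slice_threshold;
#'   `NA` defers to the majority default `floor(S/2)` at decision time
#' @return a [ConnectionMethod-class]
#' @export
connectionMethod <- function(tag = c("slice_sum", "slice_chain",
                                     "slice_threshold"),
                             threshold = NA_real_) {
  tag <- match.arg(tag)
  new("ConnectionMethod", tag = tag, threshold = as.numeric(threshold))
}

.checkHistogramList <- function(histograms) {
  if (length(histograms) < 1L) stop("need at least one histogram")
  if (!all(vapply(histograms, is, logical(1), class2 = "FeatureHistogram")))
    stop("histograms must all be FeatureHistogram objects")
  k <- vapply(histograms, nBins, integer(1))
  if (any(k != k[1]))
    stop(sprintf("mismatched bin counts across slices: %s",
                 paste(unique(k), collapse = " vs ")))
  k[1]
}

#' Slice-chain connection: concatenate per-slice histograms
#'
#' Keeps each slice's histogram separate; the feature length scales with
#' the slice count (S * K), so SVM inference cost scales with S.
#'
#' @param histograms list of S [FeatureHistogram-class] sharing a bin count K
#' @return a [VolumeFeature-class] of length S * K
#' @export
connectSliceChain <- function(histograms) {
  k <- .checkHistogramList(histograms)
  new("VolumeFeature",
      values = unlist(lapply(histograms, binCounts), use.names = FALSE),
      method = connectionMethod("slice_chain"), nBins = k,
      saturated = any(vapply(histograms, isSaturated, logical(1))))
}

#' Slice-sum connection: element-wise sum of per-slice histograms
#'
#' Extends the histogram statistic over the whole volume: occurrences of
#' the same texture type scattered across slices share one counter. The
#' feature length stays K regardless of S, cutting SVM inference cost by
#' a factor of S (100 for the reference geometry) relative to
#' slice-chain.
#'
#' @param histograms list of S [FeatureHistogram-class] sharing a bin count K
#' @return a [VolumeFeature-class] of length K
#' @export
connectSliceSum <- function(histograms) {
  k <- .checkHistogramList(histograms)
  values <- Reduce(`+`, lapply(histograms, binCounts))
  new("VolumeFeature", values = values,
      method = connectionMethod("slice_sum"), nBins = k,
      saturated = any(vapply(histograms, isSaturated, logical(1))))
}

#' Slice-threshold decision: vote over per-slice predictions
#'
#' The volume is labelled abnormal iff strictly more than `threshold`
#' slices were predicted abnormal.
#'
#' @param slicePredictions character vector of per-slice labels
#'   ("normal"/"amd")
#' @param threshold vote threshold in \[0, S\]; default `floor(S/2)`
#'   (majority)
#' @return "amd" or "normal"
#' @export
decideSliceThreshold <- function(slicePredictions, threshold = NULL) {
  S <- length(slicePredictions)
  if (S < 1L) stop("need at least one slice prediction")
  if (!all(slicePredictions %in% .LABELS))
    stop("slice predictions must be 'normal' or 'amd'")
  if (is.null(threshold) || is.na(threshold)) threshold <- floor(S / 2)
  if (threshold < 0 || threshold > S)
    stop(sprintf("threshold %s out of range [0, %d]", format(threshold), S))
  if (sum(slicePredictions == "amd") > threshold) "amd" else "normal"
}

#' Extract the volume-level feature for a connection method
#'
#' Convenience wrapper: per-slice histograms via the variant LUT, then
#' slice-chain or slice-sum aggregation. The slice-threshold method has
#' no single volume feature (it votes over per-slice predictions); use
#' [volumeHistograms()] and a per-slice model for it.
#'
#' @param volume an [OCTVolume-class]
#' @param variant LBP variant tag (default "ri")
#' @param method a [ConnectionMethod-class] or tag string
#' @param counterWidth histogram counter width in bits, or `Inf`
#' @return a [VolumeFeature-class]
#' @export
extractFeature <- function(volume, variant = "ri",
                           method = connectionMethod("slice_sum"),
                           counterWidth = Inf) {
  if (is.character(method)) method <- connectionMethod(method)
  lut <- buildLUT(variant)
  if (method@tag == "slice_sum") {
    h <- volumeHistogram(volume, lut, counterWidth)
    return(new("VolumeFeature", values = binCounts(h),
               method = method, nBins = lut@nBins,
               saturated = isSaturated(h)))
  }
  if (method@tag == "slice_chain")
    return(connectSliceChain(volumeHistograms(volume, lut, counterWidth)))
  stop("slice_threshold has no single volume feature; see volumeHistograms()")
}

#' Feature matrix for a collection of volumes
#'
#' One row per volume, built with [extractFeature()].
#'
#' @param volumes list of [OCTVolume-class]
#' @inheritParams extractFeature
#' @return list with `features` (n x p matrix), `labels` (character,
#'   NA where unknown) and `saturated` (logical per volume)
#' @export
featureMatrix <- function(volumes, variant = "ri",
                          method = connectionMethod("slice_sum"),
                          counterWidth = Inf) {
  feats <- lapply(volumes, extractFeature, variant = variant,
                  method = method, counterWidth = counterWidth)
  list(features = do.call(rbind, lapply(feats, featureValues)),
       labels = vapply(volumes, volumeLabel, character(1)),
       saturated = vapply(feats, isSaturated, logical(1)))
}
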