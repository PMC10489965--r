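#' @import methods
NULL

.VARIANTS <- c("classic", "ri", "u2", "riu2")
.VARIANT_BINS <- c(classic = 256L, ri = 36L, u2 = 59L, riu2 = 10L)
.CONNECT_METHODS <- c("slice_chain", "slice_threshold", "slice_sum")
.LABELS <- c("normal", "amd")

#' OCTVolume: an ordered stack of greyscale B-scan slices
#'
#' The unit of classification. Slices are integer matrices with values in
#' \[0, 255\]; all slices share the same height and width. The optional
#' `classLabel` ("normal" or "amd") carries ground truth for training and
#' evaluation.
#'
#' @slot slices list of H x W integer matrices, values in \[0, 255\]
#' @slot id opaque volume identifier
#' @slot classLabel "normal", "amd", or NA when unknown
#' @exportClass OCTVolume
setClass("OCTVolume",
  representation(slices = "list", id = "character", classLabel = "character"),
  prototype(slices = list(), id = NA_character_, classLabel = NA_character_)
)

setValidity("OCTVolume", function(object) {
  s <- object@slices
  if (length(s) < 1L) return("a volume needs at least one slice")
  dims <- vapply(s, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all slices must share the same dimensions")
  for (i in seq_along(s)) {
    if (!is.matrix(s[[i]]) || !is.numeric(s[[i]]))
      return(sprintf("slice %d is not a numeric matrix", i))
    if (anyNA(s[[i]]) || any(s[[i]] < 0) || any(s[[i]] > 255))
      return(sprintf("slice %d has pixel values outside [0, 255]", i))
  }
  if (!is.na(object@classLabel) && !object@classLabel %in% .LABELS)
    return("classLabel must be 'normal', 'amd', or NA")
  TRUE
})

#' VariantLUT: 256-entry lookup table for an LBP variant mapping
#'
#' Maps every raw 8-bit LBP code (0..255) to a histogram bin index
#' (0-based). The mapping is surjective onto `0:(nBins-1)`; for the
#' classic variant it is the identity.
#'
#' @slot variant one of "classic", "ri", "u2", "riu2"
#' @slot table integer vector of length 256, bin index per raw code
#' @slot nBins number of distinct bins (256 / 36 / 59 / 10)
#' @exportClass VariantLUT
setClass("VariantLUT",
  representation(variant = "character", table = "integer", nBins = "integer")
)

setValidity("VariantLUT", function(object) {
  if (!object@variant %in% .VARIANTS)
    return(sprintf("unknown variant '%s'", object@variant))
  if (length(object@table) != 256L) return("table must have exactly 256 entries")
  if (any(object@table < 0L) || any(object@table >= object@nBins))
    return("table entries must lie in [0, nBins)")
  if (length(unique(object@table)) != object@nBins)
    return("table must be surjective onto [0, nBins)")
  if (object@nBins != .VARIANT_BINS[[object@variant]])
    return(sprintf("variant '%s' must have %d bins", object@variant,
                   .VARIANT_BINS[[object@variant]]))
  TRUE
})

#' FeatureHistogram: per-bin occurrence counts with saturating-counter
#' semantics
#'
#' Counts how often each texture bin occurred while the 3x3 window swept an
#' image (or a whole volume). With a finite `counterWidth` of b bits each
#' counter clamps at 2^b - 1, mirroring the hardware's statistic-saturation
#' behaviour; `saturated` is TRUE iff at least one increment was dropped.
#'
#' @slot counts non-negative counts, one per bin
#' @slot counterWidth counter width in bits; `Inf` means unlimited
#' @slot saturated TRUE iff some counter clamped and dropped an increment
#' @slot variant the LBP variant the bins belong to
#' @exportClass FeatureHistogram
setClass("FeatureHistogram",
  representation(counts = "numeric", counterWidth = "numeric",
                 saturated = "logical", variant = "character")
)

setValidity("FeatureHistogram", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@counterWidth) != 1L || object@counterWidth < 1)
    return("counterWidth must be a single value >= 1 (Inf for unlimited)")
  if (is.finite(object@counterWidth) &&
      any(object@counts > 2^object@counterWidth - 1))
    return("counts exceed the counter ceiling")
  TRUE
})

#' ConnectionMethod: how per-slice histograms combine into a volume decision
#'
#' @slot tag "slice_chain", "slice_threshold", or "slice_sum"
#' @slot threshold positive-slice vote threshold (slice_threshold only;
#'   NA elsewhere). The volume is called abnormal iff strictly more than
#'   `threshold` slices are predicted abnormal.
#' @exportClass ConnectionMethod
setClass("ConnectionMethod",
  representation(tag = "character", threshold = "numeric"),
  prototype(threshold = NA_real_)
)

setValidity("ConnectionMethod", function(object) {
  if (!object@tag %in% .CONNECT_METHODS)
    return(sprintf("unknown connection method '%s'", object@tag))
  if (object@tag == "slice_threshold" && !is.na(object@threshold) &&
      object@threshold < 0)
    return("threshold must be >= 0")
  TRUE
})

#' VolumeFeature: volume-level feature vector
#'
#' Length is S*K for slice-chain and K for slice-sum, where K is the LUT
#' bin count and S the slice count. Saturation flags propagate from the
#' contributing histograms.
#'
#' @slot values non-negative counts
#' @slot method the ConnectionMethod that produced the feature
#' @slot nBins bins per slice histogram (K)
#' @slot saturated TRUE iff any contributing histogram saturated
#' @exportClass VolumeFeature
setClass("VolumeFeature",
  representation(values = "numeric", method = "ConnectionMethod",
                 nBins = "integer", saturated = "logical")
)

#' DualSolution: support samples, labels and Lagrange multipliers
#'
#' The dual form of a trained linear SVM, from which the primal weight
#' vector and bias are reconstructed.
#'
#' @slot samples k x p matrix of support samples (one row per support point)
#' @slot labels length-k vector in \{-1, +1\}
#' @slot multipliers length-k vector of non-negative Lagrange multipliers
#' @exportClass DualSolution
setClass("DualSolution",
  representation(samples = "matrix", labels = "numeric", multipliers = "numeric")
)

setValidity("DualSolution", function(object) {
  k <- nrow(object@samples)
  if (k < 1L) return("at least one support point is required")
  if (length(object@labels) != k || length(object@multipliers) != k)
    return("labels and multipliers must have one entry per sample row")
  if (!all(object@labels %in% c(-1, 1))) return("labels must be -1 or +1")
  if (any(object@multipliers < 0)) return("multipliers must be non-negative")
  TRUE
})

#' LinearSVMModel: weight vector, bias and label convention
#'
#' Prediction is sign(weights . feature + bias); a score of exactly zero is
#' assigned to the positive class. `labelMap` records which class sits on
#' each side of the hyperplane (positive = "amd" by default).
#'
#' @slot weights weight vector, one entry per feature element
#' @slot bias scalar bias
#' @slot labelMap named character vector c(positive = ..., negative = ...)
#' @slot variant LBP variant provenance (or NA)
#' @slot method connection-method provenance (or NA)
#' @slot dual the DualSolution the model was derived from, or NULL
#' @exportClass LinearSVMModel
setClass("LinearSVMModel",
  representation(weights = "numeric", bias = "numeric", labelMap = "character",
                 variant = "character", method = "character", dual = "ANY"),
  prototype(labelMap = c(positive = "amd", negative = "normal"),
            variant = NA_character_, method = NA_character_, dual = NULL)
)

setValidity("LinearSVMModel", function(object) {
  if (length(object@weights) < 1L) return("weights must be non-empty")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    return("bias must be a single finite number")
  if (!all(c("positive", "negative") %in% names(object@labelMap)))
    return("labelMap needs 'positive' and 'negative' entries")
  TRUE
})

#' FixedPointFormat: signedness, bit widths and overflow/rounding modes
#'
#' A signed format with I integer and F fraction bits spans raw integers
#' \[-2^(I+F), 2^(I+F)-1\] (the sign bit is extra, total width 1+I+F);
#' unsigned spans \[0, 2^(I+F)-1\]. Real values are raw * 2^-F. Rounding is
#' truncation toward -Inf (the hardware LSB drop); overflow either
#' saturates at the range limits or wraps in two's complement.
#'
#' @slot signed TRUE for two's-complement signed
#' @slot integerBits integer bits (>= 0)
#' @slot fractionBits fraction bits (>= 0)
#' @slot overflow "saturate" or "wrap"
#' @slot rounding "truncate"
#' @exportClass FixedPointFormat
setClass("FixedPointFormat",
  representation(signed = "logical", integerBits = "integer",
                 fractionBits = "integer", overflow = "character",
                 rounding = "character"),
  prototype(overflow = "saturate", rounding = "truncate")
)

setValidity("FixedPointFormat", function(object) {
  if (object@integerBits < 0L || object@fractionBits < 0L)
    return("bit counts must be >= 0")
  if (object@integerBits + object@fractionBits + as.integer(object@signed) < 1L)
    return("total width must be >= 1 bit")
  if (!object@overflow %in% c("saturate", "wrap"))
    return("overflow must be 'saturate' or 'wrap'")
  if (!identical(object@rounding, "truncate"))
    return("only truncation rounding is supported")
  TRUE
})

#' QuantizedModel: a linear SVM with fixed-point formats per operand
#'
#' Carries one FixedPointFormat for each of the feature vector, the
#' weights, the bias, and the accumulator. The accumulator format is
#' always stated explicitly; the constructor derives a provably
#' overflow-free default when none is given.
#'
#' @slot model the underlying LinearSVMModel
#' @slot featureFormat format applied to the feature vector
#' @slot weightFormat format applied to the weights
#' @slot biasFormat format applied to the bias
#' @slot accumulatorFormat format of the multiply-accumulate register
#' @exportClass QuantizedModel
setClass("QuantizedModel",
  representation(model = "LinearSVMModel", featureFormat = "FixedPointFormat",
                 weightFormat = "FixedPointFormat", biasFormat = "FixedPointFormat",
                 accumulatorFormat = "FixedPointFormat")
)

#' SyntheticSpec: parameters of the synthetic OCT-like volume generator
#'
#' @slot S,H,W volume geometry (slices, height, width)
#' @slot separation class-contrast knob in \[0, 1\]; 0 makes the two class
#'   generators identical, larger values grow the AMD-specific layer
#'   displacement and texture disruption
#' @slot noiseSd additive speckle-like noise scale, intensity units
#' @slot nNormal,nAmd volume counts per class
#' @slot seed master seed for reproducible generation
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(S = "integer", H = "integer", W = "integer",
                 separation = "numeric", noiseSd = "numeric",
                 nNormal = "integer", nAmd = "integer", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  if (object@S < 1L || object@H < 3L || object@W < 3L)
    return("geometry must satisfy S >= 1, H >= 3, W >= 3")
  if (object@separation < 0 || object@separation > 1)
    return("separation must lie in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nNormal < 0L || object@nAmd < 0L) return("counts must be >= 0")
  TRUE
})
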