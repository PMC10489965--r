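# Bit-accurate fixed-point simulation of linear SVM inference: operand
# quantization, integer multiply-accumulate, and the word-length sweep.
#
# Raw integers are carried in doubles; all raw values and products stay
# far below 2^53 for any format the sweep visits, so arithmetic is exact.

#' Fixed-point format constructor
#'
#' @param signed TRUE for two's-complement signed (sign bit extra)
#' @param integerBits integer bits I (>= 0)
#' @param fractionBits fraction bits F (>= 0)
#' @param overflow "saturate" (default) or "wrap"
#' @return a [FixedPointFormat-class]; raw range is
#'   \[-2^(I+F), 2^(I+F)-1\] signed, \[0, 2^(I+F)-1\] unsigned, value =
#'   raw * 2^-F
#' @export
fixedPointFormat <- function(signed = TRUE, integerBits = 8L,
                             fractionBits = 0L, overflow = "saturate") {
  new("FixedPointFormat", signed = signed,
      integerBits = as.integer(integerBits),
      fractionBits = as.integer(fractionBits),
      overflow = overflow, rounding = "truncate")
}

.fpRange <- function(fmt) {
  mag <- 2^(fmt@integerBits + fmt@fractionBits)
  if (fmt@signed) c(-mag, mag - 1) else c(0, mag - 1)
}

.fpSpan <- function(fmt) {
  2^(fmt@integerBits + fmt@fractionBits + as.integer(fmt@signed))
}

# raw-domain overflow handling; returns list(raw, overflowed)
.fpHandle <- function(raw, fmt) {
  rng <- .fpRange(fmt)
  over <- raw < rng[1] | raw > rng[2]
  if (any(over)) {
    if (fmt@overflow == "saturate") {
      raw <- pmin(pmax(raw, rng[1]), rng[2])
    } else {
      span <- .fpSpan(fmt)
      raw <- ((raw - rng[1]) %% span) + rng[1]
    }
  }
  list(raw = raw, overflowed = over)
}

#' Quantize real values to a fixed-point format
#'
#' Each value is scaled by 2^fractionBits and truncated toward -Inf
#' (floor — the two's-complement LSB drop), then range-limited according
#' to the format's overflow mode. Negative inputs to an unsigned format
#' overflow and are handled (and reported) like any other overflow.
#'
#' @param values numeric vector
#' @param format a [FixedPointFormat-class]
#' @return list with `values` (quantized reals, raw * 2^-F), `raw`
#'   (integers in the raw domain) and `overflow` (indices that
#'   overflowed)
#' @export
quantize <- function(values, format) {
  stopifnot(is(format, "FixedPointFormat"))
  raw <- floor(values * 2^format@fractionBits)
  h <- .fpHandle(raw, format)
  list(values = h$raw * 2^(-format@fractionBits), raw = h$raw,
       overflow = which(h$overflowed))
}

#' Quantized model constructor
#'
#' Wraps a linear SVM model with one fixed-point format per operand.
#' When `accumulatorFormat` is NULL a provably overflow-free default is
#' derived and stored explicitly: total accumulator width = feature
#' width + weight width + ceil(log2(feature length)) + 1, at the
#' product's fraction scale.
#'
#' @param model a [LinearSVMModel-class]
#' @param featureFormat,weightFormat,biasFormat
#'   [FixedPointFormat-class] per operand
#' @param accumulatorFormat accumulator [FixedPointFormat-class], or
#'   NULL for the derived default
#' @return a [QuantizedModel-class]
#' @export
quantizedModel <- function(model, featureFormat, weightFormat, biasFormat,
                           accumulatorFormat = NULL) {
  stopifnot(is(model, "LinearSVMModel"))
  if (is.null(accumulatorFormat)) {
    fw <- featureFormat@integerBits + featureFormat@fractionBits +
      as.integer(featureFormat@signed)
    ww <- weightFormat@integerBits + weightFormat@fractionBits +
      as.integer(weightFormat@signed)
    fracAcc <- featureFormat@fractionBits + weightFormat@fractionBits
    totalAcc <- fw + ww + ceiling(log2(max(2, length(model@weights)))) + 1L
    accumulatorFormat <- fixedPointFormat(
      signed = TRUE, integerBits = max(0L, as.integer(totalAcc) - 1L -
                                         as.integer(fracAcc)),
      fractionBits = fracAcc, overflow = weightFormat@overflow)
  }
  new("QuantizedModel", model = model, featureFormat = featureFormat,
      weightFormat = weightFormat, biasFormat = biasFormat,
      accumulatorFormat = accumulatorFormat)
}

# align a raw value from fraction scale fFrom to fTo by exact shift up or
# truncating shift down
.alignRaw <- function(raw, fFrom, fTo) {
  if (fTo >= fFrom) raw * 2^(fTo - fFrom) else floor(raw / 2^(fFrom - fTo))
}

# core fixed-point MAC; NULL formats mean full precision (used by the
# word-length sweep to hold components at float)
.quantPredictCore <- function(model, x, featFmt, wFmt, bFmt, accFmt) {
  nOver <- 0L
  fFeat <- if (is.null(featFmt)) 0L else featFmt@fractionBits
  fW <- if (is.null(wFmt)) 0L else wFmt@fractionBits
  if (is.null(featFmt)) xr <- x else {
    q <- quantize(x, featFmt); xr <- q$raw; nOver <- nOver + length(q$overflow)
  }
  if (is.null(wFmt)) wr <- model@weights else {
    q <- quantize(model@weights, wFmt); wr <- q$raw
    nOver <- nOver + length(q$overflow)
  }
  prodFrac <- fFeat + fW
  if (is.null(bFmt)) {
    br <- model@bias * 2^prodFrac
  } else {
    q <- quantize(model@bias, bFmt)
    nOver <- nOver + length(q$overflow)
    br <- .alignRaw(q$raw, bFmt@fractionBits, prodFrac)
  }
  if (is.null(accFmt)) {
    acc <- br + sum(wr * xr)
  } else {
    if (accFmt@fractionBits != prodFrac)
      stop("accumulator fraction bits must equal the product fraction scale")
    h <- .fpHandle(br, accFmt); acc <- h$raw
    nOver <- nOver + sum(h$overflowed)
    for (i in seq_along(xr)) {
      h <- .fpHandle(acc + wr[i] * xr[i], accFmt)
      acc <- h$raw
      nOver <- nOver + sum(h$overflowed)
    }
  }
  list(label = .scoreLabel(model, acc), raw = acc,
       scale = 2^(-prodFrac), nOverflows = nOver)
}

#' Fixed-point prediction
#'
#' Quantizes the feature vector, weights and bias to their formats, runs
#' the multiply-accumulate sequentially in integer arithmetic in the
#' accumulator format (bias first, then one product per cycle), and
#' reads the label off the accumulator's sign bit.
#'
#' @param object a [QuantizedModel-class]
#' @param feature a [VolumeFeature-class] or numeric vector
#' @param ... ignored
#' @return list with `label`, integer `score` (raw accumulator),
#'   `scale` (value of one accumulator LSB) and `nOverflows`
#' @export
setMethod("predict", "QuantizedModel", function(object, feature, ...) {
  x <- .featureVector(feature)
  .checkLengths(object@model, x)
  .quantPredictCore(object@model, x, object@featureFormat,
                    object@weightFormat, object@biasFormat,
                    object@accumulatorFormat)
})

#' Word-length sweep of one operand
#'
#' Reproduces the sequential word-length exploration: components are
#' fixed in the order feature vector, then weights, then bias. The swept
#' component is quantized at each candidate width while the others stay
#' at full float precision unless a fixed format is supplied in `fixed`.
#' Width semantics per component: for the integer-valued feature vector
#' the width is the unsigned integer bit count (fraction 0); for weights
#' and bias the width is the number of retained fraction bits, with
#' integer bits held at the smallest count covering the float values.
#'
#' @param model a [LinearSVMModel-class]
#' @param features n x p matrix of (integer-valued) volume features
#' @param labels length-n true labels ("normal"/"amd")
#' @param component "feature", "weights" or "bias"
#' @param widths integer vector of candidate widths (non-empty)
#' @param fixed named list with optional entries `feature`, `weights`,
#'   `bias` holding formats already frozen by earlier sweep stages
#' @param overflow overflow mode for the swept formats
#' @return data.frame with columns component, width, accuracy (percent),
#'   n_overflows
#' @export
wordlengthSweep <- function(model, features, labels,
                            component = c("feature", "weights", "bias"),
                            widths, fixed = list(), overflow = "saturate") {
  component <- match.arg(component)
  if (length(widths) < 1L) stop("width range must be non-empty")
  features <- as.matrix(features)
  stopifnot(length(labels) == nrow(features))
  intBitsFor <- function(v) max(1L, ceiling(log2(max(abs(v)) + 1)) + 1L)
  fmts <- list(feature = fixed$feature %||% NULL,
               weights = fixed$weights %||% NULL,
               bias = fixed$bias %||% NULL)
  rows <- lapply(as.integer(widths), function(wd) {
    f <- fmts
    f[[component]] <- switch(component,
      feature = fixedPointFormat(FALSE, integerBits = wd, fractionBits = 0L,
                                 overflow = overflow),
      weights = fixedPointFormat(TRUE, integerBits = intBitsFor(model@weights),
                                 fractionBits = wd, overflow = overflow),
      bias = fixedPointFormat(TRUE, integerBits = intBitsFor(model@bias),
                              fractionBits = wd, overflow = overflow))
    nOver <- 0L
    pred <- character(nrow(features))
    for (i in seq_len(nrow(features))) {
      r <- .quantPredictCore(model, features[i, ], f$feature, f$weights,
                             f$bias, NULL)
      pred[i] <- r$label
      nOver <- nOver + r$nOverflows
    }
    data.frame(component = component, width = wd,
               accuracy = unname(classificationMetrics(labels, pred)["acc"]),
               n_overflows = nOver)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
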