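# Linear SVM: weights/bias from the dual solution, sign prediction, the
# sequential multiply-accumulate emulation of the hardware datapath,
# training via libsvm, and K-fold evaluation.

#' Dual solution constructor
#'
#' @param samples k x p matrix of support samples (rows)
#' @param labels length-k vector in \{-1, +1\}
#' @param multipliers length-k non-negative Lagrange multipliers
#' @return a [DualSolution-class]
#' @export
dualSolution <- function(samples, labels, multipliers) {
  new("DualSolution", samples = as.matrix(samples),
      labels = as.numeric(labels), multipliers = as.numeric(multipliers))
}

#' Weight vector from a dual solution
#'
#' \eqn{w_j = \sum_{i=1}^{k} \alpha_i\, y_i\, x_{i,j}}: the weighted sum
#' of support samples.
#'
#' @param dual a [DualSolution-class]
#' @return numeric weight vector of length p
#' @export
weightsFromDual <- function(dual) {
  stopifnot(is(dual, "DualSolution"))
  as.numeric(crossprod(dual@samples, dual@multipliers * dual@labels))
}

#' Bias from a dual solution and weight vector
#'
#' The mean over support points of (label minus the point's projection on
#' the weights): \eqn{b = \mathrm{mean}_i\,(y_i - x_i \cdot w)}. For
#' hard-margin problems every support point lies on its margin, so the
#' mean is exact.
#'
#' @param dual a [DualSolution-class]
#' @param weights weight vector of length p
#' @return numeric bias
#' @export
biasFromDual <- function(dual, weights) {
  stopifnot(is(dual, "DualSolution"))
  if (length(weights) != ncol(dual@samples))
    stop(sprintf("weights length %d does not match sample width %d",
                 length(weights), ncol(dual@samples)))
  mean(dual@labels - as.numeric(dual@samples %*% weights))
}

#' Linear SVM model constructor
#'
#' @param weights weight vector
#' @param bias scalar bias
#' @param labelMap named character c(positive = , negative = ); the
#'   positive side of the hyperplane (score >= 0) maps to
#'   `labelMap["positive"]`
#' @param variant,method optional provenance tags
#' @param dual optional [DualSolution-class] the model derives from
#' @return a [LinearSVMModel-class]
#' @export
linearSVMModel <- function(weights, bias,
                           labelMap = c(positive = "amd", negative = "normal"),
                           variant = NA_character_, method = NA_character_,
                           dual = NULL) {
  new("LinearSVMModel", weights = as.numeric(weights),
      bias = as.numeric(bias), labelMap = labelMap,
      variant = as.character(variant), method = as.character(method),
      dual = dual)
}

.featureVector <- function(feature) {
  if (is(feature, "VolumeFeature")) featureValues(feature) else
    as.numeric(feature)
}

.checkLengths <- function(model, x) {
  if (length(model@weights) != length(x))
    stop(sprintf("feature length %d does not match model weight length %d",
                 length(x), length(model@weights)))
}

#' Predict the class of a volume feature
#'
#' Score = weights . feature + bias; the label is taken from the sign of
#' the score, with a score of exactly zero assigned to the positive
#' class (mirroring the unit step's u(0) = 1 convention).
#'
#' @param object a [LinearSVMModel-class]
#' @param feature a [VolumeFeature-class] or numeric vector matching the
#'   weight length
#' @param ... ignored
#' @return list with `label`, raw `score`, and `saturated` (the feature's
#'   saturation flag, FALSE for plain vectors)
#' @export
setMethod("predict", "LinearSVMModel", function(object, feature, ...) {
  x <- .featureVector(feature)
  .checkLengths(object, x)
  score <- sum(object@weights * x) + object@bias
  list(label = .scoreLabel(object, score), score = score,
       saturated = if (is(feature, "VolumeFeature")) isSaturated(feature)
                   else FALSE)
})

.scoreLabel <- function(model, score) {
  unname(if (score >= 0) model@labelMap[["positive"]]
         else model@labelMap[["negative"]])
}

#' Sequential multiply-accumulate prediction
#'
#' Emulates the chip's datapath: a single multiplier, the bias loaded as
#' the first addend, then one multiply-accumulate per feature element in
#' index order (36 cycles for an LBP-RI slice-sum feature). Algebraically
#' identical to [predict()]; the returned trace holds the accumulator
#' after each step.
#'
#' @param model a [LinearSVMModel-class]
#' @param feature a [VolumeFeature-class] or numeric vector
#' @return list with `label`, `score` and `trace` (length = feature
#'   length)
#' @export
predictSequential <- function(model, feature) {
  stopifnot(is(model, "LinearSVMModel"))
  x <- .featureVector(feature)
  if (length(x) == 0L) stop("empty feature vector")
  .checkLengths(model, x)
  acc <- model@bias
  trace <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- acc + model@weights[i] * x[i]
    trace[i] <- acc
  }
  list(label = .scoreLabel(model, acc), score = acc, trace = trace)
}

.toPm1 <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    return(as.numeric(labels))
  }
  if (!all(labels %in% .LABELS))
    stop("labels must be 'normal'/'amd' (or -1/+1)")
  ifelse(labels == "amd", 1, -1)
}

#' Train a soft-margin linear SVM and derive the explicit model
#'
#' Fits libsvm's C-classification with a linear kernel on the raw
#' (unscaled) features, extracts the dual solution (support samples,
#' labels, Lagrange multipliers), and reconstructs the primal weight
#' vector and bias from it with [weightsFromDual()] and
#' [biasFromDual()]. The label convention is +1 = "amd", -1 = "normal".
#'
#' @param features n x p numeric matrix, one volume feature per row
#' @param labels length-n labels, "normal"/"amd" or -1/+1
#' @param cost soft-margin regularisation strength C (default 1)
#' @param variant,method optional provenance tags stored on the model
#' @return a [LinearSVMModel-class] with its [DualSolution-class] in the
#'   `dual` slot
#' @export
trainLinear <- function(features, labels, cost = 1,
                        variant = NA_character_, method = NA_character_) {
  features <- as.matrix(features)
  y <- .toPm1(labels)
  if (length(y) != nrow(features))
    stop("one label per feature row is required")
  if (length(unique(y)) < 2L)
    stop("training needs at least one sample of each class")
  yf <- factor(ifelse(y > 0, "amd", "normal"), levels = c("amd", "normal"))
  fit <- e1071::svm(features, yf, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  # libsvm coefs are alpha_i * y_i with +1 assigned to whichever class
  # appears first in the data (fit$labels gives the internal order);
  # normalise so that +1 = amd regardless of row order
  coefs <- as.numeric(fit$coefs)
  if (fit$levels[fit$labels[1]] == "normal") coefs <- -coefs
  dual <- dualSolution(samples = as.matrix(fit$SV),
                       labels = sign(coefs), multipliers = abs(coefs))
  w <- weightsFromDual(dual)
  b <- biasFromDual(dual, w)
  linearSVMModel(w, b, variant = variant, method = method, dual = dual)
}

#' Classification metrics with AMD as the positive class
#'
#' @param truth,predicted character vectors of "normal"/"amd"
#' @return named numeric: `acc`, `se` (sensitivity), `sp` (specificity),
#'   as percentages
#' @export
classificationMetrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == "amd"
  se <- if (any(pos)) mean(predicted[pos] == "amd") else NA_real_
  sp <- if (any(!pos)) mean(predicted[!pos] == "normal") else NA_real_
  c(acc = 100 * mean(truth == predicted), se = 100 * se, sp = 100 * sp)
}

#' K-fold cross-validated evaluation of the pipeline
#'
#' Randomly partitions the labelled volumes into K subsets; each serves
#' once as the test set while the others train the model. For slice-chain
#' and slice-sum, volume features feed one SVM. For slice-threshold, a
#' per-slice SVM is trained on slice histograms with each volume's label
#' broadcast to its slices, and volumes are decided by the vote rule of
#' [decideSliceThreshold()]. The partition is reproducible from `seed`.
#'
#' @param volumes list of labelled [OCTVolume-class]
#' @param K fold count, 2 <= K <= number of volumes (default 5)
#' @param seed partition seed
#' @param variant LBP variant tag
#' @param method a [ConnectionMethod-class] or tag string
#' @param cost SVM regularisation strength
#' @param counterWidth histogram counter width in bits, or `Inf`
#' @return list with `folds` (data.frame fold/acc/se/sp), `mean` (named
#'   numeric acc/se/sp), and `assignment` (fold id per volume)
#' @export
kfoldEvaluate <- function(volumes, K = 5, seed = 1L, variant = "ri",
                          method = connectionMethod("slice_sum"),
                          cost = 1, counterWidth = Inf) {
  if (is.character(method)) method <- connectionMethod(method)
  n <- length(volumes)
  if (K < 2 || K > n)
    stop(sprintf("K = %s out of range [2, %d]", format(K), n))
  labels <- vapply(volumes, volumeLabel, character(1))
  if (anyNA(labels)) stop("all volumes must be labelled")
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(K), n))
  lut <- buildLUT(variant)
  sliceMode <- method@tag == "slice_threshold"
  if (sliceMode) {
    histList <- lapply(volumes, function(v)
      do.call(rbind, lapply(volumeHistograms(v, lut, counterWidth),
                            binCounts)))
  } else {
    fm <- featureMatrix(volumes, variant, method, counterWidth)
  }
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    test <- which(assignment == k)
    train <- which(assignment != k)
    if (sliceMode) {
      xTrain <- do.call(rbind, histList[train])
      yTrain <- rep(labels[train],
                    vapply(histList[train], nrow, integer(1)))
      model <- trainLinear(xTrain, yTrain, cost = cost,
                           variant = variant, method = method@tag)
      pred <- vapply(test, function(i) {
        sliceLabs <- apply(histList[[i]], 1L, function(f)
          predict(model, f)$label)
        decideSliceThreshold(sliceLabs, method@threshold)
      }, character(1))
    } else {
      model <- trainLinear(fm$features[train, , drop = FALSE],
                           labels[train], cost = cost,
                           variant = variant, method = method@tag)
      pred <- apply(fm$features[test, , drop = FALSE], 1L, function(f)
        predict(model, f)$label)
    }
    rows[[k]] <- c(fold = k, classificationMetrics(labels[test], pred))
  }
  folds <- as.data.frame(do.call(rbind, rows))
  list(folds = folds,
       mean = colMeans(folds[, c("acc", "se", "sp")], na.rm = TRUE),
       assignment = assignment)
}
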