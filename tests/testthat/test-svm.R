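test_that("weightsFromDual applies the weighted support-sample sum", {
  d <- dualSolution(rbind(c(2, 3)), 1, 1)
  expect_equal(weightsFromDual(d), c(2, 3))
  d2 <- dualSolution(rbind(c(1, 1), c(1, 1)), c(1, -1), c(1, 1))
  expect_equal(weightsFromDual(d2), c(0, 0))     # exact cancellation
  expect_error(dualSolution(matrix(numeric(0), 0, 2), numeric(0),
                            numeric(0)), "at least one")
})

test_that("biasFromDual averages label minus projection", {
  d <- dualSolution(rbind(c(1, 0)), 1, 1)
  expect_equal(biasFromDual(d, c(1, 0)), 0)
  d2 <- dualSolution(rbind(c(1, 0), c(-1, 0)), c(1, -1), c(1, 1))
  expect_equal(biasFromDual(d2, c(1, 0)), 0)
  expect_error(biasFromDual(d2, c(1, 0, 0)), "does not match")
})

test_that("dual-derived weights and bias match an independent QP oracle", {
  dual <- toyQPDual()
  w <- weightsFromDual(dual)
  b <- biasFromDual(dual, w)
  # analytic hard-margin solution of the toy problem: x1 = 1 boundary
  expect_equal(w, c(1, 0), tolerance = 1e-6)
  expect_equal(b, -1, tolerance = 1e-6)
  # the derived hyperplane reproduces the labels of all four training points
  scores <- as.numeric(dual@samples %*% w + b)
  expect_identical(sign(scores), dual@labels)
})

test_that("predict scores by dot product and maps sign to labels", {
  m0 <- linearSVMModel(c(0, 0), 1)
  expect_identical(predict(m0, c(10, -4))$label, "amd")
  m <- linearSVMModel(c(1, -1), 0)
  r <- predict(m, c(3, 5))
  expect_equal(r$score, -2)
  expect_identical(r$label, "normal")
  expect_identical(predict(m, c(5, 5))$label, "amd")   # score 0 -> positive
  expect_error(predict(m, c(1, 2, 3)), "3.*2|2.*3")    # both lengths named
})

test_that("sequential MAC emulation is identical to direct prediction", {
  set.seed(21)
  for (i in 1:100) {
    p <- sample(2:40, 1)
    m <- linearSVMModel(rnorm(p), rnorm(1))
    x <- sample(0:500, p, replace = TRUE)
    ds <- predictSequential(m, x)
    dd <- predict(m, x)
    expect_identical(ds$label, dd$label)
    expect_equal(ds$score, dd$score)
    expect_length(ds$trace, p)
    expect_equal(ds$trace[p], ds$score)
  }
  expect_error(predictSequential(linearSVMModel(1, 0), numeric(0)), "empty")
})

test_that("trainLinear separates a toy set and is stable to duplication", {
  set.seed(22)
  x <- rbind(matrix(rnorm(40, 4), 20), matrix(rnorm(40, -4), 20))
  y <- rep(c("amd", "normal"), each = 20)
  m <- trainLinear(x, y)
  pred <- apply(x, 1, function(f) predict(m, f)$label)
  expect_identical(pred, y)
  # duplicating every sample leaves the decision pattern unchanged
  m2 <- trainLinear(rbind(x, x), c(y, y))
  pred2 <- apply(x, 1, function(f) predict(m2, f)$label)
  expect_identical(pred2, pred)
  # positive scale of the features leaves training-set decisions unchanged
  m3 <- trainLinear(x * 10, y)
  pred3 <- apply(x * 10, 1, function(f) predict(m3, f)$label)
  expect_identical(pred3, pred)
  expect_error(trainLinear(x, rep("amd", 40)), "each class")
})

test_that("trainLinear reproduces its weights through Eq-style dual", {
  set.seed(23)
  x <- rbind(matrix(rnorm(30, 3), 15), matrix(rnorm(30, -3), 15))
  y <- rep(c("amd", "normal"), each = 15)
  m <- trainLinear(x, y)
  expect_s4_class(m@dual, "DualSolution")
  expect_equal(weightsFromDual(m@dual), modelWeights(m))
  expect_equal(biasFromDual(m@dual, modelWeights(m)), modelBias(m))
})

test_that("kfoldEvaluate partitions reproducibly and scores the pipeline", {
  set.seed(24)
  spec <- syntheticSpec(S = 3L, H = 20L, W = 28L, separation = 0.9,
                        nNormal = 6L, nAmd = 6L, seed = 5L)
  vols <- c(lapply(1:6, function(i) generateVolume("normal", spec, 100 + i)),
            lapply(1:6, function(i) generateVolume("amd", spec, 200 + i)))
  r1 <- kfoldEvaluate(vols, K = 3, seed = 9)
  r2 <- kfoldEvaluate(vols, K = 3, seed = 9)
  expect_identical(r1$assignment, r2$assignment)
  expect_identical(sort(unique(r1$assignment)), 1:3)
  expect_identical(tabulate(r1$assignment), rep(4L, 3))
  expect_identical(nrow(r1$folds), 3L)
  expect_true(all(r1$folds$acc >= 0 & r1$folds$acc <= 100))
  expect_error(kfoldEvaluate(vols, K = 1), "out of range")
  expect_error(kfoldEvaluate(vols, K = 13), "out of range")
})

test_that("slice-threshold evaluation votes per-slice classifiers", {
  spec <- syntheticSpec(S = 4L, H = 20L, W = 28L, separation = 0.9,
                        nNormal = 4L, nAmd = 4L, seed = 6L)
  vols <- c(lapply(1:4, function(i) generateVolume("normal", spec, 300 + i)),
            lapply(1:4, function(i) generateVolume("amd", spec, 400 + i)))
  r <- kfoldEvaluate(vols, K = 2, seed = 3,
                     method = connectionMethod("slice_threshold"))
  expect_identical(nrow(r$folds), 2L)
  expect_true(all(is.finite(r$mean)))
})
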