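test_that("quantize truncates toward -Inf and reports overflow", {
  wide <- fixedPointFormat(TRUE, integerBits = 16L, fractionBits = 0L)
  expect_equal(quantize(3.75, wide)$values, 3)
  expect_equal(quantize(-1.25, wide)$values, -2)
  # signed 8-bit integer (1 sign + 7 integer bits): range [-128, 127]
  i8 <- fixedPointFormat(TRUE, integerBits = 7L, fractionBits = 0L)
  q <- quantize(c(300, 5, -300), i8)
  expect_equal(q$values, c(127, 5, -128))
  expect_identical(q$overflow, c(1L, 3L))
  # negative input to an unsigned format overflows and is reported
  u4 <- fixedPointFormat(FALSE, integerBits = 4L, fractionBits = 0L)
  qn <- quantize(-3, u4)
  expect_equal(qn$values, 0)
  expect_identical(qn$overflow, 1L)
})

test_that("truncation error is below one LSB absent overflow", {
  set.seed(31)
  for (F in c(0L, 3L, 8L)) {
    fmt <- fixedPointFormat(TRUE, integerBits = 12L, fractionBits = F)
    v <- runif(200, -100, 100)
    q <- quantize(v, fmt)
    expect_length(q$overflow, 0L)
    expect_true(all(q$values <= v))
    expect_true(all(v - q$values < 2^(-F)))
  }
})

test_that("exactly representable operands reproduce float predictions", {
  set.seed(32)
  # snap weights/bias to a 10-fraction-bit grid so both routes see the
  # same exact numbers
  w <- floor(rnorm(12) * 2^10) / 2^10
  b <- floor(rnorm(1) * 2^10) / 2^10
  m <- linearSVMModel(w, b)
  qm <- quantizedModel(
    m,
    featureFormat = fixedPointFormat(FALSE, integerBits = 20L),
    weightFormat = fixedPointFormat(TRUE, integerBits = 6L,
                                    fractionBits = 10L),
    biasFormat = fixedPointFormat(TRUE, integerBits = 6L,
                                  fractionBits = 10L))
  for (i in 1:50) {
    x <- sample(0:1000, 12, replace = TRUE)
    qr <- predict(qm, x)
    expect_identical(qr$label, predict(m, x)$label)
    expect_equal(qr$raw * qr$scale, predict(m, x)$score)
    expect_identical(qr$nOverflows, 0L)
  }
})

test_that("wrap and saturate can disagree on an overflowing input", {
  m <- linearSVMModel(1, 0)
  sat <- quantizedModel(m,
    featureFormat = fixedPointFormat(TRUE, integerBits = 7L),
    weightFormat = fixedPointFormat(TRUE, integerBits = 4L),
    biasFormat = fixedPointFormat(TRUE, integerBits = 4L))
  wrp <- quantizedModel(m,
    featureFormat = fixedPointFormat(TRUE, integerBits = 7L,
                                     overflow = "wrap"),
    weightFormat = fixedPointFormat(TRUE, integerBits = 4L),
    biasFormat = fixedPointFormat(TRUE, integerBits = 4L))
  # 200 saturates to 127 (positive) but wraps to -56 (negative)
  rs <- predict(sat, 200)
  rw <- predict(wrp, 200)
  expect_identical(rs$label, "amd")
  expect_identical(rw$label, "normal")
  expect_identical(rs$nOverflows, 1L)
  expect_identical(rw$nOverflows, 1L)
})

test_that("fixed-point prediction is deterministic", {
  m <- linearSVMModel(c(0.3, -0.7, 0.1), 0.05)
  qm <- quantizedModel(m,
    featureFormat = fixedPointFormat(FALSE, integerBits = 10L),
    weightFormat = fixedPointFormat(TRUE, integerBits = 2L,
                                    fractionBits = 8L),
    biasFormat = fixedPointFormat(TRUE, integerBits = 2L,
                                  fractionBits = 8L))
  x <- c(17, 230, 4)
  expect_identical(predict(qm, x), predict(qm, x))
})

test_that("the derived accumulator format is explicit and overflow-free", {
  m <- linearSVMModel(rep(0.5, 36), 0.25)
  qm <- quantizedModel(m,
    featureFormat = fixedPointFormat(FALSE, integerBits = 26L),
    weightFormat = fixedPointFormat(TRUE, integerBits = 2L,
                                    fractionBits = 8L),
    biasFormat = fixedPointFormat(TRUE, integerBits = 2L,
                                  fractionBits = 8L))
  expect_s4_class(qm@accumulatorFormat, "FixedPointFormat")
  expect_identical(qm@accumulatorFormat@fractionBits, 8L)
  r <- predict(qm, rep(2^26 - 1, 36))   # worst-case magnitude input
  expect_identical(r$nOverflows, 0L)
})

test_that("word-length sweep recovers float accuracy at ample widths", {
  set.seed(33)
  p <- 8L; n <- 40L
  m <- linearSVMModel(floor(rnorm(p) * 2^8) / 2^8,
                      floor(rnorm(1) * 2^8) / 2^8)
  feats <- matrix(sample(0:300, n * p, replace = TRUE), n, p)
  labels <- apply(feats, 1, function(f) predict(m, f)$label)  # float truth
  sw <- wordlengthSweep(m, feats, labels, "feature",
                        widths = c(1L, 4L, 9L, 12L))
  expect_identical(nrow(sw), 4L)
  expect_equal(sw$accuracy[sw$width >= 9], c(100, 100))  # 300 < 2^9
  expect_lt(sw$accuracy[sw$width == 1], 100)
  expect_gte(sw$accuracy[4], sw$accuracy[1])             # monotone trend
  swW <- wordlengthSweep(m, feats, labels, "weights", widths = c(8L, 12L))
  expect_equal(swW$accuracy, c(100, 100))                # exact at F >= 8
  expect_error(wordlengthSweep(m, feats, labels, "bias", integer(0)),
               "non-empty")
})
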