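test_that("lbpCode follows the sign-of-difference rule with ties set", {
  expect_identical(lbpCode(5, rep(5, 8)), 255)     # u(0) = 1 on every bit
  expect_identical(lbpCode(200, rep(10, 8)), 0)    # centre strictly above all
  expect_identical(lbpCode(5, c(9, 9, 9, 9, 1, 1, 1, 1)), 15)  # 0b00001111
  expect_error(lbpCode(5, rep(5, 7)), "8 entries")
  expect_error(lbpCode(300, rep(5, 8)), "\\[0, 255\\]")
})

test_that("circularTransitions counts wrapped bit changes and is even", {
  expect_identical(circularTransitions(0L), 0L)
  expect_identical(circularTransitions(15L), 2L)   # one block of ones
  expect_identical(circularTransitions(85L), 8L)   # 0b01010101 alternating
  n <- circularTransitions(0:255)
  expect_true(all(n %% 2L == 0L))
  expect_true(all(n >= 0L & n <= 8L))
})

test_that("minRotation canonicalises rotation classes", {
  expect_identical(minRotation(0L), 0L)
  expect_identical(minRotation(255L), 255L)
  # invariance under every circular shift, checked against an
  # arithmetic-only rotation
  for (s in 0:7) {
    expect_identical(minRotation(rotLeft8(0:255, s)), minRotation(0:255))
  }
})

test_that("variant LUTs have the documented structure", {
  classic <- buildLUT("classic")
  expect_identical(classic@table, 0:255)           # identity mapping

  ri <- buildLUT("ri")
  riu2 <- buildLUT("riu2")
  for (s in 0:7) {
    rot <- rotLeft8(0:255, s)
    expect_identical(applyLUT(ri, rot), applyLUT(ri, 0:255))
    expect_identical(applyLUT(riu2, rot), applyLUT(riu2, 0:255))
  }

  u2 <- buildLUT("u2")
  uniform <- circularTransitions(0:255) <= 2L
  binsU <- applyLUT(u2, which(uniform) - 1L)
  expect_identical(sort(binsU), 0:(sum(uniform) - 1L))  # one bin each
  expect_true(all(applyLUT(u2, which(!uniform) - 1L) == sum(uniform)))
  # shared catch-all bins sit last
  expect_identical(max(u2@table), nBins(u2) - 1L)
  expect_true(all(applyLUT(riu2, which(!uniform) - 1L) == nBins(riu2) - 1L))

  expect_error(buildLUT("lbp-xyz"), "unknown LBP variant")
})

test_that("imageHistogram counts interior windows through the LUT", {
  img <- matrix(10L, 10, 10)
  h <- imageHistogram(img, buildLUT("classic"))
  expect_identical(binCounts(h)[256], 64)          # (10-2)^2 all-equal windows
  expect_identical(sum(binCounts(h)), 64)
  expect_false(isSaturated(h))

  hr <- imageHistogram(img, buildLUT("riu2"))
  expect_identical(max(binCounts(hr)), 64)         # one uniform bin holds all
  expect_identical(sum(binCounts(hr) > 0), 1L)

  h4 <- imageHistogram(img, buildLUT("classic"), counterWidth = 4)
  expect_identical(binCounts(h4)[256], 15)         # clamp at 2^4 - 1
  expect_true(isSaturated(h4))
  # a counter that lands exactly on its ceiling without dropping an
  # increment is not saturated: 9 x 11 has 7 * 9 = 63 = 2^6 - 1 windows
  hEdge <- imageHistogram(matrix(10L, 9, 11), buildLUT("classic"),
                          counterWidth = 6)
  expect_identical(binCounts(hEdge)[256], 63)
  expect_false(isSaturated(hEdge))
  expect_error(imageHistogram(matrix(0, 2, 5), buildLUT("ri")), "3 x 3")
})

test_that("histograms conserve window counts and ignore gray shifts", {
  set.seed(101)
  lut <- buildLUT("ri")
  for (i in 1:5) {
    img <- matrix(sample(0:200, 12 * 15, replace = TRUE), 12, 15)
    h <- imageHistogram(img, lut)
    expect_identical(sum(binCounts(h)), (12 - 2) * (15 - 2))
    shifted <- img + 55L                            # no overflow past 255
    expect_identical(binCounts(imageHistogram(shifted, lut)), binCounts(h))
  }
})

test_that("imageHistogram matches the brute-force double-loop oracle", {
  set.seed(77)
  for (variant in c("classic", "ri", "u2", "riu2")) {
    lut <- buildLUT(variant)
    for (i in 1:5) {
      img <- randomImage(8L, 8L)
      expect_equal(binCounts(imageHistogram(img, lut)),
                   bruteHistogram(img, lut))
    }
  }
})
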