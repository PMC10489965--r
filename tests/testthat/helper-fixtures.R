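# Fixtures and independent oracles shared across test files.

randomImage <- function(H = 8L, W = 8L) {
  matrix(sample(0:255, H * W, replace = TRUE), H, W)
}

randomVolume <- function(S = 3L, H = 8L, W = 10L, label = NA_character_) {
  new("OCTVolume",
      slices = replicate(S, randomImage(H, W), simplify = FALSE),
      id = "fixture", classLabel = label)
}

makeHist <- function(counts, variant = "ri", counterWidth = Inf,
                     saturated = FALSE) {
  new("FeatureHistogram", counts = as.numeric(counts),
      counterWidth = as.numeric(counterWidth), saturated = saturated,
      variant = variant)
}

# independent left-rotation of an 8-bit code, arithmetic only
rotLeft8 <- function(code, s) {
  s <- s %% 8
  (code * 2^s) %% 256 + code %/% 2^(8 - s)
}

# brute-force double-loop histogram: explicit window scan, one pixel at a
# time, same ring convention (E, NE, N, NW, W, SW, S, SE; g1 = LSB)
bruteHistogram <- function(image, lut) {
  H <- nrow(image); W <- ncol(image)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  counts <- numeric(nBins(lut))
  for (r in 2:(H - 1)) {
    for (cc in 2:(W - 1)) {
      gc <- image[r, cc]
      code <- 0
      for (i in 1:8) {
        gi <- image[r + offs[[i]][1], cc + offs[[i]][2]]
        if (gi >= gc) code <- code + 2^(i - 1)
      }
      bin <- applyLUT(lut, code)
      counts[bin + 1] <- counts[bin + 1] + 1
    }
  }
  counts
}

# hard-margin dual of the 2D toy problem via an interior-point QP,
# independent of the libsvm training route
toyQPDual <- function() {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  y <- c(-1, 1, -1, 1)
  Hm <- (y %*% t(y)) * (X %*% t(X)) + diag(1e-8, 4)
  sol <- kernlab::ipop(c = rep(-1, 4), H = Hm, A = matrix(y, 1, 4),
                       b = 0, l = rep(0, 4), u = rep(1e3, 4), r = 0)
  dualSolution(X, y, kernlab::primal(sol))
}
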