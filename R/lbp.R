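# LBP_{8,1} codes, variant lookup tables and histogram statistics.
#
# Ring convention: neighbours g1..g8 start at the east neighbour and
# proceed counterclockwise (E, NE, N, NW, W, SW, S, SE); neighbour g_i
# contributes bit i-1 of the code (g1 is the LSB). A neighbour equal to
# the centre sets its bit (the unit step u(0) = 1).

.checkGray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop(sprintf("image must be at least 3 x 3 (got %d x %d)",
                 nrow(image), ncol(image)))
  if (anyNA(image) || any(image < 0) || any(image > 255))
    stop("pixel values must lie in [0, 255]")
  invisible(image)
}

# matrix-coordinate offsets (d_row, d_col) of g1..g8; rows grow downward,
# so counterclockwise on screen is E, NE, N, NW, W, SW, S, SE
.RING_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                      c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

#' LBP code of a single 3x3 neighbourhood
#'
#' Computes the raw 8-bit local binary pattern code
#' \eqn{\sum_{i=1}^{8} u(g_i - g_c)\,2^{i-1}} with the unit step
#' \eqn{u(x) = 1} for \eqn{x \ge 0} and 0 otherwise, so a neighbour equal
#' to the centre sets its bit. `ring` lists the eight neighbours g1..g8 in
#' circular order starting east, counterclockwise.
#'
#' @param gc centre pixel value in \[0, 255\]
#' @param ring numeric vector of exactly 8 neighbour values in \[0, 255\]
#' @return integer code in \[0, 255\]
#' @examples
#' lbpCode(5, c(9, 9, 9, 9, 1, 1, 1, 1))  # 15
#' @export
lbpCode <- function(gc, ring) {
  if (length(ring) != 8L) stop("ring must have exactly 8 entries")
  if (length(gc) != 1L) stop("gc must be a single value")
  vals <- c(gc, ring)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255))
    stop("pixel values must lie in [0, 255]")
  sum(as.integer(ring >= gc) * 2L^(0:7))
}

#' Raw LBP code image
#'
#' One code per interior pixel; the 3x3 window centre never sits on the
#' 1-pixel border, so the result is (H-2) x (W-2).
#'
#' @param image H x W numeric matrix, H, W >= 3, values in \[0, 255\]
#' @return (H-2) x (W-2) integer matrix of codes in \[0, 255\]
#' @export
lbpCodeImage <- function(image) {
  .checkGray(image)
  H <- nrow(image); W <- ncol(image)
  gc <- image[2:(H - 1L), 2:(W - 1L), drop = FALSE]
  code <- matrix(0L, H - 2L, W - 2L)
  for (i in seq_len(8L)) {
    dr <- .RING_OFFSETS[[i]][1]; dc <- .RING_OFFSETS[[i]][2]
    gi <- image[(2L + dr):(H - 1L + dr), (2L + dc):(W - 1L + dc), drop = FALSE]
    code <- code + as.integer(gi >= gc) * 2L^(i - 1L)
  }
  code
}

.rotate8 <- function(code, s) {
  s <- s %% 8L
  if (s == 0L) return(as.integer(code))
  bitwAnd(bitwOr(bitwShiftR(as.integer(code), s),
                 bitwShiftL(as.integer(code), 8L - s)), 255L)
}

#' Circular 0/1 transition count of an 8-bit code
#'
#' Number of bit changes reading the 8 bits around the ring (bit 8 wraps
#' to bit 1); always even. Codes with at most 2 transitions are the
#' "uniform" patterns.
#'
#' @param code integer vector, values in \[0, 255\]
#' @return integer vector in \{0, 2, 4, 6, 8\}
#' @export
circularTransitions <- function(code) {
  code <- .checkCode(code)
  x <- bitwXor(code, .rotate8(code, 1L))
  n <- integer(length(code))
  for (k in 0:7) n <- n + bitwAnd(bitwShiftR(x, k), 1L)
  n
}

#' Canonical representative of a rotation class
#'
#' The minimum value among the 8 circular bit-rotations of a code; all
#' rotations of a code share the same representative. Enumerating all 256
#' codes yields 36 distinct representatives.
#'
#' @param code integer vector, values in \[0, 255\]
#' @return integer vector of canonical codes
#' @export
minRotation <- function(code) {
  code <- .checkCode(code)
  m <- code
  for (s in 1:7) m <- pmin(m, .rotate8(code, s))
  m
}

.checkCode <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L) || any(code > 255L))
    stop("codes must lie in [0, 255]")
  code
}

#' Build the lookup table for an LBP variant
#'
#' Enumerates all 256 raw codes and assigns each a bin:
#' \describe{
#'   \item{classic}{identity, 256 bins}
#'   \item{ri}{one bin per rotation class, 36 bins}
#'   \item{u2}{one bin per uniform code (<= 2 circular transitions, 58
#'     codes) plus one shared bin for the rest, 59 bins}
#'   \item{riu2}{one bin per rotation class of uniform codes (9 classes)
#'     plus one shared non-uniform bin, 10 bins}
#' }
#' Bin indices are assigned in ascending order of canonical code, with
#' the shared catch-all bin last.
#'
#' @param variant "classic", "ri", "u2" or "riu2"
#' @return a [VariantLUT-class]
#' @export
buildLUT <- function(variant) {
  if (length(variant) != 1L || !variant %in% .VARIANTS)
    stop(sprintf("unknown LBP variant '%s' (expected one of %s)",
                 as.character(variant)[1],
                 paste(.VARIANTS, collapse = ", ")))
  codes <- 0:255
  tab <- switch(variant,
    classic = codes,
    ri = {
      canon <- minRotation(codes)
      match(canon, sort(unique(canon))) - 1L
    },
    u2 = {
      uniform <- circularTransitions(codes) <= 2L
      idx <- integer(256L)
      idx[uniform] <- seq_len(sum(uniform)) - 1L   # ascending code order
      idx[!uniform] <- sum(uniform)                # shared catch-all, last
      idx
    },
    riu2 = {
      uniform <- circularTransitions(codes) <= 2L
      canon <- minRotation(codes)
      classes <- sort(unique(canon[uniform]))
      idx <- integer(256L)
      idx[uniform] <- match(canon[uniform], classes) - 1L
      idx[!uniform] <- length(classes)
      idx
    })
  new("VariantLUT", variant = variant, table = as.integer(tab),
      nBins = .VARIANT_BINS[[variant]])
}

#' Map raw codes through a variant lookup table
#'
#' @param lut a [VariantLUT-class]
#' @param code integer vector or matrix of raw codes in \[0, 255\]
#' @return bin indices (0-based), same shape as `code`
#' @export
applyLUT <- function(lut, code) {
  stopifnot(is(lut, "VariantLUT"))
  out <- lut@table[as.integer(code) + 1L]
  if (is.matrix(code)) dim(out) <- dim(code)
  out
}

#' LBP histogram of one greyscale image
#'
#' Slides the 3x3 window over every interior pixel ((H-2)*(W-2) windows),
#' maps each raw code through the variant lookup table and counts bin
#' occurrences. With a finite `counterWidth` of b bits, each counter
#' clamps at 2^b - 1 and the saturation flag records whether any
#' increment was dropped, mirroring the hardware statistic-saturation
#' warning.
#'
#' @param image H x W numeric matrix, values in \[0, 255\], H, W >= 3
#' @param lut a [VariantLUT-class]
#' @param counterWidth counter width in bits, or `Inf` (default) for
#'   unlimited software counters
#' @return a [FeatureHistogram-class]
#' @export
imageHistogram <- function(image, lut, counterWidth = Inf) {
  stopifnot(is(lut, "VariantLUT"))
  if (length(counterWidth) != 1L || counterWidth < 1)
    stop("counterWidth must be a single value >= 1 (Inf for unlimited)")
  bins <- applyLUT(lut, lbpCodeImage(image))
  counts <- as.numeric(tabulate(as.vector(bins) + 1L, nbins = lut@nBins))
  .histogramFromCounts(counts, lut@variant, counterWidth)
}

# clamp raw counts to the counter ceiling; saturation means an increment
# was actually dropped (raw strictly above the ceiling)
.histogramFromCounts <- function(rawCounts, variant, counterWidth) {
  saturated <- FALSE
  counts <- rawCounts
  if (is.finite(counterWidth)) {
    ceilingVal <- 2^counterWidth - 1
    saturated <- any(rawCounts > ceilingVal)
    counts <- pmin(rawCounts, ceilingVal)
  }
  new("FeatureHistogram", counts = counts, counterWidth = counterWidth,
      saturated = saturated, variant = variant)
}

#' Single-pass LBP histogram of a whole volume
#'
#' Accumulates every 3x3 window of every slice into one counter bank;
#' with unlimited counters this equals the element-wise sum of the
#' per-slice histograms (the slice-sum connection).
#'
#' @param volume an [OCTVolume-class]
#' @param lut a [VariantLUT-class]
#' @param counterWidth counter width in bits, or `Inf`
#' @return a [FeatureHistogram-class]
#' @export
volumeHistogram <- function(volume, lut, counterWidth = Inf) {
  stopifnot(is(volume, "OCTVolume"), is(lut, "VariantLUT"))
  raw <- numeric(lut@nBins)
  for (sl in volume@slices) {
    bins <- applyLUT(lut, lbpCodeImage(sl))
    raw <- raw + tabulate(as.vector(bins) + 1L, nbins = lut@nBins)
  }
  .histogramFromCounts(raw, lut@variant, counterWidth)
}

#' Per-slice LBP histograms of a volume
#'
#' @inheritParams volumeHistogram
#' @return list of [FeatureHistogram-class], one per slice in order
#' @export
volumeHistograms <- function(volume, lut, counterWidth = Inf) {
  stopifnot(is(volume, "OCTVolume"))
  lapply(volume@slices, imageHistogram, lut = lut, counterWidth = counterWidth)
}
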