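# Synthetic two-class OCT-like volume generator. The healthy retina is
# emulated as smooth horizontal layers (a sinusoidal intensity profile
# down each column) plus speckle-like noise; the diseased class adds
# dome-shaped layer displacement and local texture disruption whose
# amplitude scales with the separation parameter. Every random draw is
# consumed for both classes, so at separation 0 the two generators are
# bit-identical given the same seed.

#' Synthetic generator specification
#'
#' Defaults describe the reduced test geometry (20 x 64 x 128) and the
#' 113 + 113 volume counts that split into 100/100 training and 13/13
#' test volumes per class.
#'
#' @param S,H,W slices, height, width (chip-faithful geometry is
#'   100 x 512 x 1000)
#' @param separation class contrast in \[0, 1\]
#' @param noiseSd speckle-like noise standard deviation, intensity units
#' @param nNormal,nAmd volumes per class
#' @param seed master seed
#' @return a [SyntheticSpec-class]
#' @export
syntheticSpec <- function(S = 20L, H = 64L, W = 128L, separation = 0.8,
                          noiseSd = 6, nNormal = 113L, nAmd = 113L,
                          seed = 1L) {
  new("SyntheticSpec", S = as.integer(S), H = as.integer(H),
      W = as.integer(W), separation = as.numeric(separation),
      noiseSd = as.numeric(noiseSd), nNormal = as.integer(nNormal),
      nAmd = as.integer(nAmd), seed = as.integer(seed))
}

# layer displacement of up to one full layer period and disruption noise
# of up to 45 intensity units, both at separation = 1
.MAX_TEX_SD <- 45

#' Generate one synthetic OCT-like volume
#'
#' @param label "normal" or "amd"
#' @param spec a [SyntheticSpec-class]
#' @param seed per-volume seed
#' @param id volume identifier (default derived from the seed)
#' @return an [OCTVolume-class]
#' @export
generateVolume <- function(label, spec, seed,
                           id = sprintf("synth-%s-%d", label, seed)) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (!label %in% .LABELS) stop("label must be 'normal' or 'amd'")
  set.seed(as.integer(seed))
  H <- spec@H; W <- spec@W; S <- spec@S
  amp <- if (label == "amd") spec@separation else 0
  period <- stats::runif(1, 9, 13)
  phase <- stats::runif(1, 0, 2 * pi)
  rowIdx <- matrix(seq_len(H), H, W)
  colIdx <- matrix(rep(seq_len(W), each = H), H, W)
  slices <- vector("list", S)
  for (s in seq_len(S)) {
    # dome-shaped bumps: drawn for every volume, applied scaled by amp
    dome <- matrix(0, H, W)
    for (b in seq_len(3L)) {
      r0 <- stats::runif(1, 0.25 * H, 0.75 * H)
      c0 <- stats::runif(1, 0.15 * W, 0.85 * W)
      sr <- stats::runif(1, H / 16, H / 8)
      sc <- stats::runif(1, W / 12, W / 6)
      a <- stats::runif(1, 0.5, 1)
      dome <- dome + a * exp(-((rowIdx - r0)^2 / (2 * sr^2) +
                               (colIdx - c0)^2 / (2 * sc^2)))
    }
    dome <- pmin(dome, 1)
    speckle <- matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    disrupt <- matrix(stats::rnorm(H * W), H, W)
    layers <- 120 + 85 * sin(2 * pi * (rowIdx + amp * period * dome) /
                               period + phase)
    img <- layers + speckle + amp * .MAX_TEX_SD * dome * disrupt
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    slices[[s]] <- img
  }
  new("OCTVolume", slices = slices, id = id, classLabel = label)
}

#' Generate a labelled synthetic dataset with manifest
#'
#' Produces `nNormal + nAmd` volumes deterministically from the master
#' seed. Per class, the last `nTestNormal` / `nTestAmd` volumes are
#' marked as the held-out test split (defaults 13 + 13, leaving 100/100
#' for training under the default spec).
#'
#' @param spec a [SyntheticSpec-class]
#' @param nTestNormal,nTestAmd held-out volumes per class
#' @return list with `volumes` (list of [OCTVolume-class]) and
#'   `manifest` (data.frame: id, label, split, seed)
#' @export
generateDataset <- function(spec, nTestNormal = 13L, nTestAmd = 13L) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nNormal == 0L || spec@nAmd == 0L)
    stop("the train/test split requires volumes in both classes")
  if (nTestNormal > spec@nNormal || nTestAmd > spec@nAmd)
    stop("test split larger than the class it draws from")
  n <- spec@nNormal + spec@nAmd
  set.seed(spec@seed)
  volSeeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("normal", spec@nNormal), rep("amd", spec@nAmd))
  split <- c(rep(c("train", "test"),
                 c(spec@nNormal - nTestNormal, nTestNormal)),
             rep(c("train", "test"), c(spec@nAmd - nTestAmd, nTestAmd)))
  ids <- sprintf("%s-%03d", labels,
                 c(seq_len(spec@nNormal), seq_len(spec@nAmd)))
  volumes <- vector("list", n)
  for (i in seq_len(n))
    volumes[[i]] <- generateVolume(labels[i], spec, volSeeds[i], id = ids[i])
  list(volumes = volumes,
       manifest = data.frame(id = ids, label = labels, split = split,
                             seed = volSeeds, stringsAsFactors = FALSE))
}
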