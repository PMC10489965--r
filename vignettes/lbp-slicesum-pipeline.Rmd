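---
title: "Texture classification of OCT volumes: methods and design notes"
author: "octLBP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture classification of OCT volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octLBP)
```

# The pipeline

`octLBP` classifies a 3D OCT volume — an ordered stack of S greyscale
B-scans, each H×W 8-bit pixels — as *normal* or *AMD* in four stages:

1. **LBP_{8,1} coding**: each interior pixel of each slice yields an
   8-bit local binary pattern code from sign comparisons against its 8
   ring neighbours.
2. **Variant mapping**: a 256-entry lookup table folds raw codes into
   histogram bins (classic / rotation-invariant / uniform /
   rotation-invariant-uniform).
3. **Slice-sum aggregation**: one histogram counter bank accumulates
   over the entire volume, giving a feature vector whose length (36 for
   LBP-RI) is independent of the slice count.
4. **Linear SVM**: the label is the sign of `w · x + b`, where `w` and
   `b` are reconstructed explicitly from the dual solution of the
   training problem.

No image resizing and no denoising precede feature extraction: the
default flow is intentionally the minimal one, which also keeps a
hardware realisation small. The pipeline defaults
(`variant = "ri"`, `method = "slice_sum"`) reflect that final flow.

# LBP codes and the conventions behind them

The code of a 3×3 window is

$$\mathrm{code} = \sum_{i=1}^{8} u(g_i - g_c)\,2^{\,i-1},
\qquad u(x) = \begin{cases}1 & x \ge 0\\ 0 & x < 0\end{cases}$$

Several details are under-determined by that formula alone; the package
fixes them as follows, and the test suite pins each one down:

* **Exponent.** The per-neighbour place value is $2^{i-1}$ (neighbour
  $g_1$ is the least-significant bit). A constant exponent $2^{p-1}$
  would collapse all codes onto multiples of 128 and could not produce
  256 distinct classic bins.
* **Ring order.** $g_1 \ldots g_8$ start at the east neighbour and
  proceed counterclockwise (E, NE, N, NW, W, SW, S, SE). Any fixed
  start/direction gives the same variant bin counts and the same
  rotation classes, so downstream results do not depend on this choice;
  it is declared so that raw codes are reproducible.
* **Ties.** $g_i = g_c$ sets the bit ($u(0)=1$). A flat window therefore
  codes as 255, not 0.
* **Borders.** Window centres range over interior pixels only, giving
  exactly $(H-2)(W-2)$ windows per slice. No padding or reflection is
  applied: padded borders would inject synthetic texture into the
  histogram.

## Variant lookup tables

All four variants share one mechanism — a 256-entry table — so they cost
the same per pixel; they differ only in histogram width:

* `classic`: identity, 256 bins.
* `ri`: each code maps to the minimum of its 8 circular bit-rotations;
  36 rotation classes exist for 8 bits.
* `u2`: "uniform" codes, having at most 2 circular 0/1 transitions (58
  of them), each get a bin; the 198 non-uniform codes share one
  catch-all bin — 59 bins.
* `riu2`: rotation classes of uniform codes (9: one per count of set
  bits) plus the shared non-uniform bin — 10 bins.

Within a table, bins are assigned in ascending order of canonical code
with the catch-all last. The ordering is arbitrary in principle; fixing
it keeps models portable across sessions and machines.

## Saturating counters

Hardware histogram counters have a finite width b and clamp at
$2^b - 1$; the `saturated` flag is raised only when an increment is
actually dropped (a counter that merely reaches its ceiling is not
saturated). Software defaults to unlimited counters
(`counterWidth = Inf`); 26 bits suffice for a lossless slice-sum at the
reference geometry, since $100 \cdot 510 \cdot 998 < 2^{26}$. The flag
propagates from histograms through volume features into prediction
output, surfacing as a per-volume warning.

# Connecting slices

Three aggregation schemes are implemented:

* **slice-chain** concatenates the S per-slice histograms (length S·K).
* **slice-threshold** classifies each slice independently and calls the
  volume abnormal iff strictly more than a threshold of slices vote
  abnormal. The threshold defaults to the majority, $\lfloor S/2
  \rfloor$; the strict comparison makes the all-tied case resolve to
  normal. Because no per-slice ground truth exists, the per-slice
  classifier is trained with each volume's label broadcast to its
  slices.
* **slice-sum** adds the histograms element-wise (length K). It is
  exactly equivalent to running one counter bank over all S slices —
  a property the tests verify against a single-pass whole-volume scan —
  and shrinks SVM inference work by a factor of S.

Slice-sum is the package default: at the reference geometry it is 100×
cheaper than the alternatives at equal or better separability, which is
the core argument for the design.

# The linear SVM

Training wraps libsvm (`e1071::svm`, C-classification, linear kernel,
`scale = FALSE`, default cost 1). The package then discards libsvm's own
intercept bookkeeping and reconstructs the primal parameters from the
dual solution:

$$w_j = \sum_{i=1}^{k} \alpha_i\,y_i\,x_{i,j}, \qquad
  b = \operatorname{mean}_i\left(y_i - x_i \cdot w\right)$$

with the mean running over **all** support points. For hard-margin
problems every support point lies exactly on its margin, so the mean is
exact; the tests confirm this against an independent interior-point QP
solution of a toy problem to 1e-6. For soft-margin fits on separable
synthetic data the bounded support vectors are rare and the formula
remains a faithful estimate.

Conventions: labels are encoded +1 = AMD, −1 = normal; a score of
exactly 0 is assigned to the positive class, mirroring $u(0)=1$; raw
features are used unscaled, since the histogram counts are the
quantities a hardware datapath would consume. Accuracy, sensitivity and
specificity treat AMD as the positive class.

`predictSequential()` emulates the chip datapath: the accumulator is
initialised with the bias (saving one cycle), then one
multiply-accumulate per feature element in index order — 36 cycles for
an LBP-RI slice-sum feature. It is algebraically identical to the dot
product and bit-identical in integer arithmetic.

`kfoldEvaluate()` implements the usual K-fold flow (default K = 5, a
conventional choice): a seeded random partition, each subset serving
once as the test fold, metrics averaged over folds.

# Fixed-point simulation

A format is (signedness, I integer bits, F fraction bits, overflow
mode): raw integers span $[-2^{I+F}, 2^{I+F}-1]$ signed (sign bit
extra) or $[0, 2^{I+F}-1]$ unsigned, and represent value
$\mathrm{raw} \cdot 2^{-F}$.

* **Rounding** is truncation toward $-\infty$ — the two's-complement
  LSB drop a hardware truncation performs. The error is below one LSB:
  $|q(v) - v| < 2^{-F}$ absent overflow.
* **Overflow** defaults to saturation, with wrap-around available as a
  first-class alternative; both report the indices that overflowed. The
  two modes can legitimately disagree on the predicted label when an
  operand leaves its range, and a test constructs such a case.
* **Accumulation** happens in integer arithmetic at the product scale
  $2^{-(F_{feat}+F_w)}$; the bias is shifted to that scale (truncating
  when shifting down). The accumulator format is always explicit on a
  `QuantizedModel`; the derived default width — feature width + weight
  width + $\lceil \log_2 n \rceil$ + 1 — cannot overflow by
  construction.

`wordlengthSweep()` follows the sequential procedure of fixing one
component at a time in the order feature vector → weights → bias,
holding the others at full precision (or at formats already frozen).
Width semantics differ per component because their numeric nature
differs: the feature vector is integer counts, so the swept width is its
unsigned integer bit budget; weights and bias are fractional reals, so
the swept width is the retained fraction bits with integer bits fixed to
cover the value range. At ample widths the sweep reproduces the
floating-point accuracy exactly; at 1 feature bit every count collapses
to {0, 1} and predictions degenerate toward a single class.

# The synthetic volume generator

Real OCT volumes of the kind this pipeline targets cannot ship with a
package, so `generateVolume()` emulates the texture contrast that
matters to the method:

* **normal**: horizontal sinusoidal intensity bands (period 9–13 rows,
  random phase; amplitude 85 around a mean of 120) plus additive
  Gaussian speckle-like noise (`noiseSd`, default 6 intensity units).
* **amd**: the same layers, plus 3 dome-shaped (Gaussian-profile) bumps
  per slice that (a) displace the layer pattern vertically by up to one
  period and (b) inject local high-frequency texture noise (up to 45
  intensity units at full strength). Both effects scale linearly with
  `separation` ∈ [0, 1].

Every random draw is consumed identically for both classes, so at
`separation = 0` the two generators are *bit-identical* for equal seeds
— a strong form of "identical in distribution" that the tests exploit
directly. The class signal deliberately lives in local sign patterns
(bump edges and disruption noise change LBP statistics), not in mean
intensity, because the descriptor under test is a texture histogram
that is invariant to monotone gray shifts.

What the generator does **not** emulate: physically realistic OCT
speckle (multiplicative, correlated), acquisition artefacts, anatomical
variability across patients, or the actual appearance of drusen.
Passing tests therefore demonstrate that the pipeline recovers a known
texture contrast end-to-end — not that it reaches any particular
accuracy on clinical data.

Defaults are the package's study conditions: geometry 20×64×128 (so the
full suite runs in well under a minute; the chip-faithful 100×512×1000
geometry is opt-in), separation 0.8, 113 + 113 volumes splitting into
100/100 training and 13/13 held-out test volumes per class.

```{r example, eval = FALSE}
spec <- syntheticSpec(seed = 1L)
ds <- generateDataset(spec)
fm <- featureMatrix(ds$volumes)
train <- ds$manifest$split == "train"
model <- trainLinear(fm$features[train, ], fm$labels[train],
                     variant = "ri", method = "slice_sum")
pred <- apply(fm$features[!train, ], 1, function(f) predict(model, f)$label)
classificationMetrics(fm$labels[!train], pred)
```

# Numerical and I/O choices

* Model files are plain text with numbers printed at 17 significant
  digits, making write → read → write byte-identical while recovering
  doubles exactly.
* Slice directories are ordered by natural sort (numeric runs compared
  as numbers), so zero padding in filenames is optional. Slice index is
  0-based, pixels row-major, origin top-left.
* The raw volume container is a small header (magic `OCTVOL1`,
  little-endian int32 S, H, W) followed by row-major 8-bit pixels; PNG
  and multi-page TIFF round-trips are bit-exact for 8-bit greyscale.
* Colour input is collapsed by Rec. 601 luminance with a warning.
* The streaming pixel order of a hardware line buffer is not emulated at
  the I/O layer; the sequential multiply-accumulate emulation is the
  only datapath-faithful mode. The results are identical and the
  contract much simpler.

# Known limitations

* Only LBP with 8 neighbours at radius 1 (no interpolated sampling, no
  multi-scale variants).
* Binary classification only; no non-linear kernels; no on-line or
  on-chip training.
* The bias formula averages over all support points; for heavily
  regularised soft-margin fits with many bounded support vectors it can
  drift from the optimal intercept.
* Synthetic volumes are a texture phantom, not a clinical simulation;
  accuracy figures on them do not transfer to patient data.
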