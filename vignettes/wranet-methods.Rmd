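---
title: "Wavelet residual attention segmentation: models, conventions and design choices"
author: "wranet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet residual attention segmentation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wranet)
```

## The model

`wranet` implements a U-shaped encoder/decoder network for binary
segmentation of biomedical images (the motivating application is small,
bright lesions — aneurysms in MR angiography slices, polyps in endoscopy —
against darker, textured tissue). Three ideas distinguish it from a plain
U-Net:

1. **Wavelet downsampling.** Every encoder downsampling step is a one-level
   2D discrete wavelet transform of which only the low-frequency `LL`
   subband is kept. The three detail subbands — which concentrate
   high-frequency content, including pixel-level noise — are discarded.
   The operator is linear and parameter-free, so the choice of wavelet is
   a pure configuration switch that never changes the parameter count.
2. **Residual attention gates (RAM).** Each skip connection is recalibrated
   by a per-pixel attention coefficient `alpha in (0,1)` computed from the
   decoder (gating) feature and the encoder (skip) feature, and the gated
   feature is added back to the skip feature: `x_o = (1 + alpha) x_l`. The
   residual term keeps the gate from ever suppressing a skip feature
   entirely: the output is always elementwise between `x_l` and `2 x_l`.
3. **Hybrid loss.** Training minimizes
   `L = alpha_w * L_BCE + beta_w * L_Dice` with `alpha_w = 0.4`,
   `beta_w = 0.6`, combining per-pixel calibration (BCE) with
   overlap-driven robustness to class imbalance (soft Dice).

The channel ladder is `B, 2B, 4B, 8B` over four levels with a `16B`
bottleneck; the reference configuration is `B = 64` (64/128/256/512/1024,
about 35 M parameters). Input sides must be divisible by `2^4 = 16`.

## Wavelet filter banks

The filter-bank module is self-contained and usable on its own
(`buildFilterBank()`, `dwt2()`, `idwt2()`, `waveletDownsample()`).

**Coefficient source.** Low-pass coefficients come from the standard
published tables for each family (Daubechies/Symlet/biorthogonal spline, in
the orthonormal normalization `sum(l) = sqrt(2)`), inlined as constants.
High-pass filters are never tabulated: they are *derived* from the low-pass
filters by the quadrature-mirror recurrence `h_i = (-1)^i lt_{2n+1-i}`
(0-based indices; `lt = l` for orthogonal banks, the dual filter for
biorthogonal ones), with `n` fixed by the filter length `2n + 2` — the
unique index window keeping every reference in range. `validateBank()`
reports the residuals of every identity (orthonormality, DC gain,
low/high cross-orthogonality, the recurrences, and the dual delta identity
`sum_k l_k lt_{k+2m} = delta(m)`), and the test suite holds all 21
registry banks to 1e-8.

**Transform conventions.** Several conventions are free in principle and
fixed here once:

* *Boundary handling* is periodization (circular extension), the only
  standard mode that yields exactly `H/2 x W/2` coefficients for every
  filter length.
* *Phase*: after filtering, even-indexed outputs are kept
  (`y_k = sum_i f_i x_{(2k+i) mod N}`), matching a naive double-loop
  oracle used in the tests.
* *Orientation naming* is row-first: the row (width) pass runs first, so
  `LH` denotes row high-pass followed by column low-pass (horizontal
  detail), `HL` the converse. The worked 2x2 example
  `dwt2(matrix(c(1,3,2,4),2,2), "haar")` gives `LL = 5`, `LH = -1`,
  `HL = -2`, `HH = 0`.
* *Synthesis* is the adjoint of the analysis indexing with the synthesis
  pair; with the tabulated duals this gives perfect reconstruction for all
  21 banks (orthogonal round-trips are exact to ~1e-12, biorthogonal to
  ~1e-11), and orthogonal banks conserve energy across the four subbands.
* Inputs with an odd side are rejected rather than padded; the prediction
  pipeline resizes images to a multiple of 16 up front.

A useful analytic consequence, exercised in the tests: a pure Nyquist
checkerboard perturbation (`+e/-e` alternating) lies entirely in the detail
subbands of the Haar bank, so the retained `LL` band of a noisy image is
bitwise identical to that of the clean image.

## The attention gate in detail

The published description of the gate leaves the normalization placement
ambiguous. The ordering implemented is: 1x1 projection of each input to a
common intermediate channel count, batch normalization per branch, sum,
ReLU, a 1x1 single-channel projection (`psi`, with bias), sigmoid. The
intermediate channel count equals the skip feature's channel count at that
level — the simplest reading of "so that the number of channels is the
same", and it keeps gate capacity proportional to depth. `alpha` is a
single channel broadcast across all channels of `x_l` (a pixel-level, not
channel-level, coefficient). This ordering is documented as the package's
choice, not claimed to match the original bit for bit.

Projections that feed directly into batch normalization are bias-free: a
bias there is removed exactly by the mean subtraction, so it would be a
dead parameter (its gradient is identically zero). This is also why the
package can promise the stronger invariant that *every* trainable parameter
receives a nonzero gradient from a generic loss. The `psi` projection and
the output head, which are not normalized, keep their biases. The public
`attentionParams()` API retains biases on all projections (and makes
normalization optional) so that hand-set weights remain exactly
reproducible in scalar arithmetic.

## Decoder and fusion

Upsampling is bilinear x2 with half-pixel centers and clamped edges (an
explicit interpolation-matrix formulation, so the adjoint used in
backpropagation is exact), followed by a 3x3 convolution halving the
channel count, batch normalization and ReLU. The gating feature fed to each
RAM is this upsampled decoder feature, which by construction shares the
skip feature's spatial size. The gated skip is fused by concatenation
followed by a conv block (U-Net convention; the architecture figure does
not specify concatenation versus summation, and concatenation preserves
both signals). The head is a 1x1 convolution to one channel plus sigmoid;
the loss consumes probabilities, not logits.

## Loss and metrics: numerical conventions

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logarithms
  (the BCE is undefined at 0 and 1); clamped pixels get zero BCE gradient.
* The Dice smoothing factor defaults to `lambda = 1` (the most common
  choice; the original work does not state a value) and is exposed in
  `lossConfig()`. Note the documented degeneracy of the soft Dice loss: a
  perfectly predicted *empty* mask still scores loss 1, one reason the
  hybrid loss retains a BCE term.
* Training uses soft probabilities in the Dice term (no thresholding);
  evaluation (`metrics()`) binarizes at 0.5 by default.
* Empty-mask convention at evaluation: both masks empty — all four metrics
  are 1; exactly one empty — all four are 0.
* Metrics aggregate per image and then average ("macro", the default,
  matching per-dataset mean reporting); a pooled-count "micro" mode is
  available. `IoU = Dice / (2 - Dice)` holds per image as an algebraic
  identity and is used as a cross-check in the tests.

## The synthetic data generator

No clinical data ship with the package; every end-to-end path is exercised
on synthetic pseudo-tumor images (`syntheticSpec()`, `generateDataset()`):

* a smooth dark background (base level 0.18 plus a sum of four random
  low-frequency sinusoids, default amplitude 0.15);
* one to three bright lesions per image: ellipses with area-preserving
  eccentricity, sinusoidal boundary perturbation (modes 2-4, relative
  amplitude up to ~12%), and a Gaussian radial intensity profile peaking
  at 0.75-0.9 — qualitatively mimicking cystic lesions. The union
  footprint is the ground-truth mask; per-lesion equivalent diameters are
  recorded in the metadata;
* additive noise, by default Gaussian with sd 0.05; checkerboard and
  salt-and-pepper models are available for the denoising-specific tests;
* final intensities clamped to `[0, 1]`.

Lesion diameters map clinical size strata to pixels at a documented
2 px/mm: "large" (> 7 mm) becomes > 14 px, "medium" (3-7 mm) 6-14 px,
"small" (< 3 mm) < 6 px, so small-lesion experiments at 64 x 64 use
diameters under 6 px. Everything is a pure function of the spec's seed.

What the generator does *not* emulate: MRA physics, vessel trees, partial
volume effects, realistic polyp texture, or inter-scanner variation.
Passing the end-to-end tests therefore shows that the implementation
learns and segments a controlled bright-blob task far above trivial
baselines — not that it reproduces clinical-grade performance.

## Training recipe and problem sizes

`trainConfig()` defaults to the reference recipe: Adam (`beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-8`, weight decay 5e-4 applied as L2 on all
parameters), learning rate 1e-4, batch size 4, 200 epochs, constant
schedule. "Iterations" in the original description is read as epochs. Both
a 7:3 train/test split and fivefold cross-validation are described there;
the package supports both (`valFraction`, `crossValidate()`) and leaves the
ambiguity to the user rather than resolving it.

The package's own reference experiment — used by the test suite and the
acceptance script — is scaled to a single CPU: 200 synthetic 64 x 64
grayscale samples (medium lesions, Gaussian noise), `baseChannels = 16`,
`sym6` wavelet (the best-performing family in the original ablation),
hybrid loss, 12 epochs at the default learning rate, 70/30 split. Under
these conditions held-out Dice exceeds 0.8 by a wide margin over the
all-background predictor (whose Dice is 0 on images with lesions). Batch
normalization uses batch statistics during training and running statistics
(momentum 0.1, biased variance) at evaluation; with ~400 optimizer steps
the running estimates are well settled.

Everything is seed-controlled (initialization, shuffling, splits, folds,
generator); under single-threaded BLAS two runs with the same seed are
bitwise identical.

## Implementation notes

Feature maps are stored `H x W x C` (R's column-major image convention;
batches add a fourth dimension) — the channels-first `C x H x W` notation
used in the field's papers describes the same object. Convolutions are
im2col + BLAS GEMM in compiled code with hand-derived exact adjoints;
correctness is pinned by finite-difference gradient checks in the test
suite. The max-pooling ablation routes gradients to the first maximum in a
fixed scan order, making backpropagation deterministic under ties.

## Known limitations

* CPU-only and sized for desk-scale experiments; the reference
  configuration (`baseChannels = 64` at 256 x 256) runs forward passes in
  tens of seconds but is not practical to train here.
* Binary segmentation only; no multi-class head, no Hausdorff/boundary
  metrics, no 3D volumes (NIfTI volumes are read slice-wise).
* One DWT level per downsampling stage; no multi-level, stationary or
  lifting-scheme decompositions, and the same wavelet is used at all four
  stages (the original ablation labels one wavelet per run).
* The attention-gate normalization ordering and the skip-fusion rule are
  reasoned choices where the source is ambiguous (see above), so exact
  numerical parity with the original implementation is not expected.
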