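---
title: "Multi-scale attention residual networks for lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale attention residual networks for lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Cystic lesions of the jaw appear on radiographs as radiolucent — darker —
regions with smooth but poorly contrasted boundaries, embedded in textured
bone and confounded by bright anatomical structures. Segmenting them is a
binary, heavily class-imbalanced pixel-labelling problem: most pixels are
background, and the lesion boundary is exactly where the signal is weakest.

`maresnet` implements MARes-Net, a multi-scale attention residual network: a
U-shaped encoder-decoder whose convolution blocks carry residual shortcuts

$$y = f(x) + x,$$

with three attachable modules on the skip-connection path:

* **SFEM** (scale-aware feature extraction module), placed on every skip
  connection. The input is processed by three parallel $3\times3$
  convolutions at dilation rates 1, 3 and 5; neighbouring branch pairs are
  concatenated ($F_{12} = F_1 \oplus F_2$, $F_{23} = F_2 \oplus F_3$, where
  $\oplus$ is channel concatenation), passed through an ordinary $3\times3$
  convolution, re-concatenated with their parent branches, and refined by
  CBAM. The refined maps and the module input are concatenated and projected
  back to the input width by a $1\times1$ convolution, so the module is a
  drop-in replacement on any skip.
* **MCEM** (multi-scale compression-excitation module), consuming the four
  skip features $\{X_1,\dots,X_4\}$. Each level passes through a $3\times3$
  convolution, squeeze-and-excitation channel reweighting and a $1\times1$
  convolution, giving $\{Y_1,\dots,Y_4\}$; the deepest output passes through
  uninterrupted ($F_4 = Y_4$), while every shallower output merges top-down
  context: $F_i = \mathrm{conv}_{3\times3}(Y_i + \mathrm{up}_{\times2}
  (\mathrm{proj}_{1\times1}(F_{i+1})))$.
* **Attention gates** at each decoder level. The upsampled decoder feature
  (gating signal) and the skip feature each pass a $1\times1$ convolution and
  batch normalisation; their sum is rectified, reduced to one channel,
  normalised and squashed by a sigmoid into coefficients
  $\alpha \in (0,1)^{H\times W}$ that multiply the skip feature.

Channel attention (CAM) computes
$\sigma(\mathrm{MLP}(\mathrm{AvgPool}(F)) + \mathrm{MLP}(\mathrm{MaxPool}(F)))$
with a shared two-layer perceptron; spatial attention (SAM) concatenates the
channel-wise mean and max maps and reduces them with a padded $7\times7$
convolution and a sigmoid; CBAM applies CAM then SAM multiplicatively.

Training minimises the smoothed Dice loss
$1 - (2\sum p g + \varepsilon)/(\sum p + \sum g + \varepsilon)$ with Adam.
Evaluation uses precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, IoU
$TP/(TP+FP+FN)$ and F1 $= 2PR/(P+R)$.

## Decisions on points the architecture leaves open

Several details of the architecture are under-determined; the package fixes
them once, as follows.

* **Channel widths and depth.** Base width 16, doubling per stage
  (16, 32, 64, 128; bottleneck 256) over four down-sampling stages. Four
  stages follow from the four-level MCEM ($X_1..X_4$); the width is the
  standard U-Net scaling at one quarter of the classical base and is
  consistent in magnitude with the published parameter budget of the
  reference models. Both are configurable (`model_config()`).
* **Resampling.** $2\times2$ max pooling down, $2\times2$ transposed
  convolution up (keeps the decoder learnable); nearest-neighbour
  upsampling inside MCEM's top-down path, the feature-pyramid convention.
* **Residual shortcut.** Identity when channel counts match, else a
  $1\times1$ convolution with batch normalisation. The block output is the
  plain sum $f(x)+x$ with no activation after the addition, so the zeroed-
  weights limit reproduces the input exactly.
* **Conv/BN/ReLU ordering.** Batch normalisation sits between convolution
  and ReLU in every stage, including inside SFEM and MCEM, for consistency.
* **CAM combination rule.** The two pooled MLP branches are summed and then
  passed through a single sigmoid (the standard CBAM form, and the one the
  module's prose description implies); the variant that applies a sigmoid to
  each branch before summing — whose gains lie in $(0,2)$ — is available via
  `cam_combine = "sigmoid_then_sum"` for comparison.
* **SFEM attention scope.** CBAM is applied to the full concatenation
  $\mathrm{conv}(F_{12}) \oplus F_1 \oplus F_2$ (4C channels), not to the
  fusion convolution's output alone, so the attention sees all parent
  scales. A final $1\times1$ projection restores the input width; without
  it the module would widen every skip sevenfold and the decoder widths
  would be unspecifiable. SFEM weights are independent per level.
* **Attention-gate roles.** The upsampled decoder feature acts as the gating
  signal and the coefficients multiply the skip (MCEM) branch — gating
  exists to refine the skip before concatenation. The intermediate width is
  half the skip width, the attention-U-Net convention.
* **Module order on the skip path.** encoder → SFEM → MCEM → attention gate
  → decoder. SFEM sits in the skip connections and the gate consumes the
  MCEM output, which forces MCEM between the two for all modules to
  coexist.
* **SE/CBAM reduction.** Ratio 16 with a hidden floor of 4, so narrow layers
  retain a usable bottleneck.

## The synthetic data generator

The generator (`synth_params()`, `generate_sample()`) stands in for the
private clinical radiographs: 8-bit grayscale patches with (i) a low-
frequency textured background plus a directional exposure gradient, (ii)
1–3 darkened elliptical lesions — darkened because cysts are radiolucent —
with Gaussian-blurred borders, overlapping into irregular shapes, (iii)
bright elliptical distractor structures that are *not* in the mask, giving
the attention modules something to suppress, and (iv) pixel noise. The mask
is the exact pre-blur lesion union, so labels are noise-free. Everything is
deterministic per seed. Under the default conditions lesion pixels make up
roughly 1–25% of the image, the class-imbalance regime of the clinical
problem; the `"easy"` preset (higher contrast, less blur and noise) defines
the regime used for capability checks.

What the generator does **not** emulate: real mandibular anatomy (teeth,
canals, cortical borders), projection geometry, scanner artefacts, observer
label noise, and the long-tailed shape distribution of real cysts. Passing
tests on synthetic data therefore demonstrate that the implementation can
learn and localise low-contrast blob lesions under class imbalance — not
clinical-grade performance.

## Training protocol and problem sizes

The reference protocol is Adam (β₁ = 0.9, β₂ = 0.999, no schedule), learning
rate 0.001, batch size 4, Dice loss, 200 epochs, with augmentation (flip,
±15° rotation, 0.9–1.1 scaling, ±10% translation, elastic deformation;
two copies per original, a three-fold expansion) and a 60/20/20 split whose
validation and test sizes are floored with the remainder to training. The
best checkpoint is selected by validation IoU; training runs to completion
(no early stopping), aborting only on a non-finite loss.

The package's own capability checks run the same protocol at reduced scale,
chosen so the whole suite stays comfortably desk-sized: the full network
(1.9M-parameter baseline, 4.8M full model) trains on 32 easy-regime
128×128 synthetic images for 12 epochs and is evaluated on 8 held-out
images; a smaller residual model overfits 8 images of size 64×64 for 50
epochs. Twelve epochs are far past convergence in this regime — the training
Dice loss falls below 0.1 within about five.

## Numerical choices

* Dice smoothing ε = 1 (the convention contemporary with the reference
  setup); probability maps are binarised at 0.5.
* Batch normalisation: ε = 10⁻⁵, running-statistics momentum 0.1, biased
  batch variance; inference uses running statistics.
* Initialisation: He-normal for convolution and dense weights, zero biases,
  unit batch-norm gains — deterministic per configuration seed.
* The convolution kernels (im2col + GEMM, written in C++) accumulate in
  single precision, the standard arithmetic for convolutional networks; all
  interfaces and every other operation remain double precision. Oracle
  comparisons in the tests therefore use a 10⁻⁴ tolerance around
  convolutions and 10⁻¹⁰ elsewhere.
* Degenerate metric inputs follow one convention everywhere: if neither mask
  contains a positive pixel all four metrics are 1; any other zero
  denominator gives 0.
* Evaluation aggregates per-image metrics by averaging (the common
  convention; harmonic-mean identities between the aggregated numbers then
  hold only under the alternative `"global_pool"` mode, which is also
  provided).
* Predictions on images whose sides are not divisible by $2^{\text{depth}}$
  reflect-pad up to the next multiple and crop the output back.

## Known limitations

* Single-channel 2-D inputs with one sigmoid output; no multi-class or
  volumetric support.
* The published parameter totals of the reference comparison (1.97M /
  4.58M) do not pin the architecture uniquely; under the documented width
  and depth choices this implementation counts 1.94M for the plain baseline
  and 4.78M for the full network. The per-layer arithmetic behind these
  counts is verified in the test suite.
* Training is CPU-bound and single-threaded BLAS-limited; the package is a
  faithful, testable implementation, not a performance-oriented training
  framework.
* Augmentation is purely geometric (the recipe's four transform families);
  no intensity augmentation.
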