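# maresnet

Binary lesion segmentation of grayscale radiographs with MARes-Net, a
multi-scale attention residual network. The package is aimed at biomedical
image-analysis work where lesions appear as low-contrast, smooth-boundary
radiolucent (dark) regions — the jaw-cyst regime — and where one wants a
fully inspectable, tested implementation of the architecture rather than an
opaque training script.

## The model

The backbone is a U-shaped encoder–decoder whose double-convolution blocks
carry residual shortcuts `y = f(x) + x` (identity when channel counts match,
otherwise a 1×1 projection). Three modules attach to the skip-connection
path, each of which can be switched independently for ablation studies:

* **SFEM** — scale-aware feature extraction on every skip: three parallel
  3×3 convolutions at dilation rates 1/3/5, pairwise fusion
  (`F12 = F1 ⊕ F2`, `F23 = F2 ⊕ F3`, `⊕` = channel concatenation), a 3×3
  convolution per fused map, CBAM refinement of
  `conv(F12) ⊕ F1 ⊕ F2`, and a 1×1 projection of `F12′ ⊕ F23′ ⊕ Fin` back
  to the input width.
* **MCEM** — multi-scale compression-excitation over the four skip levels:
  per level conv3×3 → squeeze-and-excitation → conv1×1, then a top-down
  cascade `F_i = conv3x3(Y_i + upsample(proj(F_{i+1})))`, the deepest level
  passing through unchanged.
* **Attention gates** on each decoder level: coefficients
  `α = σ(ψ(ReLU(θ_g·g + θ_x·x)))` multiply the skip feature.

Channel attention follows `σ(MLP(AvgPool F) + MLP(MaxPool F))` with a shared
two-layer MLP; spatial attention is a padded 7×7 convolution over the
concatenated channel-wise mean and max maps; CBAM composes the two.
Training minimises the smoothed Dice loss
`1 − (2Σpg + ε)/(Σp + Σg + ε)`, ε = 1, with Adam; evaluation reports
precision, recall, IoU `TP/(TP+FP+FN)` and F1 `2PR/(P+R)`.

There is no deep-learning framework dependency: the package ships its own
reverse-mode autodiff tape with C++ (Rcpp/RcppArmadillo) convolution,
pooling and warping kernels, which is what makes every block directly
comparable against hand-rolled oracles in the tests.

A synthetic generator stands in for the (private) clinical data: textured
8-bit backgrounds, 1–3 darkened elliptical lesions with blurred borders and
exact pre-blur masks, bright distractor structures, and seeded determinism
throughout. See the vignette for what it does and does not emulate.

## Worked example

```r
library(maresnet)

# the full architecture and its plain baseline
full <- build_model(model_config())
print(full)
unet <- build_model(model_config(use_residual = FALSE, use_sfem = FALSE,
                                 use_mcem = FALSE, use_ag = FALSE))
print(unet)

# a quick capability check on synthetic lesions
p <- synth_params(size = 64, preset = "easy")
train_set <- generate_samples(8, p, seed = 1)
test_set  <- generate_samples(2, p, seed = 2)

cfg <- train_config(model = model_config(base_width = 16, depth = 3,
                                         use_sfem = FALSE, use_mcem = FALSE,
                                         use_ag = FALSE, seed = 7),
                    epochs = 50, batch_size = 4, lr = 0.001, seed = 9)
fit <- train_model(cfg, train_set, verbose = FALSE)
cat(sprintf("final training Dice loss: %.3f\n", tail(fit$log$train_loss, 1)))
print(evaluate_dataset(fit$model, test_set))
```

prints

```
ResU + AG + SFEM + MCEM  (base width 16, depth 4, 1 input channel)
trainable parameters: 4783401 (4.78 M)
U-Net  (base width 16, depth 4, 1 input channel)
trainable parameters: 1943761 (1.94 M)
final training Dice loss: 0.089
n = 2 images (per_image_mean)
precision 77.21%  recall 95.07%  IoU 74.04%  F1 85.08%
```

The parameter counts identify the architecture variants (all-flags-off is
the plain U-Net baseline; all-flags-on the full network). The small
residual model overfits its eight 64×64 training images to a Dice loss of
0.089 — near-perfect training overlap — while the two held-out images show
the generalisation you can expect from eight training samples; the test
suite's capability check trains the full network on 32 images at 128×128
and requires held-out IoU above 0.8. A command-line surface wraps the same
functions:

```sh
exec/maresnet params --use_residual FALSE --use_sfem FALSE --use_mcem FALSE --use_ag FALSE
exec/maresnet synth --n 100 --size 256 --seed 1 --out data/synth
exec/maresnet train --config config.yaml --data data/synth
```

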