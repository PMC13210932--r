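# momentdiff

Estimating hip and knee joint moments from multimodal wearable sensors
(thigh/shank/foot IMUs, joint-angle encoders, a plantar-pressure insole) is
a core ingredient of lower-limb exoskeleton control. The labelled data
needed to train such estimators is scarce — ground truth requires
synchronized motion capture and force measurements — and heavily imbalanced
toward common cyclic activities. `momentdiff` implements a two-stage
pipeline for this setting, entirely in R:

1. **Classifier-free conditional diffusion over sensor segments.** Fixed
   windows `x ∈ R^{Ts×D}` (25 sensor dims, 2 moment dims, 1 body-weight
   dim by default) are mapped per activity class to `[-1, 1]` by
   class-conditional min–max normalization and modelled with a DDPM:
   forward marginal `x_t = √ᾱ_t x_0 + √(1−ᾱ_t) ε` under a linear β
   schedule (`T = 1000`, 1e-4 → 0.02), a 1-D U-Net noise predictor
   `ε_θ(x_t, t, c)` with residual blocks and linear attention, sinusoidal
   step embeddings, and a learnable class/null embedding pair gated by a
   Bernoulli(0.5) variable during training. Sampling uses classifier-free
   guidance `ε̂ = ε_u + s(ε_c − ε_u)` (default `s = 3`), clipping of the
   clean-sample estimate, and ancestral steps from the reverse posterior
   `q(x_{t−1} | x_t, x̂_0)`. Because sensors *and* moments are generated
   jointly, synthetic segments come with their own regression targets.
2. **Transformer moment regression.** A cropped window (`Tc = 200` in the
   reference configuration) of z-scored sensors (statistics fitted on
   *real* training data only; insole vertical force divided by body
   weight) feeds a post-norm Transformer encoder (`C = 128`, 3 layers, 4
   heads, dropout 0.1) with a per-frame linear head; the loss is
   `L = (1/Tc) Σ_i ‖m_i − m_i*‖²`.

Between the two stages, an augmentation plan converts a ratio `ρ` (total
synthetic / total real, default 2) into per-class generation counts split
*equally* across classes, so augmentation actively reduces class
imbalance. Metrics are RMSE, R², and nMAE (MAE as a percentage of the
ground-truth peak-to-peak range). A seeded synthetic fixture generator
reproduces the statistical structure of multimodal motion data (cyclic /
impedance-like / unstructured classes, cross-channel coupling, ~5:1
imbalance, a documented moment-generating function), so the whole pipeline
is testable without external data. Both networks are implemented natively
with hand-derived backpropagation, pinned by finite-difference tests.

## Worked example

```r
library(momentdiff)

# Toy dataset: 3 activity classes, ~5:1 sequence imbalance
cfg  <- fixture_config(seed = 1)
segs <- segment_sequences(generate_toy_dataset(cfg), Ts = 64)
stats <- fit_zscore_stats(segs, fit_minmax_stats(segs))

# Class-balancing augmentation plan at rho = 2
counts <- tabulate(vapply(segs, function(s) s$class_label, integer(1)), 3)
plan_allocation(counts, rho = 2)
#> <augmentation_plan> rho = 2 (equal split)
#>           class1 class2 class3
#> before        81     32     16
#> synthetic     86     86     86
#> after        167    118    102
#> imbalance ratio: 5.06:1 -> 1.64:1

# Train a small Transformer regressor and evaluate on held-out fixtures
rcfg  <- momentformer_config(Ds = 6, Tc = 48, C = 32, L = 2, heads = 4,
                             ffn_mult = 2)
model <- train_regressor(segs, stats, rcfg, epochs = 10, lr = 1e-3, seed = 1)
test  <- segment_sequences(generate_toy_dataset(
  fixture_config(n_sequences_per_class = c(4, 4, 4), seed = 2)), Ts = 64)
ev <- evaluate_regressor(model, test, stats)
compute_metrics(ev$predictions, ev$truths)
#>         joint  rmse    r2 nmae n_frames
#> 1  hip_moment 0.472 0.804 5.54     3120
#> 2 knee_moment 0.517 0.879 5.01     3120
```

Each row reports, per joint over the pooled evaluation frames: the root
mean squared error in the moment channel's physical units, the coefficient
of determination against the ground truth, and the mean absolute error as
a percentage of the ground-truth range. Training the diffusion model and
generating synthetic data follow the same pattern via `train_diffusion()`,
`reverse_sample()` and `build_augmented_dataset()`; `toy_experiment()`
runs the full study (diffusion training, guided generation,
distribution-matching comparison, and a ρ ∈ {0, 2} regressor sweep over
five seeds) in one call.

A thin command-line interface over these functions is installed at
`inst/cli/momentdiff.R` (`make-fixtures`, `train-diffusion`, `generate`,
`augment`, `train-regressor`, `predict`, `evaluate`).

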