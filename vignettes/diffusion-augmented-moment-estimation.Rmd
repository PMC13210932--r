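---
title: "Diffusion-augmented Transformer estimation of lower-limb joint moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-augmented Transformer estimation of lower-limb joint moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lower-limb exoskeleton controllers need continuous estimates of the net
torques (moments) about the user's hip and knee. Ground truth comes from
inverse dynamics on motion-capture and force-plate data, which is expensive
to collect, so datasets are small and heavily skewed toward common cyclic
activities (walking-like motions) at the expense of posture transitions and
irregular movements. `momentdiff` implements a two-stage remedy:

1. a **classifier-free conditional denoising diffusion model** that learns
   the class-conditioned joint distribution of fixed-length multimodal
   segments — 25 wearable-sensor channels (three IMUs, two joint encoders,
   a plantar-pressure insole), the two moment channels, and a broadcast
   body-weight channel — and generates activity-conditioned synthetic
   segments to enlarge and re-balance the training set; and
2. a **Transformer-encoder regressor** that maps a cropped, z-scored sensor
   window to the frame-wise hip/knee moment sequence.

Because the diffusion model generates sensors *and* moments jointly, a
synthetic segment arrives already labelled: its own moment channels are the
regression targets. This is the mechanism that lets generated data act as
supervised training data.

## Data model and normalization

Raw recordings are variable-length; they are cut sequentially into windows
of `Ts` frames (default stride `Ts`, i.e. non-overlapping; overlap is
exposed as a parameter for regressor data but off by default since nothing
in the method requires it). Each window carries the subject's body weight
repeated over time as the last column, giving the frozen layout
`[Ds sensors | hip moment | knee moment | weight]`, `D = Ds + 3`.

Two normalization schemes coexist deliberately:

* **Per-class min–max for the diffusion model.** For class `c` and
  dimension `d`, extrema are computed over the class-`c` training frames
  and each segment is mapped to `[0, 1]` and then rescaled to `[-1, 1]`.
  A single global range would compress classes whose channels occupy
  narrow sub-ranges; per-class ranges preserve each activity's dynamic
  range. Dimensions with zero range (a constant weight column when only
  one subject is present) map to the constant 0 and carry a degeneracy
  mask; they are kept in the model and the loss — they are trivially
  learnable and keep the full `D`-channel layout intact. Out-of-range
  values at inference are *not* clipped during normalization; only the
  sampler clips its clean-sample estimate.
* **Real-only z-score for the regressor.** Channel means and population
  (1/N) standard deviations are fitted on the *real* training segments
  only (a provenance tag on every segment enforces this), and the insole
  vertical-force channel is divided frame-wise by body weight first.
  Synthetic segments pass through the same statistics after being mapped
  back to physical units with their class's min–max ranges. The population
  vs sample sd choice is immaterial at realistic frame counts and is
  documented here once.

Min–max statistics for the diffusion model are computed on raw physical
values; the weight division of the insole channel applies only in the
regressor path. (The alternative — dividing before fitting the diffusion —
would merely rescale one channel and change nothing structural.)

## The diffusion model

The forward process uses the standard linear variance schedule
`beta_t` from 1e-4 to 0.02 over `T = 1000` steps (the schedule family is
a free choice; linear is the baseline convention), with
`alpha_t = 1 - beta_t`, cumulative `alpha_bar_t`, and the convention
`alpha_bar_0 = 1`. The closed-form marginal
`x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps` is implemented
directly. For CPU-scale chains, `reduced_schedule()` raises `beta_end` so
that `alpha_bar_T < 0.01` still holds — a short chain with the default
`beta_end` would terminate far from the Gaussian prior that reverse
sampling starts from.

Conditioning is classifier-free: a learnable `K x d` class-embedding table
plus a learnable null embedding; during training a per-sample Bernoulli
gate (`p = 0.5`) selects the class row or the null row, so one network
learns both the conditional and the unconditional score. The diffusion
step enters through the sinusoidal embedding
`PE(t, 2k) = sin(t w_k)`, `PE(t, 2k+1) = cos(t w_k)`,
`w_k = 1/10000^{2k/d}` (even `d` required; odd values are rejected rather
than padded), passed through a small MLP; the class embedding is linearly
projected and *summed* with the step embedding, and each residual block
adds its own linear projection of that combined vector to its hidden
features (FiLM-style modulation would be an alternative; addition is the
simpler convention and suffices).

The denoiser is a 1-D encoder–decoder U-Net over the time axis: per level
a residual block (SiLU, width-3 convolutions, conditioning injection, and
a zero-initialised second convolution so every block starts as an
identity) and a kernelized **linear attention** block
(`phi(x) = elu(x) + 1`, single head, normalised by the key sum — the
specific kernel is replaceable and documented as such), with stride-2
convolution downsampling, nearest-neighbour upsampling, and skip
connections concatenated into the matching decoder level. Defaults are 4
levels at widths 64/128/256/512. There are no normalization layers; at
these widths, zero-initialised residual branches plus Adam are stable, and
omitting them keeps the hand-derived backward passes (pinned by
finite-difference tests) small. The training objective is the plain noise
MSE with `t` uniform on `{1, ..., T}`; every stochastic draw (`t`, `eps`,
gate) comes from a single seeded generator in a fixed documented order, so
runs are bit-reproducible.

## Sampling and augmentation

Generation starts from `x_T ~ N(0, I)` and iterates `t = T, ..., 1`. Each
step queries the denoiser twice (class branch, null branch), forms the
guided estimate `eps_u + s (eps_c - eps_u)` (scale `s = 3` by default),
inverts the forward marginal to a clean estimate, clips it to `[-1, 1]`
(only the clean estimate is clipped — intermediate samples are not), and
draws from the reverse posterior with mean

```
mu_t = sqrt(alpha_bar_{t-1}) beta_t / (1 - alpha_bar_t) * x0_hat
     + sqrt(alpha_t) (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * x_t
```

and variance
`sigma_t^2 = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`.
At `t = 1` these coefficients collapse exactly (`mu_1 = x0_hat`,
`sigma_1^2 = 0`), and the posterior mean is returned. A numerical note:
the two mean coefficients do *not* generally sum to one — with
`a = sqrt(alpha_t)`, `b = sqrt(alpha_bar_{t-1})` their sum is
`(a + b)/(1 + ab)`, below one by up to ~1% late in the default schedule;
the exact identity the tests verify is
`b beta_t + a (1 - alpha_bar_{t-1}) = (a + b)(1 - sqrt(alpha_bar_t))`.

The sampler is validated against an analytic oracle: for scalar Gaussian
data the Bayes-optimal noise predictor has a closed form, and with it the
chain must reproduce the data law's first two moments. On the full
1000-step schedule the recovered sd is within a few percent of truth; very
short chains systematically shrink the sd (the fixed-variance reverse
kernel ignores clean-sample uncertainty, which is non-negligible at coarse
steps), which is why distribution-sensitive tests use the full schedule.

The augmentation ratio `rho` is the ratio of *total* synthetic to total
real samples. The synthetic budget `round(rho * n_real)` is split
**equally** across classes (floor, remainder to the largest classes): with
before-counts of 1,729,000 / 420,000 / 344,000 and `rho = 2`, every class
gains 1,662,000 samples and the imbalance ratio falls from 5.03:1 to
1.69:1 — the equal-split reading is the only one consistent with that
arithmetic, and a proportional `per_class` mode is available for
comparison. Generated segments are denormalized with their own class's
ranges; the generated weight column (slightly time-varying) is replaced by
its temporal mean before any weight division. Real and synthetic segments
are not deduplicated.

## The regressor

A segment is partitioned along features into sensors, moments and weight;
a `Tc`-frame crop (random start during training, centre start at
evaluation — the crop policy is free, and a random crop doubles as data
augmentation) of the z-scored sensors feeds a post-norm Transformer
encoder: linear projection `Ds -> C`, additive sinusoidal positional
encoding over the frame index, then `L` layers of multi-head
self-attention and a feedforward block, each followed by residual
connection *then* layer normalization (the post-norm order is taken
literally from the model definition even though pre-norm is now more
common), and a per-frame linear head to the two moments. Defaults:
`C = 128`, `L = 3`, 4 heads, feedforward width `4C`, dropout 0.1 after
both sublayers, GELU activation (the feedforward nonlinearity is a free
choice; GELU is smooth, which also keeps gradient checks exact). Attention
is non-causal over the whole window — as an estimator it looks ahead,
which is a deployment caveat, not a training concern.

The loss is the windowed squared error
`L = (1/Tc) sum_i ||m_i - m_i*||^2` averaged over the batch (identically
two times the elementwise MSE of the `Tc x 2` block). Training uses Adam
with weight decay 1e-5, initial rate 1e-4, reduce-on-plateau (patience 10,
factor 0.9) and early stopping (patience 50), all configurable; one random
crop per segment per epoch.

## Metrics

Per joint over pooled evaluation frames (frame-weighted, not
trial-weighted): RMSE; `R^2 = 1 - SS_res/SS_tot`; and nMAE defined in this
package as `100 * MAE / (max(m*) - min(m*))` — the mean absolute error as
a percentage of the ground-truth peak-to-peak range. The nMAE convention
is ours (reported values in the single digits are consistent with a
percentage-of-range reading); a per-trial aggregation mode exists behind a
flag. `R^2` is undefined for constant ground truth and errors rather than
returning a sentinel.

## The synthetic fixture generator

`generate_toy_dataset()` emulates the *statistical* structure the method
relies on, not biomechanics: three activity classes — cyclic (shared-phase
sinusoids with class-specific frequency and per-channel phase offsets),
impedance-like (smoothed random step transitions shared across channels),
and unstructured (an AR(1) latent at stationary sd 1, shared across
channels plus a private component) — with distinct per-class per-channel
offsets and scales, a body-weight-proportional insole force channel, ~5:1
sequence imbalance by default, and moment channels that are a fixed,
documented linear + 5-frame-lagged function of the two encoder channels
plus `N(0, noise_sd^2)` noise (`noise_sd = 0.05` by default, small against
unit-scale channel amplitudes). The moment function gives the regressor a
known noise floor; the class structure makes conditioning learnable (a
nearest-centroid rule on channel means separates classes essentially
perfectly, which the tests assert at >90%). What the fixtures do *not*
emulate: sensor drift and calibration error, gait-event timing, contact
dynamics, inter-subject kinematic variability beyond offsets, or any
physical consistency between IMU and encoder channels — so passing tests
demonstrate that the machinery works on data with the assumed structure,
not that the model is accurate on real recordings.

## CPU-scale study sizes

`toy_experiment()` runs the whole pipeline at sizes chosen for a single
CPU, and those choices are fixed here: `Ds = 6`, `Ts = 64`, ~135 real
segments at 5:1 imbalance; an 80-step reduced schedule; a 2-level U-Net at
widths 16/32 with conditioning embedding 32 and linear attention disabled
(the convolutional path dominates at these widths; attention stays on in
the reference configuration and is exercised by its own unit and gradient
tests); 5,000 Adam steps at batch 32 and rate 1.5e-3 (a larger rate than
the reference 1e-4, which is tuned to a 1M-iteration budget; the toy loss
curve plateaus within this budget); guidance scale 3 and `rho = 2` for
generation; and a `Tc = 48`, `C = 32`, `L = 2`, 4-head regressor trained
30 epochs at rate 1e-3 for each of 5 seeds and each ratio. The study
reports (a) a distribution-matching table comparing real and synthetic
per-class means on each class's two largest-magnitude channels and (b)
minority-class RMSE at `rho = 0` vs `rho = 2` on held-out balanced
fixtures. Expect roughly ten minutes end to end on one core.

## Known limitations

* Pure-R networks: fine at study sizes, far from the throughput needed for
  the reference configuration; there is no GPU path.
* Short-chain sampling shrinks generated variance (see above); studies that
  compare spreads should use longer chains.
* The classifier-free pair is approximated by one network; with very few
  minority samples the conditional branch for that class is the weakest
  part of the model, which is visible as larger distribution errors for
  the minority class early in training.
* No rejection or quality filtering of synthetic samples, no DDIM-style
  accelerated sampling, no uncertainty estimates on predictions.
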