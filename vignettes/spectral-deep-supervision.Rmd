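---
title: "Spectral deep supervision for lightweight rPPG networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral deep supervision for lightweight rPPG networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dsenn)
```

## The problem

Remote photoplethysmography (rPPG) recovers the blood-volume pulse from
facial video: cardiac perfusion modulates skin color by a fraction of a
percent, strongest in the green channel, and the heart rate is the dominant
spectral component of that modulation within 40–180 bpm (0.667–3 Hz).
End-to-end 3D CNNs map a `3 × T × H × W` clip directly to a T-length pulse
waveform, but they are heavy, slow to converge, and opaque. This package
implements a remedy built from three ingredients:

1. a **spectral auxiliary loss** attached to every intermediate layer
   (deep supervision at zero parameter cost),
2. a **channel-width cost function** that shrinks the network to the
   complexity the task actually needs, and
3. **visualization** of what the intermediate layers learn, which motivates
   both of the above.

## The maximum cross-correlation (MCC) loss

For a reference waveform $y$ and prediction $\hat y$ of length $N$ at rate
$f_s$, both mean-centered, the loss core is

$$\mathrm{MCC} = c_{pr} \times
  \frac{\max_k \; \mathcal F^{-1}\!\left\{\mathrm{BPass}\!\left(
  \mathcal F\{y\}\cdot\overline{\mathcal F\{\hat y\}}\right)\right\}(k)}
  {N\,\sigma_y\,\sigma_{\hat y}},$$

computed as: zero-pad both signals to the next power of two at or above
$2N$ (so the correlation is linear, not circular), transform, form the
cross-spectrum, zero every frequency bin outside 40–180 bpm (positive and
negative frequencies alike, keeping the spectrum Hermitian), invert to a
cross-correlation over lags, and take the maximum. Training minimizes
`negmcc` ($-\mathrm{MCC}$). Taking the maximum over lags is the point of
the construction: a prediction that is right up to a temporal offset —
pulse-transit delay, annotation skew — still earns full credit for the
aligned overlap, where MSE or a Pearson loss would punish it severely.

Numerical choices that were genuinely open, and how they were fixed:

* **$c_{pr}$** ("power ratio") is the fraction of the *reference's* non-DC
  power inside the band, computed from $y$ alone. It is therefore a
  constant with respect to the prediction and contributes no gradient; it
  discounts windows whose reference is noise-dominated.
* **Normalization** divides by $N\sigma_y\sigma_{\hat y}$ with population
  standard deviations of the mean-centered, *unpadded* signals. The $N$
  factor makes the loss dimensionless and length-independent: a perfect
  in-band match scores ≈ 1 at any $N$.
* **Lags** are unrestricted. The band-pass removes DC, so end effects do
  not create spurious maxima.
* **Degenerate (constant) signals** raise an error rather than returning
  0, to surface label bugs early; inside the training loop a constant
  *tap trace* is skipped per-batch with a warning instead, since a
  correlation loss has no defined direction there.

Two properties deserve honesty. First, a finite windowed tone leaks a small
fraction of its energy out of band (≈ 0.8 % for a 10 s tone), and both
$c_{pr}$ and the masked correlation inherit that fraction, so the
self-correlation of a pure in-band tone scores ≈ 0.98, not exactly 1.
Second, the zero-padded *linear* correlation of two length-$N$ windows
offset by $k$ samples can only overlap on $N-k$ samples: MCC of a delayed
copy retains the $(1-k/N)$ overlap share of the aligned value rather than
being exactly invariant. Both effects are intrinsic to the definition; the
test suite pins them quantitatively (oracle equivalence against a direct
lag-scan is at $10^{-15}$).

## The encoder–decoder network

The network is a PhysNet-style 3D CNN with twelve convolutional layers:

| block | layers | kernel | output T | notes |
|---|---|---|---|---|
| stem | 1 conv | (1,5,5) | T | spatial avg-pool ×2 *before* the conv; unpadded |
| encoder1 | 2 convs | 3×3×3 | T | spatially unpadded ("border-trimming"); spatial pool ×2 after |
| encoder2 | 4 convs | 3×3×3 | T/2 | padded; spatiotemporal pool (2,2,2) after |
| encoder3 | 2 convs | 3×3×3 | T/4 | padded; spatiotemporal pool (2,2,2) after |
| decoder | 2 transposed convs | (4,1,1), stride (2,1,1) | T/2 → T | temporal upsampling |
| head | 1×1×1 conv | — | T | after global spatial pooling |

Every convolution carries a bias and is followed by batch normalization
(affine) and ReLU, except the head. With the baseline widths — stem 32,
encoders 64/64/64, decoders 64/64 — this reconstruction counts **866,689**
trainable scalars; with the optimized widths (stem and encoders 16,
decoders 2/2) it counts **57,087**; reducing only the encoder to 16 gives
**77,857** (≈ 78 k, a 91 % reduction from baseline). Those three counts are
the architecture's anchors and are enforced by the test suite; they also
settle an ambiguity in the width bookkeeping: only the decoder-at-64
baseline reproduces all three simultaneously, so `preset_config("baseline")`
uses decoder widths (64, 64) and the sweep is what produces the small
decoders.

The placement of the stem's spatial pooling *before* its convolution, with
the stem and encoder1 convolutions spatially unpadded, reproduces the
56×56 encoder1 activation geometry from 128×128 input
(128 → 64 → 60 → 58 → 56). The practical consequence is a shape contract:
T must be a multiple of 4, and H and W must be even with $(H/2-8)$ a
positive multiple of 8 (32, 48, 64, 128, ...). Violations raise an error
naming the offending axis.

Average pooling is used where the original design family uses max pooling:
the pooled quantity here is a photometric mean signal, the choice does not
affect any parameter count, and it keeps the pooling linear (which the tap
analysis below exploits). Weights are initialized fan-in-scaled Gaussian
from a recorded seed; the network, backpropagation, and Adam are
implemented in the package itself (R with C++ convolution kernels), and the
whole gradient path is verified against finite differences in the tests.

## Deep supervision

Six *taps* expose intermediate activations: stem, each encoder block, each
decoder layer. A tap is the spatial average of its activation — a
channels × $T_\ell$ matrix at the layer's own temporal rate
$f_\ell = f_s T_\ell / T$ — so taps add **zero** trainable parameters and
the train/test network differs only in batch-norm statistics. The
composite objective is

$$L = L_\mathrm{primary}(\hat y, y) \; + \; w \sum_{\ell}
      L_\mathrm{aux}\big(\overline{a_\ell},\; y \downarrow T_\ell\big),$$

with $w = 0.1$, primary MSE, auxiliary `negmcc`, $\overline{a_\ell}$ the
across-channel mean trace, and $y \downarrow T_\ell$ the label linearly
interpolated to the tap length (which preserves in-band peak frequencies).
The across-channel mean is a deliberate choice: trained decoder channels
collapse onto one or two shared temporal patterns, so the mean preserves
the consensus pulse; a per-channel variant is available via
`supervision_config(channel_mode = "per_channel")`. The auxiliary loss is
spectral on purpose — early layers carry the pulse with arbitrary phase
and sign, which a lag-maximized band-limited correlation tolerates and a
pointwise loss would not.

Training follows the standard recipe for this network family: Adam (learning rate $10^{-4}$,
weight decay 0.1 applied as L2-in-gradient, the convention of the
mainstream deep-learning toolchain), batch size 6, default 100 epochs.
Validation heart-rate RMSE is computed every epoch; `epochs_to_threshold()`
reads convergence speed off the history.

## Heart-rate evaluation

Predicted and reference waveforms go through the *same* pipeline:
frequency-bin mask band-pass to 40–180 bpm, standardization, then a
sliding-window short-time Fourier analysis (default 5 s window, 0.1 s
step, Hann-tapered, zero-padded to ≥ 2048 bins so the grid is finer than
1 bpm at 30 fps). Each window's HR is the argmax of the in-band magnitude
spectrum; agreement is summarized by RMSE, MAE, and Pearson correlation
over windows (pooled across clips), with mean ± SD and Welch's two-sided
t-test across repeated runs. PCC of constant series is undefined and is
flagged rather than silently emitted; identical constant series report 1
by convention.

## Channel-width selection

`sweep_channels()` retrains the network across widths
$\alpha \in \{1,2,4,\dots,64\}$ — encoder axis first with the decoder at
baseline, then the decoder axis with the encoder fixed at its selected
width — and `compute_cost()` selects
$\arg\min_\alpha\, \epsilon(\alpha) + \lambda P(\alpha)$ with
$\lambda = \sigma_\epsilon / \sigma_P$, which equalizes the spread of the
two addends across the sweep. Ties go to the smaller parameter count,
consistent with the goal of weight reduction. Repeats default to 10 (the
evaluation protocol's run count) and are reducible for desk-scale work.

## The synthetic data generator

The generator emulates the statistical structure rPPG rests on, not faces:
a skin-like ellipse whose color is modulated by a PPG-shaped waveform
(fundamental 50–150 bpm by default, second harmonic 0.3, 0.1 Hz baseline
wander, sensor noise), over a static texture, with shared per-frame
illumination flicker, per-pixel Gaussian noise, and a smooth bounded
random-walk translation of the region. Modulation is green-dominant
(R:G:B ≈ 0.5:1:0.4, hemoglobin absorption ordering) at ~2 intensity
levels against base levels near 150/105/85 — small relative to the base,
as in real video. Subjects (a base color + texture identity) are exclusive
to one split. Default geometry is 32×32 pixels × 128 frames at 30 fps,
a desk-scale proxy for the 128×128×256 clips of public benchmarks; the
full geometry remains available through `scene_params()`.

Before any learning is attempted the dataset is certified *solvable*: the
classic hand-crafted extraction (mean green inside the region, band-pass,
STFT) achieves < 2 bpm RMSE at default noise, and difficulty behaves
monotonically (error grows as modulation shrinks against noise; the
in-band SNR of the mean trace falls with motion). What passing tests on
this data do **not** show: robustness to real faces, expressions, specular
highlights, compression artifacts, or skin-tone diversity — none of which
the generator models.

## Desk-scale study sizes

The training-based checks in the test suite run at sizes chosen so the
full pipeline is exercised on an ordinary CPU: the end-to-end learning
check trains the optimized configuration on 36 clips of 3×128×32×32 for
15 epochs (evaluation window 4 s, matching the 4.27 s clips) and requires
test HR RMSE < 5 bpm — the trained model reaches well under 1 bpm — and
the convergence-direction check compares epochs-to-10-bpm with and without
deep supervision over three seeds at the same geometry (a 30-clip dataset,
10 epochs per run). These sizes are the package's study conditions for the
synthetic benchmark; the training recipe itself (optimizer, rates, batch
size) is never scaled. The learning check needs its stated size: with
fewer clips or epochs a fraction of evaluation windows still locks onto
the second PPG harmonic (2× the true rate, inside the detection band for
rates under 90 bpm), which is the characteristic failure mode of an
under-trained spectral readout.

## Known limitations

* The MCC loss treats the maximizing lag as locally constant when
  differentiating; at lag ties the subgradient choice is the first
  maximum.
* Batch normalization uses batch statistics in training mode, so training
  is deterministic only for a fixed batch composition (seeded shuffling
  guarantees this).
* The evaluation window must fit inside the clip; clips shorter than 5 s
  need an explicitly smaller window (`window_s`).
* Convolution kernels are single-threaded; the package targets desk-scale
  experiments, not GPU-scale benchmark training.
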