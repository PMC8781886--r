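---
title: "Measuring heart rate from facial video: the rppgnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring heart rate from facial video: the rppgnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Each heartbeat pushes a blood-volume wave through the skin's capillary bed,
changing how much light the skin absorbs. The change is tiny — a fraction of
an intensity unit per pixel in 8-bit video, strongest in the green channel —
but it is coherent over large skin areas and over time, so a camera can
recover the pulse without touching the subject. This is remote
photoplethysmography (rPPG). `rppgnet` implements a complete rPPG pipeline:
landmark-driven region-of-interest (ROI) extraction, a lightweight
spatiotemporal network that maps an ROI clip to a pulse trace, a
shape-sensitive training loss, spectral heart-rate estimation, agreement
metrics, and a synthetic pulse-video generator that lets every stage be
exercised and validated without clinical recordings.

## ROI geometry

Only skin carries pulse information; eyes, brows, lips and background add
noise. The pipeline therefore crops two rectangles from each frame using the
standard 68-point facial landmark set (0-based: jaw 0–16, brows 17–26, eyes
36–47, mouth 48–67), which an external detector such as OpenFace supplies:

* **cheek**: horizontally from jaw point P3 to jaw point P13; vertically
  from the lowest lower-eyelid point (max y of P40, P41, P46, P47) to the
  highest upper-lip point (min y of P50, P52);
* **forehead**: horizontally from brow point P19 to P24, extending upward
  from the higher brow by half the cheek height.

Both crops are resized with bilinear interpolation — cheek to 64×96, forehead
to 32×96 — and stacked into a single 96×96×3 tile. 128 consecutive tiles,
sampled every 8 frames, form one network input clip.

Numerical choices the landmark convention leaves open: image coordinates are
0-based with y increasing downward; fractional box edges are rounded
half-up (plain nearest-integer rounding with ties to even would round a box
at `y` and the same box shifted by an integer to different pixel offsets,
breaking translation equivariance — a property the test suite checks);
forehead boxes that extend above the frame are clipped to row 0 with a
warning rather than rejected, since brow-anchored boxes routinely graze the
frame edge on close-up video.

## Temporal central-difference convolution

A plain 3-D convolution responds to absolute intensity, which makes it
sensitive to illumination. The temporal central-difference variant (3DCDC-T)
adds a term that responds to *change over time*: with kernel weights
$\omega$, receptive field $\mathcal{C}$, and the field split into the
current time step $\mathcal{R}'$ (temporal offset 0) and the adjacent time
steps $\mathcal{R}''$,

$$y(p_0) = \sum_{p_n \in \mathcal{C}} \omega(p_n)\, x(p_0 + p_n)
  + \theta \Big(-x(p_0) \sum_{p_n \in \mathcal{R}''} \omega(p_n)\Big).$$

$\theta \in [0,1]$ trades intensity-level against temporal-gradient
information; $\theta = 0$ is exactly conventional convolution. The layer
default is $\theta = 0.6$, the convention of the central-difference
literature, and it is surfaced in the layer spec rather than hard-coded.

The implementation folds the correction into the kernel — subtracting
$\theta \sum_{\mathcal{R}''} \omega$ from the centre tap — so one ordinary
convolution (im2col + GEMM in C++, chunked one output time slice at a time
to bound memory) computes the full operator under any stride and padding.
A nested-loop transcription of the definition serves as the oracle: the
optimized path must match it to 1e−5 absolute on dozens of random instances
across $\theta \in \{0, 0.3, 0.6, 1\}$, and in practice agrees to 1e−12.
Bias, when enabled, is added once after the combined sum, which keeps the
$\theta = 0$ case identical to a conventional biased convolution.

## 3D convolutional block attention

Each block ends with a 3-D convolutional block attention module (3D-CBAM):
channel attention then spatial attention, each a multiplicative rescaling.

* **Channel attention** pools the feature map globally over $T \times H
  \times W$ by average and by max, pushes both descriptors through a shared
  two-layer perceptron ($C \to C/r \to C$, inner rectifier), sums the two
  outputs and applies the sigmoid. Some renderings of this formula
  distribute the sigmoid over the sum ($\sigma(\cdot) + \sigma(\cdot)$),
  which contradicts the original CBAM design and would allow attention
  weights up to 2; this package applies the sigmoid once, to the sum.
* **Spatial attention** pools over channels (average and max), stacks the
  two maps, convolves with a 7×7×7 kernel (padding 3) and applies the
  sigmoid.

Both maps therefore lie strictly in (0, 1) and the module preserves shape.
The reduction ratio $r$ and perceptron biases are unreported in the rPPG
setting; the package uses CBAM's original defaults ($r = 16$, no perceptron
biases), a combination under which the assembled network reproduces the
architecture's canonical ~0.66 M parameter count exactly (655,869).

## Architecture

The default network, for a 128×96×96×3 clip:

| stage | layer | output |
|---|---|---|
| stem | conv 1×5×5, 3→16 | 128×96×96×16 |
| | avg-pool 1×2×2 | 128×48×48×16 |
| block 1 | 2 × 3DCDC-T 3×3×3 (16→32, 32→32) + 3D-CBAM | 128×48×48×32 |
| | avg-pool 1×2×2 | 128×24×24×32 |
| block 2 | 2 × 3DCDC-T (32→64, 64→64) + 3D-CBAM | 128×24×24×64 |
| | avg-pool 1×2×2 | 128×12×12×64 |
| block 3 | 2 × 3DCDC-T (64→64) + 3D-CBAM | 128×12×12×64 |
| | avg-pool 1×2×2 | 128×6×6×64 |
| block 4 | 2 × 3DCDC-T (64→64) + 3D-CBAM | 128×6×6×64 |
| head | adaptive avg-pool to 1×1, conv 1×1×1, 64→1 | 128×1×1×1 |

Pooling is spatial only — temporal resolution is never reduced, so a T-frame
clip always yields a T-sample trace. Every convolution is followed by a
rectifier except the head, which stays linear so the trace can be
zero-centred and negative, as pulse traces are. The stem's 1×5×5 kernel is
the natural 3-D reading of a per-frame "2-D" colour-mixing layer, and the
head's "1-D" convolution is a 1×1×1 channel collapse — the only readings
consistent with the shape chain above. Paddings ((0,2,2) stem, (1,1,1)
blocks, (3,3,3) attention) are the unique size-preserving choices. Batch
normalisation is omitted: the reference architecture does not use it, and
adding it would change the parameter census. Input clips are scaled to
[0, 1] by the maximum representable intensity (255 by default), recorded in
the network config.

Weight initialisation (left open by the reference protocol) is He-scaled
normal for all convolutions and perceptron layers with zero biases, seeded
through R's RNG.

## Loss and training

Predicted and reference pulse traces differ in scale and offset by
construction (camera units vs oximeter units), so magnitude-sensitive
losses are wrong. Training minimises the negative Pearson correlation

$$L = 1 - r(x, y) \in [0, 2],$$

which is invariant to positive affine transforms of either trace and
penalises only waveform-shape mismatch. Degenerate (zero-variance) inputs
return $L = 1$ with a warning and a zero gradient, so a pathological batch
degrades an update instead of killing the run. Gradients are hand-derived
and verified against central finite differences through the entire network
(worst relative error ~1e−7 on a tiny configuration).

The optimiser is Adam at learning rate 2e−4, batch size 8, 30 epochs (all
configurable); batch gradients are clip-averaged. The reference PPG is
z-scored and linearly interpolated at frame timestamps, then sliced to each
clip's frame range, so every clip carries a frame-aligned label.
Left-right flip augmentation mirrors the width axis and leaves labels
untouched, doubling the corpus. When validation clips are given, the
parameters with the best validation loss are kept — checkpoint selection is
left open by the reference protocol, so best-by-validation is this
package's choice, with final-parameters fallback when no validation set
exists. Splits are by scene identity, mirroring subject-wise evaluation.

## Heart-rate estimation

The predicted trace is band-passed to 0.7–2.5 Hz (42–150 bpm) with a
6-pole Butterworth filter applied forward–backward, so the filter is
zero-phase and predicted and reference peaks stay time-aligned for
agreement analysis. Two implementation details matter at 10 s window
lengths: the trace mean is removed first, and the signal is extended by odd
reflection (about three cycles of the low band edge) before filtering, so
the forward–backward start-up transient falls outside the returned samples.

Heart rate per window is spectral: the 10 s window is mean-removed,
Hann-windowed, zero-padded until the frequency grid is at most 0.01 Hz
(0.6 bpm) per bin, and the rate is 60 times the frequency of the largest
in-band PSD peak. Windows slide by 2 s. "PSD" alone under-specifies the estimator; a Hann-windowed zero-padded periodogram is the single-segment limit
of Welch's method and gives stable peaks at this window length. Predicted
and reference series always use identical spectral settings.

Agreement is reported as MAE, RMSE and Pearson's R over all windows pooled
across recordings, plus a Bland–Altman table (per-window mean/difference
with bias and 1.96 SD limits). With a single window, or a constant series,
R is undefined and reported as `NA` with a warning rather than a number.

## The synthetic generator

`render_scene()` produces what the method assumes real data provides: an
elliptical "skin" region whose pixels are additively modulated by a
quasi-periodic pulse (fundamental plus a 0.3-weighted second harmonic,
instantaneous frequency following a configurable 42–150 bpm trajectory),
with a green-dominant colour vector (green twice red/blue), per-pixel
Gaussian noise, a slow global sinusoidal illumination drift, a consistent
68-point landmark set with Gaussian jitter, and a 60 Hz reference trace
from the same phase function. Defaults — 30 fps, pulse amplitude 2
intensity units against noise of SD 1, jitter 0.5 px — put per-pixel SNR
near 2 but leave single pixels useless for timing, so spatial pooling is
genuinely required; the landmark template guarantees the cheek and forehead
boxes land on skin.

The generator validates itself independently of any network: averaging the
green channel over the true skin mask, band-passing and taking windowed PSD
peaks recovers the configured trajectory within 2 bpm in every window of a
noise-free scene. What the generator does **not** emulate — head motion,
specular highlights, compression artifacts, non-skin facial structure,
realistic PPG morphology variation — bounds what passing tests mean:
they demonstrate the pipeline's mechanics and trainability, not clinical
performance on real video.

## The scaled-down recovery study

`rppg_recovery_experiment()` runs the whole loop at a size chosen to finish
in minutes on one CPU while keeping the learning problem honest: 20 scenes
of 15 s at 30 fps with constant heart rates spread over 54–108 bpm
(shuffled so the scene-identity split does not align with frequency), 24×24
ROI tiles, 64-frame non-overlapping clips, a two-block network (8/16/16
channels, reduction ratio 8, θ = 0.6), Adam at 1e−3 for 6 epochs with flip
augmentation, 14 training and 6 held-out scenes. The elevated learning rate
relative to the full protocol matches the much smaller network; it is a
configuration choice of this study, exposed as an argument. Success is
measured on held-out scenes as the mean Pearson correlation between the
band-passed predicted trace and the aligned reference, and the pooled MAE
of windowed heart rates against the configured trajectory.

## Known limitations

* The network is CPU-bound R/C++ with no GPU path; full-scale training on
  real benchmark datasets such as PURE or UBFC-rPPG is out of scope by
  design.
* Landmark detection is consumed, not performed; frames with failed
  landmarks must be handled upstream.
* The synthetic generator's simplifications above mean its results
  over-state real-world accuracy.
* Heart-rate estimation is spectral only; inter-beat intervals and HRV are
  out of scope.
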