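---
title: "Recognising facial gestures from EEG band power with a SOM-Hebb classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising facial gestures from EEG band power with a SOM-Hebb classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Facial movements — closing the eyes, widening them, clenching the teeth on one
side — leave strong, spatially structured artifacts in scalp EEG: eye closure
raises alpha power over posterior electrodes, eye widening raises power over
the frontal electrodes, and unilateral teeth clenching injects broadband EMG
into the temporal electrode on the clenching side (channels 13 and 14 of the
16-channel montage). Conventional EEG analysis removes these artifacts;
`somgesture` implements the opposite idea: treat them as the *signal* and
classify facial gestures from them, giving a simple, robust channel for
brain-computer-interface style control.

Seven gestures are defined by combining these movements (`gesture_descriptions()`):
open eyes (G1), closed eyes (G2), open eyes + right clench (G3), open eyes +
left clench (G4), eyes wide open (G5), closed eyes + right clench (G6), closed
eyes + left clench (G7). Recognition tasks use prefix subsets: (G1,G2),
(G1..G4), (G1..G5), (G1..G7).

## Features: per-channel band power

Each 2 s, 16-channel segment sampled at 125 Hz is reduced to a 48-dimensional
vector $\vec{x} = (\xi_0, \ldots, \xi_{47})$: the absolute power of each
channel in the alpha (8–13 Hz), beta (14–30 Hz) and theta (4–7 Hz) bands, laid
out band-major (alpha ch1..16, beta ch1..16, theta ch1..16). The delta band is
excluded — its cycles are too slow to estimate reliably from a 2 s window.

The band-power estimator is a design choice of this package (the quantity
itself — "power in a band" — does not pin one down): Welch's method with a
Hann window of 1 s, 50% overlap, and linear absolute (not relative) power.
This averages three periodograms per segment, trading a little spectral
resolution (1 Hz bins) for variance reduction, and is fully reproducible.
The density is normalised so that its integral over the whole grid equals the
signal's mean squared amplitude (Parseval); a unit sinusoid therefore carries
total power $A^2/2 = 0.5$, which the tests verify to 5%. Band integrals use
the trapezoidal rule over the bins whose centers fall in the closed interval
$[lo, hi]$; at 1 Hz resolution the 13|14 Hz and 7|8 Hz band boundaries place
no bin in two bands. No feature normalisation is applied by default
(`band_features(..., normalize = TRUE)` exists but is off everywhere,
including the acceptance checks).

## The SOM-Hebb classifier

The classifier is a hybrid of an unsupervised self-organizing map and a
supervised Hebbian labeling layer.

**Learning phase.** An $M \times M$ grid of neurons ($M = 8$ by default) each
holds a weight vector $\vec{m}_k \in \mathbb{R}^D$. For every presented
training vector the *winner* is the neuron minimising the Euclidean distance
$d_k = \sqrt{\sum_j (\xi_j - \mu_{kj})^2}$ (ties broken by lowest neuron
index), and every neuron moves toward the input:

$$\vec{m}_k(t+1) = \vec{m}_k(t) + h_{Ck}\,(\vec{x} - \vec{m}_k(t)),
\qquad h_{Ck} = \alpha(t)\, e^{-\|\vec{r}_C - \vec{r}_k\|^2 / \sigma^2(t)},$$

with $\vec{r}_k$ the neuron's integer lattice coordinates. Note the
neighborhood kernel uses $\sigma^2$, not the $2\sigma^2$ of some SOM
formulations, and is evaluated for *all* neurons — no cutoff radius. Since
$0 < h \le \alpha(t) \le 1$, each update is a convex combination, so weights
can never leave the data's per-dimension range once initialised inside it.

**Labeling phase (Hebbian).** The labeled training set is fed once more
through a winner search (all neurons eligible); each neuron records how often
it won and under which class. A neuron is associated with the class that made
it win most often (ties to the lowest class index). Neurons that never won
get no class and are *disabled*.

**Recall phase.** Classification is a single winner search over the enabled
neurons only, with frozen weights; the prediction is the winner's class, and
its grid coordinates are reported alongside. Excluding disabled neurons
prevents false recognition by map regions that never represented training
data.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `grid_size` | 8 | map side; 64 neurons comfortably cover 2–7 classes of 30 vectors each |
| `epochs` | 100 | passes over the training set; well past quantization-error plateau at these sizes |
| `alpha0`, `alpha_final` | 0.5 → 0.01 | linear learning-rate decay, conventional Kohonen practice |
| `sigma0`, `sigma_final` | $M/2$ → 0.5 | neighborhood radius decay, global ordering → local refinement |
| `window_length`, `overlap_fraction` | 1 s, 0.5 | Welch estimator resolution/variance trade-off (1 Hz bins, 3 windows per segment) |
| `noise_sd` | 2 | generator background noise (see below) |

The schedule clock ticks per *presentation* (not per epoch): $\alpha(t)$ and
$\sigma(t)$ are interpolated over `epochs × n` presentations. Presentation
order is a fresh seeded shuffle each epoch. Weights are initialised uniformly
within the training data's per-dimension range. All three random sources —
generator, initialisation, shuffling — flow from named integer seeds, so every
pipeline run is bit-reproducible; this is asserted in the tests.

## The synthetic generator

No public recordings accompany the recognition protocol, so the package ships
a generator that reproduces the *band-power structure* the classifier
consumes — not realistic EEG. Each channel is the sum of one random-phase
sinusoid per band (frequency drawn uniformly inside the band), scaled by the
gesture's per-channel × per-band amplitude multiplier; clench gestures add
white noise band-passed to 14–30 Hz (inside the measured beta band) on the
clench-side temporal electrode; white Gaussian background noise is added
everywhere. One sinusoid per band, rather than filtered noise, was chosen
deliberately: it gives the closed-form expected band power $(mA)^2/2$, so the
tests can check feature extraction and signature effects analytically.

Default signatures encode the observed orderings: posterior alpha multiplier
3 when the eyes are closed (G2, G6, G7); frontal multiplier 2.5 for eyes wide
open (G5); EMG gain 3 on channel 14 for right clench (G3, G6) and channel 13
for left clench (G4, G7). G5 additionally carries a multiplier of 1.6 on both
temporal channels: the scalp region excited by eye widening lies near
electrodes 13 and 14, which is what makes G5 confusable with the clench
gestures — the hardest confusion in the reference protocol — and without it
the five-class task is unrealistically easy (adding G5 *raised* the average).
The electrode role map (`channel_roles()`) is configuration, defaulting to
frontal 1–2, posterior 7–8, temporal 13/14.

Effect sizes and the background noise level are free parameters (the
underlying observations are figural, not quantitative). `noise_sd = 2` was
fixed once, from a coarse scan, as the level at which the synthetic tasks
show graded difficulty — two-gesture recognition essentially perfect,
seven-gesture recognition in the mid-90s, accuracy non-increasing in the
number of classes — rather than all tasks saturating at 100%. What passing
the end-to-end checks shows is therefore that *the pipeline recovers the
class structure its features encode at realistic separations*; it says
nothing about electrode placement variability, non-stationarity, 1/f
background, blink transients or inter-subject variation, none of which the
generator emulates.

## Numerical and degenerate-input choices

- Winner ties (exactly equidistant neurons) go to the lowest neuron index;
  label ties to the lowest class index. Both are documented and tested.
- A training dimension with zero range initialises every neuron at that
  constant value (the uniform draw degenerates).
- `sigma_t <= 0`, empty training sets, all-disabled masks, band/geometry
  mismatches and malformed files raise immediate, specific errors rather than
  propagating NaNs.
- Win counting is a single pass over the training set; the count table is
  order-independent either way.
- Labeling reuses the SOM training set — the offline flow feeds one dataset
  through both phases.
- Segment files are delimited text with full-precision values; model files
  are JSON with weights as 17-significant-digit strings, so save/load
  round-trips are bit-exact.

## Problem sizes used in the checks

The test suite and the acceptance script mirror the reference protocol
directly: 30 training segments per gesture (210 vectors for seven gestures),
an 8 × 8 map, held-out test sets of 30 trials per gesture (50 in the
two-gesture case), and means over 5 seeds for the stochastic end-to-end
checks. Module-level tests use smaller maps and epoch counts purely for
speed; every algorithmic property they check is size-independent.

## Known limitations

- The synthetic accuracies are not estimates of the human-subject accuracies
  of the reference protocol; the generator's separations, not the method,
  set their level. Only qualitative behaviour (degradation with class count,
  G5/clench confusability) is expected to transfer.
- The SOM schedule used in the original protocol is not public; the defaults
  here are conventional but not a reconstruction.
- Recall is batch-only; there is no streaming/online acquisition path.
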