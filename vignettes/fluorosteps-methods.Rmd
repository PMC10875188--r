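---
title: "Models and methods behind fluorosteps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorosteps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fluorosteps is an integrated toolkit for single-molecule TIRF microscopy
analysis: it simulates photobleaching traces and EMCCD-like movies with
full ground truth, detects fluorescent foci with sub-pixel precision,
corrects chromatic aberration between colour channels, counts
photobleaching steps with a convolutional-recurrent network, locates step
time points, tracks diffusing molecules, and infers complex
stoichiometries. This vignette explains the underlying models, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

## The photobleaching trace model

A fluorescent focus contains `n` fluorophores. Bleaching is stochastic
with a constant hazard: each fluorophore independently bleaches each
frame with probability `p`, so lifetimes are geometric with mean
`1/p - 1` emitting frames. A half-life of `h` frames corresponds to
`p = 1 - 2^(-1/h)`; the movie simulator defaults to `h = 40.5`. Because
the hazard is constant, more fluorophores bleach in the first frame than
in any other — a fluorophore may bleach before contributing to a single
frame, in which case its step is real but invisible in principle. This
is deliberately retained: it is one of the irreducible error sources for
any step-counting method, together with simultaneous bleaching of two
fluorophores in the same frame.

Step heights follow one of two models:

* `constant_pm20` — unit height times Uniform(0.8, 1.2), appropriate for
  organic dyes such as Cy5;
* `cos2` — `max(cos^2(theta), 0.10)` with the dipole angle `theta`
  uniform on `[0, pi/2]`, reflecting the orientation dependence of
  excitation for surface-immobilized protein fluorophores (in-plane
  dipoles still experience roughly 10% of the peak field, hence the
  floor). The exact sampling geometry is not uniquely determined by the
  physics; both the angle distribution and floor are parameters.

Noise is i.i.d. Gaussian per frame. Its scale is set from the **average
step signal-to-noise ratio** (aSNR): with `k` plateaus of means `m_i`
and standard deviations `s_i`,

```
aSNR = mean over steps of  2 * |m_i - m_(i+1)| / (s_i + s_(i+1)).
```

The simulator first sets the noise standard deviation analytically
(mean plateau difference divided by the target aSNR), then rescales the
drawn noise once by the ratio of the realized to the target aSNR,
measured over plateaus with at least two frames. Realized aSNRs match
the target to within about 1% on average. A length-2 `target_asnr` is a
sampling range, drawn **uniformly** per trace: an early version sampled
log-uniformly, which under-represented the high-SNR regime and produced
a classifier miscalibrated exactly where traces are cleanest.

For **training data only**, a plateau-length restriction prevents the
classifier from learning to overpredict: two steps closer than
`ceiling(25 / aSNR^2)` frames (clamped to [1, 20]) are pushed apart, the
intermediate plateau being extended until it is statistically resolvable
at that noise level. The constant 25 is a configuration parameter; at
aSNR 8 and above the restriction is inactive. Test data always keeps
fully stochastic bleaching.

## The movie model

Complexes are 2-D Gaussian functions (`psf_sigma = 1.3` px) whose
amplitude per frame is the sum of the surviving fluorophores'
intensities. Label counts per complex follow a binomial distribution
(sites `N`, labelling probability `p`) or a fixed count. Each frame adds

* a constant camera baseline (100 counts),
* a smooth non-uniform autofluorescence surface (low-order 2-D
  polynomial, seedable, peak-to-peak amplitude 30 counts by default),
* Gaussian dark current (sigma 10 counts),
* gamma-distributed shot noise on the signal (shape 50, mean-preserving,
  relative sd `1/sqrt(shape)`), standing in for the excess noise of
  EMCCD gain.

Complexes are placed by rejection sampling with a minimum separation
(12 px default — wide enough that a neighbour never enters another
spot's 11 x 11 fitting patch or the core of its background annulus) so
ground-truth spots are genuinely resolvable; an over-filled field is an
error. Brownian movies draw per-frame, per-axis
displacements with variance `2 D dt` (converted to pixels) and reflect
at the field boundary.

Default brightness (160 counts/fluorophore peak) against the default
noise gives extracted traces with aSNR around 20 (bright, dye-like
movies); protein-fluorophore conditions are reached by lowering the
amplitude.

## Image enhancement and spot detection

The composite projection averages the first 20% of frames (persistent
foci gain signal-to-noise) and takes the per-pixel maximum over the same
window (so foci that bleach within the first frames are not lost); both
terms are min-max normalized, combined with equal weight, and
renormalized. A constant stack normalizes to zeros rather than NaN.

Two enhancement methods are available. The high-pass filter subtracts a
large-kernel Gaussian blur (129 x 129 after odd-adjustment, sigma 32,
reflective padding; implemented exactly as two banded-matrix products).
The wavelet-style enhancement correlates each pixel with a zero-mean,
unit-norm spot-matched kernel — a difference of Gaussians with
`sigma1 = psf_sigma` and `sigma2 = 2 sigma1` — and clips negative
responses, leaving an image that is zero away from foci. The original
tool defers its wavelet definition to supplementary material; the DoG is
the standard matched choice here and is configurable.

Detection is a four-step algorithm: (1) per-box maxima on an 8 x 8 grid,
thresholded at 5 robust noise units above background (on zero-clipped
enhanced images the noise scale comes from the half-normal median of the
positive excess, because the MAD collapses to zero); candidates are
re-centred on the intensity-weighted centroid of an 11 x 11 patch;
(2) a precomputed-Gaussian kernel screen discards aberrant bright
regions — measured on the simulator, spots at SNR 5 have normalized
residuals below ~0.55 while single hot pixels sit at ~1.1 and noise
maxima above ~1.4, so the default acceptance threshold is 0.8;
(3) an elliptical 2-D Gaussian with constant offset is fitted by
Levenberg–Marquardt; (4) fits are filtered on width (0.8–2.5 px),
eccentricity (max 1.8) and relative RMS residual (max 0.3), and
duplicates closer than 2 px merged keeping the lower residual. Tracking
mode relaxes the width window to 0.6–3.0 px and the fit residual by
1.5x (individual frames are noisier than projections); the kernel
screen is not relaxed so hot pixels stay rejected.

Coordinates are 1-based with pixel-centre convention (x = 1.0 is the
centre of the first column), matching R's indexing; simulators and
detectors round-trip exactly under this convention.

## Chromatic aberration and colocalization

The apparent shift of a spot between colour channels is modelled as a
radial linear transform about an origin:
`dx = F (x - xc) / Sx`, `dy = F (y - yc) / Sy`, with `F = 1` for
640 nm → 488 nm and `F = 0.35` for 640 nm → 561 nm, held fixed per
channel pair. `Sx`, `Sy` are the distances from the origin producing a
1-pixel shift. The transform is exactly linear in `F` and in the
distance from the origin, with the origin a fixed point.

The per-field auto-solver maximizes the number of colocalized spots by
grid search over origins (central half of the field, 8 px spacing — the
linear model is only trusted in the central 256 x 256 of a 512 x 512
detector) and scale factors (10 geometric steps over 300–3000 px),
because the pair count is a discontinuous function of the parameters.
Ties break on the smaller mean pair distance. A Nelder–Mead simplex then
minimizes the mean distance of the grid-stage pairs; the pairings are
frozen during refinement, precisely to keep the objective continuous.
Below 4 colocalized spots the solver reports failure rather than a
spurious fit. Pairing is greedy mutual-nearest-neighbour with a default
radius of 2 px (configurable; no canonical value exists).

## Trace extraction

Traces are computed from the raw, unenhanced stack: per frame, the sum
of a 5 x 5 window centred on the rounded spot position minus the window
area times a robust local background — the median of a 4–8 px annulus
excluding the FWHM disc, with pixels more than 3 MAD above the annulus
median trimmed first (robustness against neighbours). Local background
subtraction every frame guarantees that once every fluorophore has
bleached the trace mean is zero; a surviving fluorophore leaves the
final plateau above zero and the stoichiometry undecided. Window and
annulus sizes are configuration parameters; summation vs averaging of
the window differs only by a constant and summation is used.

## The step-count network

The classifier maps a 300-point trace to seven classes: 0–4 steps,
"5+", and "undefined" (incomplete bleaching). Architecture: three 1-D
convolution layers (16/32/80 filters, kernels 9/7/5, each followed by
max-pooling of 2/2/4, collapsing 300 samples to 18 time steps), a
128-unit LSTM (which can, e.g., ignore photo-blinking by pairing an
upward step with a matching downward one), 50% dropout (training only),
and a 384/128 perceptron with a 7-way softmax — 223,383 trainable
parameters. The layer shapes within the conv stack and perceptron were
fixed once to land within 2% of 220K parameters; pooling sizes carry no
parameters and were chosen by comparing validation accuracy of the
candidate configurations at a small fixed budget.

The training signal-to-noise distribution is a mixture: 70% of traces
draw their target aSNR uniformly from 1–10 (the regime where counting is
genuinely ambiguous) and 30% uniformly from 10–30 (bright, dye-like
traces such as those extracted from well-exposed movies). The coverage
matters: a classifier miscalibrates badly on signal-to-noise regimes
absent from its training set — an early log-uniform 1–10 distribution
over-counted clean traces by one step, both at the top of its range and,
worse, on pipeline-extracted movie traces whose aSNR sits near 20.

Inputs are normalized per trace by the 99th intensity percentile so the
initial plateau maps near 1 regardless of camera gain; the identical
normalization is applied at training and prediction time. Traces of
other lengths are linearly resampled to 300 points; interpolation
introduces points between plateaus, and accuracy on resampled traces is
lower than on native 300-frame traces at equal aSNR.

Training uses Adam and sparse categorical cross-entropy on
class-balanced simulated traces, with weights kept (and checkpointed)
only when validation accuracy improves. Three fluorophore presets exist
(Cy5 constant ±20%, mCherry and mEGFP cos²). The reference recipe is
learning rate 1e-4 with large streamed shards; the **fast preset** used
throughout the package's own evaluation is 5,000 traces per class
(35,000 total), 3 epochs, batch 512, learning rate 1e-3. That is about
three orders of magnitude less data than a full-scale training run, and
the headline accuracies in `scripts/acceptance.R` are expected to be
several points below a fully trained model, particularly in the extreme
signal-to-noise bins; the parameter count, monotone accuracy trend,
under-prediction structure at fast bleaching, and the downstream
binomial recovery are robust at this scale. The neural-network kernel
itself (im2col convolutions, LSTM backpropagation-through-time, Adam)
is implemented in vectorized R over BLAS and verified against
finite-difference gradients in the test suite.

## The step-position network

Given a step count `k` from the classifier, a separate convolutional
network emits one activation per time point (inputs and outputs both
length 300; 4 conv layers, kernel 9, linear 1-channel output). Training
traces have step times drawn uniformly over the trace — a rectangular
distribution avoiding temporal class imbalance — with multi-hot targets
(1 exactly at step frames) under the cosine-similarity loss, which
aligns the output direction with the target direction in 300-dimensional
space; a perfect output attains similarity 1. The widths are 16/32/32/16:
at full temporal resolution this stack already costs an order of
magnitude more compute per trace than the pooled classifier, and halving
a wider 32/64/64/32 variant's widths was the single change made to keep
training tractable on one CPU; depth, kernel size and resolution are
unchanged.

Step selection takes the top `2k` activation indices, collapses runs of
consecutive indices to the run's maximum (a wide peak would otherwise
crowd out a separate weaker peak and misplace a step), then keeps the
top `k` surviving peaks. "Consecutive" means adjacent indices; no gap
tolerance. Plateau means between the selected frames give the fitted
trace — exactly the least-squares piecewise-constant fit for those
breakpoints. A legacy moving-average change-point locator is retained
behind `moving_avg_steps()` for comparison.

## Tracking, MSD and diffusivity deconvolution

Framewise detections are linked by temporal nearest neighbours within a
maximum jump distance; a blinking molecule reconnects within a 1-frame
window (configurable); ambiguous assignments resolve greedily by
smallest distance so tracks stay topologically linear; short tracks are
discarded. The mean square displacement at lag `dn` averages squared
displacements over all frame pairs `(n, n + dn)`; pairs whose interval
contains a gap are skipped and the pair count adjusted.

The diffusion coefficient is the slope/4 of a linear regression of the
MSD against lag time, restricted to an adaptive prefix: regressions are
computed for growing prefixes from 3 points, and the fitted region ends
where the first backward difference of R² turns negative (beyond
floating-point jitter, 1e-12) — large lags average few pairs and deviate
from linearity. The standard deviation of the per-prefix `D` values, as
a percentage of the final `D` (sample sd), is the per-track quality
score; tracks above a threshold (4–5% for stringent work) are rejected,
which sharpens the diffusivity histogram of heterogeneous mixtures at
the cost of track count. The surviving `D` values are fitted with a
Gaussian mixture (EM via mclust, unequal variances; BIC selection over
1–6 components, or a fixed count for a planned design). The four-species
evaluation feeds ground-truth Brownian positions plus 0.2 px
localization jitter (the ~20 nm accuracy of a well-exposed spot)
directly to the linker; rendering and detecting four full movie stacks
would measure the same estimator at far greater cost, and image-based
detection and tracking are exercised end-to-end separately on small
rendered movies in the test suite.

## Stoichiometry inference and FRET

Under binomial labelling, the observed step-count histogram estimates
`(N, p)` by profile likelihood: for each candidate `N` (1–8) the
maximum-likelihood `p` is found, and the reported confidence is the
normalized profile likelihood over candidates — a declared definition,
since no standard one exists. Zero-label complexes emit nothing and are
invisible, so by default the 0-step bin is excluded and the binomial is
conditioned on at least one label; simulation ground truth can include
the 0 bin. The "5+" class is treated as a right tail.

When the histogram comes from the step classifier rather than from
ground truth, a face-value likelihood is brittle: a single over-counted
trace in a bin above the true `N` rules that `N` out entirely. The
remedy is to estimate the classifier's confusion matrix on synthetic
traces with known ground truth in the same signal-to-noise regime
(`classifier_confusion()`) and fold the binomial class probabilities
through it before comparison. This is ordinary response-matrix
unfolding; it uses no information from the data under analysis, and it
is how the full-pipeline evaluation recovers the planted site counts.

The FRET add-in computes per-frame efficiency `E = I_A / (I_A + I_D)`
from background-subtracted traces (non-positive totals masked), assigns
states with the same Gaussian mixture machinery (1 or 2 components by
BIC), absorbs dwells shorter than 4 frames into their neighbours, and
reports first-order exit rates from mean dwell times. Because observed
dwells are truncated at the 4-frame minimum, rates use the memoryless
correction `E[dwell | dwell >= m] = m - 1 + E[dwell]`; censored first
and last dwells are excluded. No gamma or crosstalk correction is
applied, and more than two states are out of scope.

## What the simulators do and do not emulate

The generators reproduce: constant-hazard bleaching including
first-frame events, dye-like and protein-like step-height statistics,
aSNR-controlled Gaussian trace noise, optional two-state blinking,
EMCCD-like movie noise (dark current, smooth autofluorescence,
gamma shot noise), binomial labelling, and Brownian motion. They do not
emulate: triplet or other multi-state photophysics, spectral crosstalk,
stage drift or focus wobble, CMOS-specific noise, anomalous diffusion,
or spatially varying PSFs. Green tests therefore certify the algorithms
under these stated conditions, not performance on any particular
microscope.

## Evaluation scale

All problem sizes in the tests and in `scripts/acceptance.R` are the
package's documented evaluation presets: 35K training traces for the
classifier and 8K for the position network; 100-trace-per-class test
bins; 250 tracks per species of 100 frames for the diffusivity study;
and three 700-complex, 300-frame, 384 x 384 stacks for the stoichiometry
pipeline. Larger presets (streamed shards of 240K traces, more epochs at
learning rate 1e-4) are exposed through `train_config()` for users with
the hardware to run them, and should be preferred for production models.
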