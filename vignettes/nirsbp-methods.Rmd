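---
title: "Methods: continuous blood-pressure estimation from NIRS-PPG waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous blood-pressure estimation from NIRS-PPG waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An arterial line gives continuous, accurate blood pressure but is invasive
and removed as soon as clinically possible, leaving only intermittent cuff
readings during a period of elevated hemodynamic risk.  A continuous-wave
near-infrared spectroscopy device worn on the forehead records, at large
(2--3 cm) source-detector separation and 266 Hz, a photoplethysmographic
pulse waveform (NIRS-PPG) whose morphology tracks arterial pressure.  This
package implements the full analysis chain that turns such a recording plus
a reference pressure series into a subject-specific, continuously evaluable
pressure estimator, together with a synthetic-data generator that provides
exact ground truth for every stage.

The estimator never uses the pulse *amplitude*, which depends on optode
coupling and local perfusion.  It uses three amplitude-independent features
of each (ensemble-averaged) beat:

* **P2/P1** — the ratio of the reflected to the forward systolic peak of the
  waveform's first time derivative.  Stronger wave reflection accompanies
  higher pressure.
* **HR** — heart rate, 60 / mean inter-beat interval.
* **P1-P2 slope** — the signed slope between the two derivative peaks,
  indexing the rate of transition between forward and reflected waves.

## Preprocessing

Stages, in order: ambient-light subtraction, artifact masking, wavelet
band-pass, conversion to delta optical density, interquartile normalization.

**Ambient subtraction.** The device samples ambient light once per cycle;
the corrected intensity is the elementwise difference.  Samples where the
difference is non-positive are flagged and absorbed into the artifact mask.

**Artifact masking.** Samples whose accelerometer-magnitude deviation or
ambient-light deviation (absolute distance from the series median) exceeds
the subject-specific 99th percentile are flagged; flagged runs are padded by
1 s and merged.  The percentile threshold is floored at 8 robust standard
deviations (MAD-based): a pure percentile rule would always flag 1% of an
artifact-free recording and, with padding, progressively mask clean data.
The floor preserves the monotone property that lowering the percentile can
only enlarge the mask.  Masked runs are bridged by linear interpolation
before filtering so artifact excursions do not ring into clean segments; the
padding absorbs the residual boundary effect.

**Band-pass.** The pulsatile band (nominally 0.5--15 Hz) is isolated with
Daubechies-5 wavelets in two complementary transforms.  A decimated
8-level decomposition with the level-8 approximation zeroed implements the
high-pass: at 266 Hz the approximation holds content below
$f_s/2^9 \approx 0.52$ Hz (respiration, Mayer waves, drift).  An
undecimated (maximal-overlap) decomposition whose level-3 smooth is retained
implements the low-pass with edge $f_s/2^4 \approx 16.6$ Hz.  These depths
are derived from the sampling rate: they are the unique choices whose dyadic
band edges fall nearest the nominal cutoffs.  Both transforms see a
reflect-padded copy of the signal (symmetric extension) and the result is
trimmed to the input length; the undecimated smooth is computed as the
scaling-filter pyramid followed by its adjoint, which is zero-phase by
construction.  Measured on 120-s sinusoids, the cascade passes 1--5 Hz at
more than 99% amplitude and attenuates 0.05 Hz and 40 Hz tones below 1%.

**Delta-OD and normalization.** The filtered intensity fluctuation is
re-referenced to the baseline $I_0$ (median of unmasked corrected
intensity; configurable) and converted as
$\Delta OD = \ln(I_0 / I(t))$, so absorption increases during systole give a
positive-going pulse.  Filtering before the logarithm keeps the log argument
positive; the alternative order (delta-OD first) is available via
`od_before_filter`.  The series is then centered at its median and scaled by
its interquartile range, computed over unmasked samples with linear
interpolation between order statistics.

## Pulse segmentation and quality control

Beat onsets are placed at local minima preceding systolic upstrokes:
upstroke regions are runs where the first derivative exceeds half its 98th
percentile; runs closer than the 0.3-s refractory period are merged; the
onset is the last non-positive-derivative sample before the run.  Pulses
are the half-open intervals between consecutive onsets.

Per-pulse duration and amplitude are computed after removing residual
baseline wander with a 15-s centered moving median.  Outliers are rejected
sequentially — duration outside the recording's [1st, 99th] percentiles,
amplitude outside [5th, 95th], then shape similarity outside [7th, 93rd] —
each filter applied to the survivors of the previous one, with inclusive
bounds (exact ties are never rejected).  The shape score of a pulse is the
Pearson correlation between its min-max-scaled, resampled waveform and the
pointwise mean of its 20-pulse neighborhood.  The two-sided shape filter
follows the stated percentile pair even though rejecting unusually *high*
similarity is counterintuitive; `shape_one_sided = TRUE` switches to
lower-tail-only rejection.  Note that percentile QC always rejects a fixed
fraction of beats (about 24% under the defaults) whether or not artifacts
are present; this is inherent to the rule, not a defect.

Retained pulses are averaged in overlapping windows of four (50% overlap,
so windows advance by two beats), each member resampled to a common length
before pointwise averaging.  Four-beat averaging gives a feature stream
with roughly 2-beat resolution while suppressing uncorrelated noise.  The
ensemble heart rate is 60 over the mean *member duration* rather than the
mean onset difference: the two agree for consecutive members, but the
former remains correct when quality control has removed a beat between
members.

## Four-Gaussian decomposition

The first derivative of each ensemble waveform is modeled as

$$f(x) = \sum_{i=1}^{4} A_i \exp\!\left(-\frac{(x-\mu_i)^2}{2\sigma_i^2}\right) + c,$$

fitted by bounded Levenberg-Marquardt least squares with an analytic
Jacobian.  The constant $c$ is not part of the classical four-Gaussian
pulse model but is structurally necessary: any mechanism that keeps blood
volume bounded across beats (diastolic outflow in vivo, the within-beat
linear detrend in the generator, or high-pass filtering) shifts the beat
derivative by a beat-wise constant, and without the offset term the fit
absorbs that shift into the components and biases the peak ratio by tens of
percent.  Fiducial values are read from the Gaussian components only, so
$c$ never enters the features.

Numerical choices: derivatives use a fourth-order central stencil;
components are initialized at the four most prominent local maxima, with
missing slots filled at the positions farthest from the peaks already found
(the dicrotic-region components often ride on the preceding component's
tail without a maximum of their own); a second deterministic start uses
generic morphology fractions (15/35/55/75% of the window); up to five
seeded restarts perturb the best start by 10% of the parameter range; the
final 5% of the window is excluded from the fit because the segment
boundary sits on the following beat's early upstroke; a fit is accepted
early once its residual is below 2% of the best single-Gaussian fit's, and
is flagged converged only if it does not exceed that single-component
residual.  Bounds: $|A_i| \le 2\max|f|$, $\mu_i$ inside the window,
$\sigma_i \in [2/f_s,\, \text{window}/2]$.

Pulses are resampled to 150 points for shape comparison, averaging and
fitting.  At 100 points the discretized derivative attenuates the narrow P1
component enough to bias the recovered ratio by up to 2%; at 150 points the
worst-case error on noiseless simulations is below 1.6%, with negligible
extra cost.

P1, P2 and DP are the components with the three smallest means, in order;
their values are the full model (components only) evaluated at the means,
which remains consistent when components overlap.  The dicrotic notch is
the interior local minimum of the model between the P2 and DP means, and is
reported absent when the model is monotone there.  P2/P1 and the P1-P2
slope follow directly; the slope is computed on the derivative signal by
default (`slope_on_derivative = FALSE` uses the integrated waveform).

## Calibration

Features are aligned to the reference pressure by nearest-neighbor pairing
within 2 s.  The training segment is the contiguous 1200-s window (scanned
at 60-s steps) maximizing the reference-pressure standard deviation —
emulating calibration on the most hemodynamically active period — with the
earliest window taken on ties; the test set is the remainder minus a 60-s
buffer on each side.

**Linear model.** Ordinary least squares of pressure on intercept, P2/P1
and HR.  Coefficient standard errors use the residual variance adjusted for
degrees of freedom ($n-3$) and the diagonal of $(X^TX)^{-1}$; p-values come
from the $t$ distribution with $n-3$ degrees of freedom.  By default the
linear model is fit on the same training segment as the nonlinear models
for a like-for-like comparison; `fit_linear_on = "all"` fits it on the
whole aligned series.

**Gaussian-process model.** An RBF kernel with one length scale per feature
(automatic relevance determination) plus independent noise; features are
z-scored with training statistics and the target centered.  Hyperparameters
maximize the log marginal likelihood (L-BFGS-B with analytic gradients)
from several starts: unit length scales, a long-length-scale (near-linear)
start, and seeded perturbations; the start whose optimum attains the lowest
mean 5-fold cross-validated RMSE on the training segment is kept.  Folds
are contiguous in time, which penalizes hyperparameters that only
interpolate.  Two guard rails matter in practice and are deliberate
modeling choices: the signal variance is capped near the observed target
variance, because on near-linear targets the RBF marginal likelihood is
maximized along a degenerate ridge (signal variance and length scales
growing together) whose finite iterates generalize poorly; and length
scales are floored at 0.3 standardized units, since pressure varies
smoothly with these features and shorter scales only ever fit noise.
Predictions report the posterior mean and the predictive standard deviation
including the noise term.  A known limitation is inherited from the method
itself: at feature values outside the training range the posterior mean
reverts toward the training mean, so a training segment that fails to span
the subject's operating range degrades the nonlinear models first.

**Evaluation.** $R^2 = 1 - SS_{res}/SS_{tot}$ on the held-out interval by
default (`r2_method = "correlation"` gives the squared-Pearson alternative;
reports name which was used), RMSE, MAE, and Bland-Altman bias with
$\pm 1.96$-SD limits (sample SD, $n-1$).  Paired model comparisons report
the textbook paired $t$ statistic with a Wilcoxon signed-rank companion;
all-zero differences are flagged degenerate, and zero-variance nonzero
shifts are reported as the infinite-$t$ limit.

## The synthetic generator

The generator exists so that every pipeline stage has an exact oracle.  Its
central design decision: the beat *velocity* is the four-Gaussian sum
itself, integrated in closed form to a waveform, so the decomposition model
is exactly realizable and recovery can be tested to machine precision.  The
amplitude of the second component is solved per beat so that the model
value ratio at the first two means equals the target P2/P1 exactly, with
morphology expressed in beat fractions (means at 12.5/31.25/56.25/75% of
the beat) and rescaled to each beat's length.  Within each beat the
integrated waveform is linearly detrended to its net excursion, keeping
simulated blood volume bounded; as discussed above this leaves the beat
derivative equal to the Gaussian sum minus a beat-wise constant, which the
extractor's offset term absorbs.

Optical conversion: $I(t) = I_0 e^{-(g\,w(t) + d(t))} + \text{ambient} +
\varepsilon$, so intensity falls during systole.  Defaults, chosen once as
plausible operating-room values and exposed in `simulation_spec()`:
baseline 20 000 counts, ambient 1000 counts, OD gain 0.15 (pulse excursion
about 1.5% of baseline), white optical noise 8 counts, respiration
(0.3 Hz) and Mayer-wave (0.1 Hz) OD drifts of 0.004 and 0.002,
accelerometer noise 0.02 g.  Heart rate and ratio trajectories default to
sinusoids (periods 400 s and 600 s, 75 ± 8 bpm and 0.65 ± 0.15) emulating
deliberate intraoperative pressure modulation; the periods are chosen so a
20-min calibration window observes the full joint feature range, which is
the regime the training-segment selection rule is designed for.  Reference
pressure is generated per beat from the linear mapping (default
coefficients: intercept −67 mmHg, 137.10 mmHg per unit ratio, 1.16 mmHg
per bpm), optionally perturbed by a smooth, curvature-dominant nonlinear
term for exercising the nonlinear models.  Artifact injection adds
accelerometer bursts, ambient steps and optical corruption inside scheduled
intervals only.

A companion generator, `simulate_feature_dataset()`, draws the feature
triple directly (skipping waveform synthesis) with a slope component
partially independent of ratio and HR, and a nonlinear pressure term that
depends partly on that independent component.  It is the workhorse for
calibration-model tests: the 3-feature model can in principle explain the
slope-dependent part, the 2-feature models cannot, and a plane cannot
absorb the curvature-dominant part.

What the generator does **not** emulate: arrhythmia and ectopic beats,
baseline wander correlated with blood pressure, probe-coupling drift,
pressure-waveform-derived (rather than beat-wise) references, pulse-shape
changes beyond the P2/P1 parameterization, and any nonstationarity of the
feature-pressure relationship.  Tests passing on this generator therefore
demonstrate correctness of the algorithms under the stated signal model,
not clinical performance on patients.

## Problem sizes and runtime choices

The test suite exercises the end-to-end path at desk scale: a 90-minute
simulated recording (about 1.4 million samples, 6700 beats) for the
held-out accuracy check, a 60-minute noise-free recording for full-path
coefficient recovery, 100 random parameter draws for decomposition
recovery, and ten seeded repetitions of the three-model comparison on
1500-sample feature streams.  These sizes were chosen so the whole suite
completes in a few minutes while every stage still operates well above its
minimum data requirements.

## Known limitations

* The Gaussian decomposition assumes a single dominant upstroke per beat;
  severe arrhythmia or double-peaked systole would need template logic the
  package does not provide.
* Percentile quality control always rejects its fixed tails; on pristine
  recordings this discards clean beats.
* GPR extrapolation beyond the training feature range reverts to the mean;
  the maximum-variability training window mitigates but does not eliminate
  this.
* Calibrations are strictly subject-specific; nothing in the package
  supports transferring a model across subjects.
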