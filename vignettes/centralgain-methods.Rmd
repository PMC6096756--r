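---
title: "Methods: models, estimators and design choices in centralgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in centralgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centralgain)
```

`centralgain` implements the measurement chain of a noise-exposure auditory
study — brainstem evoked potentials, operant detection psychophysics,
startle reactivity, immunolabel densitometry, tonotopic mapping and
stereology — together with synthetic generators that produce every input
modality with known ground truth. This vignette documents the models, the
parameters that matter, the numerical conventions, and the limits of what
passing tests demonstrate.

## ABR model and analysis

**Generator.** A synthetic epoch at level $L$ (dB SPL) is
$$x(t) = \sum_{k=1}^{4} a_k(L)\, w\!\left(\frac{t - \tau_k(L)}{\sigma_k}\right) + \varepsilon(t),$$
where $w(u) = -(u-1)\,e^{(1-(u-1)^2)/2}$ is a biphasic
(derivative-of-Gaussian) wavelet with unit positive peak at $u = 0$ and
unit trough at $u = 2$, $a_k(L) = \max(0, s_k (L - \theta))$ is a linear
amplitude growth above threshold $\theta$ (so the peak-to-trough amplitude
is $2a_k$), $\tau_k(L)$ decreases linearly with level, and $\varepsilon$
is white Gaussian noise. Real ABR waves are neither symmetric nor
independent across generators; the wavelet model captures only the
morphology that the measurement chain relies on (single positive peak,
following trough, level-dependent latency).

Key defaults, all in `defaultABRTruth()`:

* wavelet width $\sigma_k$ = 0.2 ms. At the 1-ms inter-peak spacing this
  keeps cross-talk between adjacent wavelets' extrema below 0.3 %; at
  0.25 ms the contamination alone would reach the few-percent level and
  confound amplitude accuracy checks.
* latency $\tau_k(L) = \{2.3, 3.3, 4.3, 5.3\}\ \mathrm{ms} - 0.01\,L$,
  matching the usual ~1.5–4.5 ms peak positions at 80 dB SPL.
* amplitude slopes (µV/dB): sham $\{0.100, 0.075, 0.055, 0.065\}$, noise
  $\{0.045, 0.051, 0.036, 0.053\}$. Because ratios of linear growths are
  level-independent, these fix the central-gain signature analytically:
  sham p2:p1 = 0.75 versus noise 1.13, sham p4:p1 = 0.65 versus 1.18.
  Peak 1 is attenuated most, later peaks partially spared — the hallmark
  of increased central gain after peripheral damage.
* single-epoch noise SD = 3 µV. This is a clean-prep figure chosen so
  that with 300-sweep averaging (averaged noise ≈ 0.17 µV) the 2-SD
  baseline criterion resolves thresholds at the 5-dB presentation step.
  With substantially noisier epochs the criterion overestimates threshold
  by two or more steps — mostly because the fixed 2-ms response-window
  start clips peak 1 near threshold, where its latency approaches 2 ms.
* sampling 9.5 kHz, 2 ms pre- and 30 ms post-onset (the baseline window
  at 20–28 ms must fit in the record). The generator refuses sampling
  rates below twice the wavelet bandwidth ($\approx 3/2\pi\sigma$).

**Analysis.** `averageEpochs()` applies a 4th-order Butterworth 300–3000 Hz
band-pass forward and backward (zero phase) and averages. Since the filter
is linear, it is applied once to the pointwise mean — identical to
filtering every epoch first, and much faster. `detectPeaks()` takes, per
peak, the largest local maximum in its latency window (defaults p1
0.8–2.2, p2 1.8–3.2, p3 2.8–4.4, p4 3.8–5.8 ms); because these windows
overlap, successive peaks are additionally constrained to advance in time.
Amplitude is the maximum minus the deepest trough before the next detected
maximum (a 1.2-ms tail after peak 4); a window without a local maximum
yields a missing peak, not an error. `determineThreshold()` pools baseline
(20–28 ms) window amplitudes across all levels of a stimulus, sets the
criterion at their mean + 2 SD, and returns the lowest level at which the
response-window (2–10 ms) amplitude is *strictly* above the criterion with
every higher level also above; strictness matters only in the degenerate
zero-variance case, where a response identical to baseline must not count.
"Not reached" is an explicit status, never a sentinel number. Amplitude
ratios are formed from the averaged waveform (not per sweep), and level
functions are fitted by ordinary least squares on log10 amplitude (raw
latency).

## Lick-suppression psychophysics

**Generator.** Each trial carries 35 pre- and 35 post-stimulus 20-ms bins
of Bernoulli lick indicators at a baseline rate (default 0.9/bin). On a
warning trial at level $L$ the animal suppresses with probability
$$p(L) = \mathrm{FA} + (H_{\max} - \mathrm{FA})\,\Phi\!\left(\frac{L - \theta}{s}\right),$$
and a suppressed trial has zero post-stimulus lick probability. Defaults:
$s$ = 4 dB, $H_{\max}$ = 0.95, FA floor 0.16. The per-trial binary gate
(rather than a graded rate reduction) is the reading consistent with
count-based hit scoring; a graded multiplicative reduction would make
subthreshold "hits" almost certain, since the criterion is set on the
undiminished safe-trial rate.

**Analysis.** `selectCriterion()` enumerates all integer criteria 0–35 on
the safe-trial post counts and picks the one whose response rate is
closest to 16 %; ties between distinct rates resolve toward the lower
(conservative) rate, and within a plateau of equal rates the largest
criterion is returned (this matters only in degenerate sessions, which are
flagged). `dprime()` uses the standard $1/2N$ correction for rates of 0 or
1. `thresholdAtDprime()` interpolates linearly in d′-versus-dB between the
highest level below target and the next level; it refuses to extrapolate
(all-below → "not reached", all-at-or-above → lowest level flagged as
ceiling). `aggregateThresholds()` finds the latest run of ≥3 consecutive
sessions spanning <5 dB and averages the last 3–4 of them; consecutiveness
is required, which is the stricter reading of an ambiguous protocol.
False-alarm rates are computed per session, not pooled. The analytic
ground-truth threshold (`clsAnalyticThreshold()`) combines the binomial
safe-count distribution with the suppression model in closed form; with a
16 % false-alarm floor the d′ = 1 hit rate is ≈50 %, so the analytic
threshold sits slightly below the psychometric midpoint.

## Startle

Relative startle amplitude is RMS of the 100-ms response trace divided by
RMS of the final 1 s of the 5-s baseline trace. This normalization is a
package convention — reactivity measures are often reported in arbitrary
units, and the ratio form makes the quantity dimensionless and invariant
to sensor gain (a property the tests assert). The quiet gate returns the
first time at which a trailing 5-s window has RMS below the stillness
threshold (default recommendation: twice the sensor noise floor). The
generator scales deterministic or Gaussian carriers to exact target RMS,
so with zero trial-to-trial noise the measured ratio equals the specified
mean exactly.

## Immunolabel densitometry

**Leveling.** Every section is multiplied by one scalar gain so that all
ROI means equal a common target
$$T = \min\Bigl(\max_i m_i,\ \min_i 255\,m_i / x_i\Bigr),$$
with $m_i$ the ROI mean and $x_i$ the ROI maximum: never clip any ROI
pixel, and never brighten beyond the best-exposed section's native mean
(avoiding needless amplification of noise and quantization). Images stay
on the 8-bit grid (rounded), which preserves weak rank order and equalizes
means to well within 0.5 gray level.

**Thresholding.** The pooled 256-bin ROI histogram feeds two classical
auto-thresholders implemented from their geometric/information-theoretic
definitions: the *triangle* method (perpendicular distance from the
histogram to the peak-to-tail line, searching the longer-tail side) and
the *Rényi entropy* method (Sahoo–Wilkins–Yeager: exhaustive maximization
of background + foreground Rényi entropy at orders ½, 1 and 2, combined
with the published spread-dependent β-weights). Both are verified against
brute-force oracles on every tested histogram; ties resolve to the first
maximizing bin. Label density is the fraction of ROI pixels at or above
the threshold (bright-label convention; an `invert` flag serves dark
chromogenic material, and reports state the polarity). A threshold of 256
is an explicit sentinel meaning "nothing labeled".

**Phantom.** Sections are cut from a tapered, bent ellipsoid (~1.0 × 0.8 ×
0.5 mm, 50-µm sections, 4-µm pixels) carrying a log-frequency field along
one axis; puncta (8-µm discs, +160 gray over a 40 ± 8 background) are
placed by an inhomogeneous Poisson process with intensity $d(f)$ per µm²
(sham default 2.5 × 10⁻⁴, noise-condition default one half of that), and
each section receives a multiplicative illumination factor drawn from
U(0.75, 1.05) for the leveling stage to undo. What the phantom does *not*
emulate: stain deconvolution artifacts, spatially correlated background,
out-of-focus light, and section damage — so passing recovery tests shows
the estimator chain is correct, not that real material is this benign.

## Tonotopic mapping

Outlines of each section's ROI are lifted to $z = k \times 50$ µm to form
a point-cloud surface; first and last sections are marked open so
registration ignores artificial end rings. The template is the same shape
with a voxelized (20 µm) log2-frequency field; field lookup is trilinear,
and pixels leaving the valid mask are flagged unassigned and excluded from
both numerator and denominator of any density (clamping would inflate edge
bins).

A pure ellipsoid cannot serve as the registration target: the affine maps
that carry an ellipsoid onto itself form a continuum (conjugates of the
rotation group, plus reflections), so an affine surface fit is
under-determined and the frequency axis can be silently rotated. The
phantom therefore tapers the x semi-axis along z and y and bends the x
centre quadratically along z (defaults 0.22/0.18/0.15; `taper = c(0,0,0)`
recovers the ellipsoid where the symmetric shape is wanted).

`fitAffine()` is an iterative-closest-point loop with the closed-form
least-squares affine update, initialized by principal-axes alignment; the
four proper-rotation sign assignments of the PCA frame are screened with
short ICP runs and the best is refined. Stopping: RMS improvement below
0.1 µm (configurable) for 5 consecutive iterations, or 100 iterations.
RMS is reported against nearest template-surface points. On noiseless
phantoms self-registration recovers a known affine to machine precision;
with 10 sections of outline data the fitted map keeps ≥95 % of ROI pixels
within ⅛ octave of their true frequency. With many fewer sections the fit
degrades gracefully (the RMS stays low but the in-plane rotation is less
constrained) — section count is the main determinant of mapping accuracy.

Quarter-octave bins place 11 centres symmetric in log2 about
$\sqrt{f_{\min} f_{\max}}$; for 6–32 kHz they round to 5.8, 6.9, 8.2, 9.8,
11.7, 13.9, 16.5, 19.6, 23.3, 27.7, 33.0 kHz. Edges sit at centre ×
$2^{\pm 1/8}$, half-open upward; empty bins report `NA` density, never 0.

## Stereology and cochleogram

The optical fractionator estimate is
$\hat N = \sum Q^- \cdot \frac{1}{ssf} \cdot \frac{1}{asf} \cdot \frac{1}{hsf}$.
The area sampling fraction defaults to 1 (counting frame = grid cell),
because the emulated counting protocol tallies every neuron inside the
grid; the height fraction defaults to 1 as no optical dissector height is
modeled. The generator places cells uniformly, samples every
$1/ssf$-th section from a random start and counts inside a random-phase
counting frame, so each cell is counted with probability
$ssf \cdot asf \cdot hsf$ — the estimator is exactly unbiased, which the
tests confirm to within 2 % over 150–200 replicates. Guard zones and
forbidden-line rules are not implemented. Percent loss is
$100(1 - \bar N_{test}/\bar N_{ref})$; synapses per inner hair cell and
hair-cell survival are straight ratios with explicit flags for undefined
(no IHC) and >100 % cases.

## Group statistics

The package deliberately exposes a simplified, fully specified contract
instead of reproducing mixed-model machinery: per-cell Welch two-sample
contrasts (noise vs sham, group-specific variances) with Holm correction
across the requested family, Cohen's d with $n-1$-weighted pooled SD, and
partial η² = SS_effect/(SS_effect+SS_error). Null simulations at unequal
variances keep the empirical type-I error within Monte-Carlo error of the
nominal 5 %. Users needing full mixed models should fit them with `nlme`
or `lme4` on the tidy tables this package emits.

## Orchestration and reproducibility

`runExperiment()` runs all seven stages over a sham and a noise cohort
from one configuration, derives every per-subject seed deterministically
from the master seed, writes tidy CSVs and a JSON manifest with MD5
checksums, and marks a failing stage in the manifest while the rest
proceed. Reruns with the same configuration are bit-identical. The default
configuration builds in the compensation signature: behavioral threshold
shifts (≈4.5–20 dB across 8–16 kHz) smaller than the corresponding ABR
shifts, so the ABR-minus-behavior discrepancy is positive at every
frequency.

## Problem sizes

Test and acceptance runs use desk-scale sizes chosen to keep Monte-Carlo
error comfortably inside the asserted tolerances: 300-epoch ABR averages
with 25-seed threshold-recovery replicates; 50 warning trials per level
and 3 sessions per behavioral subject; 10-section phantoms with 4–8
stacks per arm for densitometry recovery (the density-reduction estimate
then fluctuates by ±2–3 percentage points across seeds); 150–200
replicates for fractionator unbiasedness. The acceptance script uses 6
stacks per arm and 5 subjects per arm.

## Known limitations

* The ABR wavelet model has no refractory or cross-generator interactions
  and white (not 1/f or mains-contaminated) noise; electrode-artifact
  rejection is out of scope.
* Peak detection assumes the four peaks stay within their canonical
  latency windows; severe latency pathology would need window overrides.
* The lick model is per-bin Bernoulli, not a temporal point process with
  refractoriness; reaction-time analyses are out of scope.
* Registration is affine only; nonlinear deformation between subjects is
  not modeled, matching the template-fitting protocol it emulates.
* The frequency template is a synthetic stand-in with a monotone
  log-frequency field; it reproduces the geometry of the analysis, not
  any published anatomical frequency model.
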