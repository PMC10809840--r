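---
title: "Quantifying seizure waveform morphology in neonatal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seizure waveform morphology in neonatal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neowave)
```

## The problem and the three markers

Bedside monitors for neonatal seizures lean almost entirely on amplitude
trends. Amplitude captures *how strong* an oscillation is, but not *what
shape* it has -- and seizure discharges differ from background activity in
shape: their extrema sharpen, and the oscillation's instantaneous
frequency wobbles within each cycle as the discharge destabilizes toward
termination. `neowave` computes three complementary per-epoch markers from
the Hilbert analytic signal $z(t) = x(t) + i\,\mathcal{H}[x](t)$ of each
bipolar EEG channel:

* **Complex envelope.** The median of $|z(t)|$ over a nonoverlapping 1-s
  epoch; per-period summaries average these medians. The median (not the
  mean) suppresses the transient spikes the Hilbert envelope develops at
  epoch edges. Although the literature often calls this quantity
  "envelope power", it is an amplitude: nothing is squared.

* **Epileptic sharpness.** Local extrema are detected with an
  order-statistic filter: a Tukey window (default 0.25 s, taper 0.5)
  slides with a one-sample shift; at each position the *track* is the
  maximum of the window-weighted samples, and samples that meet their own
  track are detected peaks. Because the criterion compares each sample
  against tapered neighbours, it adapts to the local amplitude scale:
  `detect_extrema(c*x)` equals `detect_extrema(x)` for any `c > 0`, and
  the input is median-centered first so constant offsets are irrelevant.
  For each extremum the absolute voltage differences to the signal 7 ms
  before and after are averaged,
  $s_i = (|x_{\mathrm{peak}} - x_{\mathrm{peak}-7\,\mathrm{ms}}| +
  |x_{\mathrm{peak}} - x_{\mathrm{peak}+7\,\mathrm{ms}}|)/2$, and the
  segment's sharpness is the median of $s_i$. On z-scored input the value
  is in z-units per 7 ms.

* **Degree of nonlinearity (DoN).** With $\theta(t)$ the unwrapped
  Hilbert phase, the instantaneous frequency is
  $\mathrm{IF}(t) = \theta'(t)/2\pi$ (central differences), and the
  zero-crossing frequency of a segment is
  $\mathrm{IF}_z = \#\{\text{zero crossings}\}/(2T)$. Then
  $\mathrm{DoN} = \mathrm{sd}\!\left[(\mathrm{IF} -
  \mathrm{IF}_z)/\mathrm{IF}_z\right]$: the depth of *intrawave*
  frequency modulation relative to the *interwave* rate. A pure sinusoid
  gives about 0; the canonical modulated tone
  $\cos(\omega t + \varepsilon \sin \omega t)$ has
  $\mathrm{IF} = f_0(1 + \varepsilon\cos\omega t)$ and hence
  $\mathrm{DoN} = \varepsilon/\sqrt{2}$, the closed form used as the
  estimator's oracle. DoN is invariant to amplitude scaling, which
  matters below.

Two conventional comparators are included: five Hamming-window band
powers per 1-s epoch (delta 1--4, theta 4--9, alpha 9--13, beta 13--30,
gamma >30 Hz), the energy ratio
$\mathrm{ER} = (\beta + \gamma)/(\theta + \alpha)$, and the RMS.

## Preprocessing

The chain is fixed: out-of-range correction, 50-Hz notch, 1-Hz
high-pass, per-channel z-scoring, PCA denoising.

* Samples with $|x| > 200\,\mu V$ are replaced by monotone
  (shape-preserving) piecewise-cubic interpolation over valid neighbours;
  runs touching a record edge take the nearest valid value; channels more
  than half out of range are flagged unusable.
* The notch is a second-order IIR biquad. Its quality factor is a free
  parameter; the default Q = 25 (a 2-Hz-wide -3 dB notch at 50 Hz) is
  narrow enough to spare gamma-band content.
* The high-pass is a sixth-order Butterworth with 1-Hz cutoff
  (single-pass magnitude $1/\sqrt{2}$ at the cutoff).
* **All filters run forward-backward (zero phase).** Sharpness and DoN
  are waveform-shape measures; causal filtering would skew every peak it
  passes. The cost is a squared magnitude response -- the quoted orders
  are single-pass conventions, and the doubled attenuation is accepted.
* z-scoring uses the population (1/N) standard deviation, stated so that
  closed-form tests are exact. Zero-variance channels become zeros and
  are flagged.
* PCA keeps the smallest leading set of components reaching 95% of
  cumulative eigenvalue mass and *back-projects* to channel space, so
  per-contact features stay defined. Back-projection is an
  interpretation: reduced components do not map to 18 contacts by
  themselves, and downstream results are reported per contact, so the
  projection-reconstruction reading is implemented (a strict
  component-space analysis would change the meaning of "contact").
  Single-channel recordings skip PCA with a provenance note.

## Annotations, fusion, segments

Seizure annotations are per-second binary masks, one per rater (three
raters). Fusion level $k$ marks a second as seizure when at least $k$
raters agree; by construction fused masks are nested in $k$. Maximal
runs of fused seconds form events; each event at least 3 s long is split
into three equal-length stages S1/S2/S3 with boundaries at
$\mathrm{round}(n/3)$ and $\mathrm{round}(2n/3)$ seconds -- second
resolution, because that is the resolution of the annotations;
sample-exact thirds would fake precision the labels lack. Epochs
straddling a boundary take the label covering more than half the epoch.
Events shorter than 3 s stay in the seizure period but are excluded from
stage analysis. Nonseizure is all non-annotated time; no guard band is
inserted by default.

## Group statistics

Epoch values are aggregated to one observation per subject and factor
cell (mean of epochs) before testing -- epoch-level testing would inflate
the degrees of freedom. Responses are Box-Cox transformed (maximum
likelihood $\lambda$ on a grid, log branch at $\lambda = 0$, automatic
shift for nonpositive values).

The repeated-measures ANOVA treats subject as a random factor. For
balanced tables the implementation is the classical strata form
(`aov` with `Error(subject/...)`): each within-subject effect is tested
against its own subject-by-effect stratum, which for a two-level factor
is exactly the paired $t$ test. This choice is deliberate and has teeth:
per-recording z-scoring couples the seizure and nonseizure means of a
recording (if one is high the other must be low, since the total
variance is pinned at 1), producing *negative* within-subject
correlation. A mixed model with a non-negative random intercept
truncates that correlation at zero and becomes anticonservative -- in
null simulations its period-effect type-I error reached ~0.16 at
$\alpha = 0.05$, while the strata form sits at ~0.03. The
subject-random-intercept mixed model (`lmerTest`, Satterthwaite) remains
as the fallback for unbalanced tables and is flagged in the result.
Tukey-adjusted pairwise comparisons (via `emmeans`) accompany each main
factor. Topography tables report
$100 \cdot (F_{\text{seizure}} - F_{\text{nonseizure}}) /
F_{\text{nonseizure}}$ per contact.

## Classification

Three schemes mirror the clinical questions: seizure vs nonseizure, S1
vs nonseizure (onset), S3 vs S1 (termination). The observation unit is
the per-subject median of a feature over the epochs of a class, on a
single contact (default C4-P4); per-subject medians are used because
epoch-level observations from the same subject are not exchangeable.
Evaluation is a seeded stratified 80/20 split; SVM (RBF; cost and gamma)
and kNN ($k \in \{3,5,7\}$) hyperparameters come from 5-fold
cross-validation on the training 80%; metrics, the ROC and a
quantile-binned calibration curve are computed on the held-out 20%.
Metrics are reported on the held-out set, not pooled CV folds. The
ROC/AUC orientation is fixed (higher score = positive class), so
relabelling maps AUC to $1 - \mathrm{AUC}$ rather than silently
re-orienting.

## The synthetic generator: what it emulates and what it does not

`generate_recording()` produces multichannel recordings with the
structure the pipeline assumes: 256 Hz, 18 longitudinal bipolar
channels, per-second triple-rater masks, and seizure events whose thirds
carry an elevated delta envelope (gains 2, 3, 1.6 -- middle stage
highest), sharpened extrema (half-wave power warp
$\mathrm{sign}(u)|u|^{1+2s}$, $s = 0.3$; this transform sharpens peaks
while leaving zero crossings and extremum timing untouched, keeping the
sharpness and nonlinearity knobs as independent as the mathematics
allows), and a rising intrawave modulation depth
$\varepsilon = (0.1, 0.25, 0.6)$ toward termination. A per-recording
log-normal amplitude factor (sd 0.2) models inter-individual
variability; without it, fixed stage gains would make per-subject
medians of any amplitude feature a perfect classifier for every
contrast, which no real cohort shows. Rater masks are the ground truth
corrupted by per-rater boundary jitter (sd 1 s) and a 5% per-event miss
probability -- the simplest model that makes the fusion levels diverge.

Two design points deserve emphasis because measurement forced them:

* **The background is a drifting rhythm, not plain 1/f noise.** The
  instantaneous frequency of Gaussian noise is heavy-tailed, so the
  per-epoch DoN of any band-limited Gaussian background is ~1 or more --
  far above anything a seizure oscillation can reach
  ($\varepsilon/\sqrt{2} < 0.71$). A pure-noise background would
  therefore *invert* the seizure > nonseizure DoN ordering the pipeline
  is meant to detect. The default background is instead a slowly
  amplitude- and frequency-modulated delta rhythm (3 Hz, 15% frequency
  drift, 30% amplitude drift) with a small 1/f admixture
  (`noise_mix = 0.02`), giving a background DoN near 0.12. This is an
  idealization: real neonatal background (tracé alternant, burst
  suppression, artifacts) is far richer, and passing tests on this
  generator says nothing about detection performance on clinical data.
* **The 1-Hz high-pass eats part of the modulation effect.** Intrawave
  modulation at the carrier rate places its first lower Bessel sideband
  exactly at DC, so the high-pass removes a share of the
  $\varepsilon$ effect that grows with $\varepsilon$ (for
  $\varepsilon = 0.4$ the measured DoN drops from 0.42 to 0.32 after
  zero-phase filtering). The default $\varepsilon$ ladder is chosen wide
  enough that the post-filter stage contrast survives.

Within seizures the background is attenuated to 20% of its amplitude --
seizure discharges dominate the trace -- and events ramp on and off over
0.5 s.

## Numerical choices

* 7 ms at 256 Hz is 1.79 samples; flank values are linearly interpolated
  at exactly $\pm 7$ ms (config `flank_mode = "nearest"` reverts to the
  nearest sample). This keeps the sharpness definition
  sampling-rate-independent.
* Extremum detection uses both polarities by default (the negated signal
  supplies minima), window length 0.25 s so at least one delta cycle
  fits per window; detections within half a window of the record edge
  are discarded.
* The IF is a central difference of the unwrapped phase; the first and
  last 0.1 s of each segment are excluded from the DoN standard
  deviation to suppress Hilbert edge effects. Negative IF samples
  (phase slips) are retained -- they are part of the phenomenon -- but a
  segment with more than 20% negative IF carries a quality flag.
* DoN and sharpness default to the same 1-s grid as the envelope;
  stage-level segments can be analysed by slicing the recording, and the
  per-segment functions accept arbitrary lengths.
* The per-segment zero-crossing frequency is a scalar, reading the
  definition's "referenced to the zero-crossing frequency" as a
  segment-level (interwave) reference; a per-sample reference track
  would conflate the two modulation scales.
* EDF export scales each channel to the full signed 16-bit range, so the
  round trip is exact to one quantization step.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen for a laptop-class
run: 20-subject cohorts of 120-s three-channel recordings for the
pattern and classification checks, 500 six-subject background-only
datasets for the type-I calibration of the period test, and ten
20-subject datasets at envelope gain 3 for its power. The defaults above
are the generator's study conditions; tests scale the *problem size*
(channels, durations, subject counts), never the generative parameters.

## Known limitations

* The generator's background is deliberately narrowband; broadband or
  artifact-laden backgrounds will raise the background DoN and compress
  the seizure contrast.
* The order-statistic extremum detector does not report maxima whose
  peak value is negative (they are handled through the minima pass on
  the negated signal); signals riding a large negative offset should be
  centered first, which `detect_extrema` does by median subtraction.
* With per-subject observations, held-out test sets are small (4 + 4 at
  20 subjects), so held-out AUCs are coarse (multiples of 1/16).
* `read_edf` handles plain EDF with a common sampling rate across
  signals; EDF+ annotation channels are ignored, not parsed.
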