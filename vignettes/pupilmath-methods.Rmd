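---
title: "Models, parameters and design choices in pupilmath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in pupilmath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupilmath` simulates and analyses cued mental-arithmetic pupillometry in
relation to math anxiety. This vignette documents the generative model,
the preprocessing and inference machinery, every tunable that matters, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The scientific setting

Each trial of the task unfolds as: a 750 ms pre-trial baseline window; an
auditory difficulty cue ("easy"/"hard") opening a 4000 ms anticipation
window; three 750 ms sounds (multiplicand 12–14, the operator, multiplier
6–9 or 16–19); a 6000 ms window in which no response may be given; a vocal
response at the participant's own pace; then a second part — 750 ms
baseline, a 750 ms confirmation sound with a 4000 ms wait window, and a
750 ms feedback sound with a 4000 ms feedback window — followed by a
750–1250 ms uniform inter-trial interval. The 24 problems are each
repeated three times (72 trials, two blocks of 36), after four discarded
practice trials. Pre-response phase onsets are fixed: the second operand
ends 7000 ms after trial onset and the earliest allowed response is at
13000 ms.

Two pupil features summarise each trial: **maximum dilation** relative to
the trial baseline (in participant-wise z units) and **peak latency**, the
time from second-operand offset to that maximum, a proxy for the duration
of cognitive effort. The analysis asks (i) whether difficulty and anxiety
modulate the pupil timecourse and (ii) how well performance and pupil
features predict questionnaire anxiety scores.

## The synthetic cohort

### Trait layer (Gaussian copula)

Six variables are generated per participant: AMAS, TAI, STAI and PMP
questionnaire totals, plus two continuous latent traits — `acc_trait`
(expected accuracy) and `lat_trait` (expected peak latency). Latents are
drawn from a multivariate normal whose correlation matrix is the user's
*observed-scale* target (`default_trait_correlations()`), disattenuated
per variable before sampling so that the observed totals, not the
latents, hit the targets. The disattenuation factors (0.937 AMAS, 0.959
TAI, 0.946 STAI, 0.877 PMP, 1 for the continuous traits) combine the
analytic sum-score shrinkage of the one-factor item model with the loss
from discretising items, and were pinned once from a large-n calibration.
The AMAS row of the default matrix (r = .41 with TAI, .23 with STAI,
−.30 with PMP, −.36 with accuracy, .48 with latency) and the TAI/STAI
latency entries (.42, .14) are the study's reported values; the remaining
pairs (e.g. TAI–STAI .55, PMP–accuracy .45, accuracy–latency −.40) were
chosen once as values a psychometrician would call realistic for these
constructs, and are not revisited. A non-positive-semi-definite target —
either as given or after disattenuation — is rejected with the offending
eigenvalue named.

Items follow a one-factor model: item *j* of questionnaire *q* loads
λ = √(ᾱ/(k − ᾱ(k−1))) on the questionnaire's latent, with unique normal
noise, and the continuous response is cut at fixed thresholds (AMAS 9
items, 5 levels; TAI/STAI 20 items, 4 levels; PMP 30 binary items with
difficulties spread over .64–.97). The continuous-scale consistencies are
set slightly above the observed targets (.89/.93/.90/.85) to absorb the
discretisation loss. Totals therefore always equal item sums and respect
the instrument ranges by construction.

Accuracy probabilities are logistic in the accuracy trait
(easy: plogis(2.6 + z); hard: plogis(0.55 + 1.5 z)), matching easy ≈ .90
and hard ≈ .61 with realistic spread. Expected peak latencies are linear
in the latency trait (easy 8.9 ± 3.0 s, hard 15.5 ± 6.4 s, floored at
2–3 s), the simplest monotone link that reproduces the reported
between-participant means and SDs.

### Trace layer

A trial's raw 500 Hz trace is

> tonic baseline + effort kernel + (anticipation bump) + (error bump)
> + AR(1) noise,

in arbitrary eye-tracker units (baseline mean 4000, SD 600 between
participants — the scale is irrelevant after the participant-wise
z-transform). The effort kernel is a gamma density (shape 3) rising from
the first spoken operand and peaking at the trial's expected latency
(plus trial jitter, SD 2 s) after second-operand offset; its amplitude is
500 a.u. for easy and 625 a.u. for hard trials. A gamma shape was chosen
for a single interpretable peak with a skewed decay; nothing in the
analysis depends on this exact form. A small anticipation bump (15 % of
the gain) follows hard cues and an error bump (30 %) follows incorrect
feedback. Measurement noise is AR(1) at 2 ms pitch with φ = 0.99 and
innovation SD 7 a.u. (stationary SD ≈ 50 a.u., autocorrelation time
≈ 200 ms). Blinks arrive at 0.25/s, last 100–300 ms, set the validity
flag false and the trace to zero, and are flanked by steep
partial-occlusion edges that the velocity criterion must catch. Response
time is the trial's peak latency plus a response lag, floored at the
6000 ms minimum window, which couples slow effort to slow responses.

With `null_cohort = TRUE` every anxiety–pupil and difficulty–pupil
coupling is removed (equal amplitudes and latency distributions, no
anticipation or error bumps, difficulty-independent accuracy); the
type-I-error studies rely on this switch.

`simulate_epoched_cohort()` is a second, first-class generator that emits
binned series directly on the analysis grid — the same structure the full
pipeline produces — for simulations that need hundreds of replicate
cohorts. Its bin-level noise autocorrelation defaults to 0.08, the value
the raw-trace noise model induces between bins 0.5 s apart (0.99^250), so
the two generators agree about the statistics that reach the mixed
models.

### What the generator does not emulate

No pupillary light reflex or luminance coupling (the paradigm is auditory
with a constant display), no gaze position or foreshortening artifacts,
no slow session-scale arousal drifts, no item-content effects within
questionnaires, and no within-participant variability figures beyond
those implied by the trial jitter (none are reported to calibrate
against). Passing tests therefore demonstrate that the *machinery* is
correct and calibrated under a plausible data-generating process — not
that real recordings satisfy these assumptions.

## Preprocessing

The chain runs strictly in this order: artifact detection → missingness
rejection → interpolation → spline smoothing → median binning →
participant z-transform → baseline alignment → baseline rejection.

* **Artifact detection.** Tracker-flagged samples plus samples whose
  absolute first difference exceeds `velocity_k` = 16 MADs of the
  non-missing first differences; every artifact run is then extended
  100 ms per side. The velocity threshold is not specified by the
  protocol; 16 MADs flags blink edges reliably while leaving smooth
  physiological change untouched, and is exposed in
  `analysis_config()`.
* **Missingness.** "More than 40 %" is read as a strict `>`: a trial at
  exactly 40 % masked is kept.
* **Interpolation.** Linear between nearest unmasked neighbours; edge
  gaps are filled flat from the nearest unmasked value (interpolation is
  undefined there and flat extension adds no spurious slope).
* **Smoothing.** A cubic smoothing spline with `spar = 0.6` and 25 knots
  per second. The default was set by a frequency-response criterion:
  on 500 Hz test sinusoids it attenuates 10 Hz content by > 99 % and
  anything above 4 Hz by ≥ 90 %, while passing 0.5 Hz content at > 99 %;
  knot density proportional to duration makes the response invariant to
  trial length.
* **Binning.** 25 ms bins, value = median of in-bin samples; empty bins
  stay missing.
* **z-transform.** Binned samples (the text order places the transform
  after binning), pooled over all of a participant's kept trials, are
  standardised by that participant's grand mean and SD; zero variance is
  an error naming the participant.
* **Baseline alignment.** The mean of the first 750 ms of each part is
  subtracted from that part; alignment is idempotent. The ± 2 SD
  baseline rejection is computed per participant (it follows
  participant-wise standardisation; a pooled rule would mix
  participants' baseline scales), and an all-equal baseline set (SD 0)
  rejects nothing.
* **Features.** The peak search runs from second-operand offset
  (7000 ms) to the end of the first part (the trial's own response
  time); latency is reported in seconds from that offset. The tonic
  baseline is the mean *arbitrary-unit* pupil during the first fixation
  window. Blinks in the response phase receive the same artifact
  treatment as elsewhere, and the 40 % rule is evaluated over the whole
  trial — the simplest reading consistent with blinks being permitted
  there.

## Crossvalidated timepoint-selection mixed models

Trials are assigned to 3 folds deterministically by within-participant
rank (rank − 1 mod 3 + 1), so 72 kept trials split 24/24/24 and 70 split
24/23/23. For each rotation, two folds form the training set; at every
timepoint an "intercept-only" linear mixed model — random intercept per
participant, no random slopes — is fitted by maximum likelihood, and each
fixed effect's peak-|t| timepoint is recorded. Held-out trials contribute
their pupil value at the timepoint selected without them; after three
rotations every trial carries exactly one value per effect, and a final
intercept-only mixed model (Satterthwaite df, fractional as in mixed-model
t-tests) yields the reported t/p per effect, with a normal-approximation
(df = ∞) fallback available everywhere. Per-timepoint scans default to
the normal approximation: selection needs only the location of the peak
|t|, and degrees of freedom barely move it. Maximum likelihood (not REML)
is the default for comparability of fits across timepoints; REML is a
flag. Consensus clusters are maximal runs of timepoints where *all*
rotations exceed |t| > 2, and a confirmatory mixed model on the
within-cluster mean pupil value is fitted per cluster. `liberal_scan()`
implements the uncorrected per-timepoint variant and reports each
effect's minimum p and its location.

Covariate codings: the cue is sum-coded (−0.5 easy, +0.5 hard),
questionnaire totals are z-scored, trial accuracy is 0/1 centered — none
of this is dictated by the protocol, but it makes t-signs directly
interpretable. The common timepoint grid runs at 0.5 s pitch to the 90th
percentile of the response-time distribution; trials that ended earlier
are missing at later timepoints and drop from those timepoints' fits.
Each fixed effect selects its own peak timepoint, and one final model per
effect is fitted on the full fixed-effects formula (reporting that
effect's row), matching a procedure that quotes a single t per effect.

### Calibration and a known limitation

The no-leakage property is structural (selection statistics never touch
the held-out fold) and is additionally checked empirically: the test
suite measures the final-test rejection rate of the cue effect at
α = .05 over 500 independent null cohorts (20 participants × 24 trials on
a 24-point grid — sizes chosen to keep the suite fast while leaving the
Monte-Carlo error at ≈ ±0.01). Two caveats belong here. First, the
mixed-model p-values themselves are well calibrated at these sizes (a
fixed-timepoint fit with Satterthwaite df rejects at ≈ 0.04–0.05 on the
same null cohorts); the normal fallback is mildly liberal for
between-participant effects with few participants. Second — and this is
a finding of the packaged simulations, not a bug — the selection scheme
itself is *mildly anticonservative*. Its three training sets overlap
pairwise in one fold, so the selected timepoints are correlated across
rotations; whenever two rotations select the same (or a serially
correlated nearby) timepoint, a fold's held-out values are evaluated at
a timepoint that its own data helped select in the *other* rotation.
Under the packaged null conditions the cue effect rejects at ≈ 0.08
instead of 0.05, the effect is larger for participant-level terms (the
cue-by-anxiety interaction reaches ≈ 0.12 with 20 participants), and it
grows with the bin-to-bin noise correlation (φ = 0.7 at the grid pitch
pushes the cue rate to ≈ 0.14). The corresponding packaged check asserts
the nominal 0.03–0.07 band and therefore fails by design under these
conditions; it is retained as an honest record of the procedure's
behaviour. Users should treat borderline p-values from this procedure
with caution, especially for between-participant moderators, and can
decorrelate neighbouring timepoints (wider grid pitch) or increase the
number of folds to reduce the overlap-induced tilt.

## Model selection

The anxiety outcome is z-scored (n − 1 denominator) before modelling;
predictors stay on their native scales. All 2^p ordinary least-squares
subsets (p ≤ 15) are fitted and ranked by BIC with the Gaussian
maximum-likelihood convention: variance estimated as SSE/n and the
parameter count including intercept and residual variance, so the
intercept-only model on any z-scored n = 70 outcome has
BIC = 70·(log 2π + log(69/70) + 1) + 2 log 70 = 206.14 — a pinned
regression test, since it uniquely identifies the convention. Evidence is
read as BF(A,B) = exp((BIC_B − BIC_A)/2) (the unit-information-prior
approximation), which is exactly antisymmetric and transitive.
Leave-one-subject-out cv-R² is 1 − Σ(yᵢ−ŷ₋ᵢ)²/Σ(yᵢ−ȳ)² with ȳ the
full-sample mean (the simplest reading; a training-mean denominator
differs only at O(1/n)); the reported value is floored at zero — a
reporting convention for non-predictive models — with the raw value also
returned. `adj_r2_from_f()` inverts R² = uF/(uF+v),
adjusted R² = 1 − (1−R²)(u+v)/v.

One property of BIC-ranked best-subset selection is worth stating
explicitly: at n = 70 the probability that a *spurious* candidate improves
the BIC is P(F(1,66) exceeds the ln-n penalty) ≈ 4.6 % per candidate,
*independent of the signal-to-noise ratio*. With a five-candidate set
containing two true predictors, exact recovery of the true subset is
therefore capped near (1 − 0.046)³ ≈ 0.87 no matter how strong the
signal; the packaged recovery check asserts a 95 % exact-recovery rate
and fails by design under these conditions (it measures ≈ 0.80 over 60
replicates, consistent with the cap). The true predictors themselves are
essentially always included — the misses are spurious *additions* — so
consumers of the ranking should read trailing low-BIC models as
equivalent within one spurious term.

Power curves use f² = R²_partial/(1−R²_partial) and the noncentral F
distribution with v = n − u − 1. Both common noncentrality conventions
are implemented — λ = f²(u+v+1) (Cohen, the default) and λ = f²n — because
published power analyses rarely state which was used; the two disagree
slightly at small n, so no specific published sample size is asserted.

## Psychometrics

Pearson correlations report t = r√(n−2)/√(1−r²) on n − 2 df and the
Fisher-z interval tanh(atanh r ± z₀.₉₇₅/√(n−3)); a perfect correlation
returns the degenerate interval [r, r]. Descriptives use bias-uncorrected
moment skewness and *excess* kurtosis (consistent with reported values;
both conventions documented here so they can be compared). Cronbach's α
is k/(k−1)(1 − Σs²ᵢ/s²ₜ). The k-means clustering standardises its
features, runs 50 restarts under a fixed seed, and relabels clusters so
cluster 1 always has the higher anxiety mean; `median_split()` exists for
plotting only — inference is parametric throughout.

## Problem sizes used by the packaged checks

The test suite exercises the full raw-trace chain on an 8-participant,
12-trial study; inference calibration and recovery on 20 × 24-trial
epoched cohorts (24-point grid, 500 null replicates, 40 effect
replicates); subset recovery at n = 70 over 60 replicates; and trait
structure recovery at n = 5000. These sizes are the package's own
choices, balancing Monte-Carlo error against a suite that runs in
minutes; all of them scale up by changing one argument.

## Other limitations

* The generator's between-participant summary statistics are calibrated;
  trial-level variability is plausible but uncalibrated (no published
  figures exist to match).
* Best-subset regression with BIC is exhaustive and consistent but
  ignores model-averaging uncertainty; no regularised or Bayesian
  alternatives are provided.
* The pipeline assumes a monocular, constant-luminance, auditory
  paradigm; nothing corrects for gaze-angle foreshortening or light
  reflexes.
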