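---
title: "From foot markers to gait asymmetry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From foot markers to gait asymmetry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsym)
```

## The problem

Community studies of walking in older adults commonly record only two
reflective markers per foot — heel and toe — at around 100 Hz on a straight
walkway, and pair the gait recording with a short mental-health screen such
as the 12-item General Health Questionnaire (GHQ-12). From those four
marker trajectories the analysis must deliver, per participant, the classic
spatiotemporal parameters and their left-right symmetry:

* **step length** — anterior heel-to-heel displacement at heel contact (m);
* **step width** — absolute mediolateral heel-to-heel displacement at the
  same instant (m);
* **double support time** — heel contact to contralateral toe off (s);
* **minimum foot clearance (MFC)** — the lowest toe height above the
  walking surface during mid-swing (cm), the variable most directly tied
  to tripping risk: at that instant the foot skims the floor at 1–2 cm
  while moving at its peak forward velocity.

Each parameter is summarized per foot as a mean and an intra-subject SD
(sample SD across step cycles, the standard measure of movement
consistency), and left-right differences are expressed with the Symmetry
Index

$$SI = \frac{|R - L|}{(R + L)/2} \times 100\ (\%),$$

applied to both the mean and the SD of each parameter — 16 features per
subject. The cohort stage correlates each feature with the GHQ-12 total
and fits an ordinary least-squares regression of the GHQ-12 total on the
full feature set.

`gaitsym` implements this pipeline end to end, and — because raw cohort
recordings of this kind are rarely shareable — ships a synthetic gait
generator with exact ground truth so that every stage is testable.

## Signal model and preprocessing

Marker positions live in a lab frame with x anterior, y to the
participant's left, z up, floor near z = 0; passes walked in −x are
rotated 180° on load. Occlusion gaps up to 10 consecutive frames (100 ms
at 100 Hz) are filled by linear interpolation; longer gaps reject the
trial, since interpolated kinematics over longer spans can no longer be
trusted for event timing.

All coordinates are smoothed with a zero-phase low-pass Butterworth
filter, cutoff 6 Hz — the conventional choice for foot marker data, which
preserves gait harmonics (fundamental ≈ 1 Hz) while suppressing
marker-tracking noise. The stated order 4 is realized as an order-2 design
applied forward and backward; this has exactly zero phase lag (event
timing is not shifted) and a magnitude response of
$1/(1 + (f/6\,\mathrm{Hz})^4)$, so the gain is 0.9992 at 1 Hz, exactly 0.5
at the cutoff, and 1.6e-3 at 30 Hz. No cutoff correction is applied for
the dual pass: 6 Hz is treated as the design cutoff, and the half-power
point at 6 Hz is part of the documented contract. Before filtering, the
series is extended by reflection over six filter time constants
(6·fs/cutoff samples) and trimmed afterwards; shorter paddings leave IIR
startup transients above 1e-9 even on a constant input, which would
violate the DC contract on short walkway passes. Derivatives are central
differences on the filtered signal, one-sided at the ends.

## Event detection

With only heel and toe markers (no force plates), events come from the
vertical kinematics:

* **Heel contact** — a local minimum of filtered heel height whose mean
  vertical velocity over the preceding 50 ms is below −0.03 m/s (the final
  descent) and whose height is within 15 mm of the trial's 5th-percentile
  heel height (near the floor). A 0.4 s refractory interval — equivalent
  to a cadence ceiling of 150 steps/min, above any plausible preferred
  pace in this population — prunes duplicates, keeping the lowest.
  A strictly negative velocity test is not usable in practice: on flat
  stance plateaus the filtered velocity ripples around zero at the 1e-6
  m/s level, and under 1–2 mm marker noise sign-only gating admits false
  contacts; the −0.03 m/s margin is far below the ≈ −0.1 m/s of a real
  final descent. All thresholds are exposed in `pipeline_config()`.
* **Toe off** — within each heel-contact-to-heel-contact cycle, the last
  upward zero crossing (≤0 to >0) of filtered toe vertical velocity before
  the toe first rises 5 mm above its stance height. The search begins
  after the toe has settled from the previous landing, so the landing
  transient cannot satisfy the rise criterion.

The first and last partial cycles of a pass are discarded (gait initiation
and termination are not steady state). Steps are then assembled from
strictly alternating heel contacts; a violation of alternation (a missed
detection) drops the affected step with a warning rather than silently
patching the sequence.

MFC is extracted per swing as the lowest local minimum of filtered toe
height within 20–80% of the swing — "mid-swing" is qualitative in the
literature, and this window excludes the toe-off and landing transients
while comfortably containing the clearance minimum, which the generator
places at 45–65% of swing. The ground reference is, by default, the
per-foot median toe height over mid-stance (a foot-flat proxy that removes
the shoe/marker offset); `ground_ref = "absolute"` uses z directly and is
appropriate for synthetic data whose floor is exactly z = 0 (for such
data the two references agree, since the synthetic toe rests at z = 0 in
stance).

## The synthetic generator

`simulate_trial()` builds marker trajectories as piecewise
quintic-smoothstep curves (the minimum-jerk ramp, C² with zero velocity
and acceleration at every knot) through physiologic control points, so
knots are the only interior extrema and every event time, landing
position and clearance value is known exactly. Per stride:

* heel height descends into a symmetric dip reaching 0 exactly at heel
  contact (local symmetry keeps the filtered minimum at the true frame);
* toe height is flat in stance, dips 4 mm → 0 into toe off and rises 4 mm
  on fixed ±60 ms offsets (local antisymmetry of the velocity about toe
  off keeps the detected zero crossing unbiased across swing durations),
  then traces the classic two-peak swing profile: early peak (5 cm),
  mid-swing clearance plateau at 45–65% of swing, late peak (10 cm);
* anterior position holds in stance and advances by the programmed step
  length during swing, with the final 4 mm spread over the last 100 ms —
  a soft landing, so the filter ringing excited by the main advance has
  decayed at the contact instant where step length is read;
* mediolateral landing positions place each foot the programmed step
  width lateral to the trailing foot.

**Clearance is programmed as an observable.** Published MFC values are
read off low-pass-filtered trajectories, so the generator calibrates the
depth of the clearance plateau (three fixed-point iterations) such that
the minimum of the 6 Hz zero-phase-filtered toe height equals the
programmed value. A raw-minimum convention would leave an irreducible
1–3 mm filter-rounding bias for any realistic two-peak swing curve at
100 Hz; programming the observable is what makes 0.5 mm-level recovery a
well-posed contract. If a user analyzes with a different cutoff, the
recovered clearance shifts accordingly — exactly as it would for real
recordings.

Default study conditions: step length 0.657 m, step width 0.121 m, double
support 0.099 s, MFC 1.667 cm, with stride-to-stride SDs 0.036 m, 0.030 m,
0.019 s and 0.447 cm; cadence 110 steps/min (consistent with 0.657 m steps
at a typical ~1.2 m/s preferred pace); 30 strides per trial (≈58 usable
steps, satisfying the ≥30-step-cycles inclusion rule); 100 Hz sampling;
1 mm RMS marker noise for cohort data (typical of calibrated optical
capture). The clearance SD default treats a printed "447 cm" in the
source material for these conditions as the evident typo for 0.447 cm.

### The latent-coupling cohort model

`simulate_cohort()` draws a latent mental-health burden score
$m_i \sim N(0,1)$ per subject. Each parameter's relative left-right
asymmetry is $|a_p + \beta_p m_i + \varepsilon|$ (a random sign decides
which side is larger), applied separately to per-side means and to
per-side stride-to-stride SDs; baselines default to the asymmetry
magnitudes typical of healthy older walkers (5.9–25.7% for means, 32–37%
for SDs). GHQ-12 items are independent Bernoulli draws with agree
probability $\mathrm{logit}^{-1}(-2.536 + 1.444\,m_i)$; those two
constants were moment-matched so simulated totals have mean ≈ 1.56 and
SD ≈ 2.08 — a predominantly healthy cohort with an overdispersed tail,
and a latent-to-total correlation of ≈ 0.76.

The default couplings $\beta_p$ (0.045/0.065/0.055/0.07 for means,
0.20 for SDs) are calibrated per parameter against the analytic
finite-sample noise of each feature: estimating a side mean from ~29
steps leaves 1.5 (step length) to 7 (MFC) SI points of sampling noise,
and estimating a side SD leaves ~19 points, so parameters with noisier
features need stronger latent coupling for the cohort to operate in the
moderate-to-strong regime (feature–GHQ r ≈ 0.4–0.55) that the pipeline
is designed to resolve. Setting every $\beta$ to zero gives a null cohort
for type-I-error calibration.

Two modeling limits worth knowing: the folded asymmetry $|a + \beta m|$
is monotone in $\beta$ only below the baseline fold point (couplings are
kept well under it; the monotonicity test uses a grid capped at 0.06),
and for a perfectly periodic zero-jitter walker the double-support SI is
quantization-limited at 100 Hz (phase-locked ±1-frame rounding of a
~0.1 s interval), which is why the symmetric-subject test tolerates a few
SI points on that parameter only.

All randomness flows from one base seed through per-subject streams
(subject index → stream), so cohorts reproduce bit for bit and any
subject can be regenerated in isolation.

### What the generator does and does not emulate

It emulates: marker-level trajectories with realistic shapes, event
spacing, stride-to-stride variability, tunable asymmetry, occlusion-free
optical noise, and a latent trait coupling gait asymmetry to
questionnaire responses. It does not emulate: soft-tissue artifact,
non-stationary noise, turning or gait initiation dynamics, foot-angle
kinematics (heel and toe are generated as rigid offsets), correlated GHQ
item structure, or mean-level couplings between the latent score and
step width / clearance levels (only asymmetry is coupled). Passing tests
therefore demonstrate correctness of the pipeline's logic and its
statistical calibration under this model — not field performance on
arbitrary real recordings.

## Cohort statistics

Pearson correlations use the classical t-based two-sided p-value on
n − 2 df. No multiple-testing correction is applied across the 16
feature tests by default — matching common practice in exploratory gait
studies — with Benjamini–Hochberg available via `adjust = "BH"`. The
regression is OLS with intercept; the default predictor set is the 16
gait features plus age, 17 predictors, so a 126-subject cohort reports
the F(17, 108) structure. Rank-deficient designs fail loudly with the
offending columns named. Group contrasts (e.g. sex differences in
clearance variability) use Welch's unequal-variance t test.

Subjects are excluded listwise, with reasons recorded in the manifest:
trial-level failures (too few events, over-long gaps) at extraction, and
the <30-steps inclusion rule at analysis.

## Numerical choices, sizes and runtime

Tests validate, among other things: analytic filter gains at 1/6/30 Hz;
event recovery within ±1 frame on clean trials and ±2 frames at 1 mm RMS
noise over 20 seeds; recovery of programmed step length and width within
5 mm, double support within 10 ms, and MFC within 0.5 mm; a programmed
1.0/2.0 cm clearance asymmetry recovered within 2 points of SI = 66.7%;
type-I rate of the correlation stage inside the binomial 95% band around
0.05 over 20 null cohorts of 126 subjects; and all eight SI features
significant at p < 0.001 in ≥95% of 20 coupled cohorts. The cohort sizes
(126 subjects, 30 strides) mirror the study conditions; one cohort
simulates and analyzes in a few seconds on a laptop-class core, and the
full suite runs in minutes.

Ties in the clearance search resolve to the lowest minimum (earliest
frame on exact ties); degenerate inputs (constant markers, zero-variance
features, empty sides) raise classed conditions
(`gaitsym_*_error`) rather than propagating NaN.

## Known limitations

* Event detection is validated against the generator's trajectory family;
  pathological gait (shuffling, foot drop, crossover stepping) may violate
  the heel-minimum and toe-rise assumptions and would need re-tuned
  thresholds (all are config-exposed).
* The GHQ item model ignores item polarity handling upstream of coding
  (responses are assumed already encoded with 0/1 as the healthy pole)
  and item heterogeneity.
* Walking speed is deliberately not computed (it is not part of the
  16-feature set this pipeline targets).
* The predictor set reproducing the F(17, 108) structure includes age as
  the 17th predictor; the choice is config-overridable.
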