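---
title: "Quantifying motor dysfunction from tablet tracking: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor dysfunction from tablet tracking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mestrack)
library(dplyr)
```

## The problem

Clinician rating scales for movement disorders (such as the motor
examination of the MDS-UPDRS) summarize a patient's state at the
granularity of an office visit. A continuous tracking task measures motor
function at a far finer timescale: a target moves smoothly across a tablet
screen, the subject follows it with a stylus, and target position, cursor
position, and stylus force are sampled at 100 Hz. `mestrack` implements
the full analysis chain for such a task: target-path generation, per-epoch
kinematic metrics, and a per-subject severity score — the Motor Error
Score (MES) — derived from a linear support vector machine, together with
the downstream evaluation analyses (correlation with clinical ratings,
ROC/AUC discrimination, metric-weight profiles, within-subject state
contrasts).

Because patient recordings are not freely available, the package also
ships a first-class synthetic-subject simulator. It defines the study
conditions under which all of the package's tests and reproduction
scripts run, and it makes every stage testable end to end.

## Target paths

Each trial's target path chains 20 cubic Bezier curves,
$B(t) = (1-t)^3 P_0 + 3(1-t)^2 t\,P_1 + 3(1-t)t^2 P_2 + t^3 P_3$,
into one continuous curve. Control points are placed sequentially: each
lies on a circle centred on the previous point, with radius drawn
uniformly from 2.0–2.4 cm and a turning angle drawn uniformly from
60–75°, signed by a turn direction that is random except near a screen
edge, where the path is forced to curve toward the interior. Consecutive
curves share their junction point exactly (C0), and the first control
point of each curve continues the previous curve's exit direction (G1) —
this collinearity is what prevents kinks at the joins.

Decisions the task description leaves open, fixed here as configurable
defaults:

* **Screen.** 19.7 × 14.7 cm (a stylus-tablet class display, landscape),
  coordinates in `[0, W] × [0, H]`.
* **Edge margin.** 2.5 cm: inside this band the turn direction is forced
  interior-ward. The margin exceeds the maximum control-point radius, so
  a segment can always be placed.
* **Curvature meaning.** The 60–75° draw is the polar angle step, relative
  to the running direction, at which the next control point is placed on
  its circle.
* **Feasibility.** A candidate segment is rejected (and redrawn, up to
  100 times) unless all its control points lie on screen *and* its exit
  pose admits a maximal-turn follow-up segment — a one-segment lookahead
  that prevents the chain from wedging itself into a corner. In the rare
  case a chain still wedges, the whole path restarts with a fresh
  heading (at most 20 restarts, deterministically under the seed).

The target is animated at 4.25 cm/s and sampled at 100 Hz. Constant speed
is achieved by arc-length reparameterization: the path is evaluated on a
dense grid (1,000 points per segment), cumulative chord length is
computed, and sample positions are linearly interpolated at arc-length
steps of `speed / sampling_rate`. On generated paths the coefficient of
variation of inter-sample speed is below 1%, the invariant the sampling
must meet; any method achieving it would be acceptable.

A session is 15 trials of about 25 s. A single 20-segment path spans
roughly 110–130 cm of arc (about 26–30 s at 4.25 cm/s), so one path per
trial is generated and truncated to the trial duration; trials are
independent.

## Synthetic subjects

The simulator is a stand-in for human subjects, not a biophysical model.
Each trial, the cursor follows a first-order pursuit rule: it moves
toward the (lag-shifted) target with per-step gain, and — when the
profile models slowing — its per-step displacement is capped at
`speed_scale` times the target's step. On top of the pursuit state the
simulator adds a sinusoidal tremor $A \sin(2\pi f t + \phi)$ along a
random fixed direction (phase and direction drawn once per trial), plus
isotropic Gaussian positional noise; stylus force is a constant mean plus
Gaussian fluctuation.

Default profiles (chosen to produce the qualitative group structure the
analyses should detect — a tremor-dominant group, a heterogeneous group,
and clean controls):

| parameter | control | pd | et |
|---|---|---|---|
| tremor amplitude (cm) | 0 | 0.1 @ 5 Hz | 0.35 @ 6 Hz |
| tracking lag (s) | 0 | 0.12 | 0 |
| pursuit gain | 1 | 0.85 | 1 |
| noise SD (cm) | 0.02 | 0.08 | 0.02 |
| speed scale | 1 | 0.8 | 1 |
| force variance | 0.01 | 0.04 | 0.01 |

A scalar `severity` interpolates every pathological component between the
control baseline (severity 0) and the nominal profile (severity 1), and
extrapolates beyond; it is the simulator's single disease-burden dial and
the basis of the parameter-recovery checks (epoch-mean MES must increase
strictly along a severity grid).

Deliberate simplifications: tremor is a single sinusoid per trial (so the
envelope metric has an analytic expected value; a band-limited-noise
tremor is available via `tremor_model = "bandnoise"`), the pursuit cap is
exact rather than noisy, and no medication cycles, fatigue, learning, or
non-dominant-hand effects are modelled. Passing tests therefore show the
*pipeline* behaves correctly under controlled input — not that the
synthetic profiles match real patients. One consequence worth noting:
simulated controls are much cleaner than human controls, so standardized
effect sizes (and hence MES magnitudes and accuracies) are larger than
the corresponding clinical values; orderings and chance levels, not
magnitudes, are the reproducible content.

## The eight metrics

Traces are cut into 1-second non-overlapping epochs (100 samples;
trailing partial seconds dropped; epochs never span trials). Within each
epoch, eight metrics are computed. All non-tremor metrics use a 3 Hz
low-pass filtered cursor, so tremor cannot confound them; the tremor
metric uses a 3–10 Hz band-pass. Displacement "bin vectors" $C_i$
(cursor) and $T_i$ (target) are successive-sample differences of the
filtered traces, with $\Delta t = 0.01$ s.

* **distance** — mean of $\sqrt{(x_C - x_T)^2 + (y_C - y_T)^2}$ (cm).
* **tremor** — mean of $\sqrt{\tilde x_C^2 + \tilde y_C^2}$ where
  $\tilde\cdot$ is the analytic-signal envelope of the band-passed
  coordinate (cm). For a pure in-band sinusoid this equals the tremor
  amplitude.
* **vector_error** — mean $|C_i - T_i|$ (cm).
* **tracking_angle** — mean $\cos^{-1}\!\big(C_i \cdot T_i / (|C_i||T_i|)\big)$
  (rad); defined as 0 when either bin vector vanishes, which avoids NaN
  bursts during hesitations.
* **slowness** — mean $\exp(b\,|C_i|/\Delta t)$ with $b = -0.042$ and
  speed expressed in **mm/s**. The unit is a decision: with mm/s the
  transform is responsive around the task's typical speeds (target speed
  42.5 mm/s gives $e^{-1.79} \approx 0.17$). Changing the unit rescales
  $b$; `calibrate_slowness_b()` offers a data-driven alternative anchored
  at the empirical 80th-percentile speed.
* **speed_difference** — mean cursor-minus-target speed (cm/s).
* **excursion_difference** — mean distance of the low-pass cursor
  position from the screen origin (cm). The magnitude-of-displacement
  reading ($|C_i|$) duplicates speed information, so the positional
  reading is the default; `excursion_mode = "displacement"` implements
  the other. This metric is deliberately origin-referenced and therefore
  *not* translation-invariant.
* **pressure** — population variance of stylus force within the epoch.

Filters are 4th-order Butterworth applied forward and backward
(zero-phase), designed per trial and never run across trial boundaries.
Two numerical points matter. First, forward-backward filtering needs
padding: traces carry a large positional offset, and unpadded filtering
rings multi-centimetre transients off the edges. The implementation uses
odd-reflection padding (3 s at each end), after which a linear trend
passes through the low-pass essentially exactly. Second, zero-phase
filtering squares the magnitude response, so in-band attenuation near the
band edges is doubled: a 6 Hz tremor envelope is recovered to well within
5%, but 3.5 or 9.5 Hz components are attenuated by roughly 8–30%. Tests
assert tight recovery only on the band interior.

Per-epoch aggregation is the arithmetic mean for every per-sample or
per-bin series; pressure uses the population variance. Both are
conventions fixed here, as the task description names the epoch but not
the aggregator.

## The MES classifier

For a patient (or group) versus the pooled control epochs, the classifier
follows a Monte Carlo protocol that neutralizes class imbalance: on each
of 100 iterations the control pool is subsampled without replacement to
exactly the patient epoch count (1:1), the balanced set is split 80/20
with stratification, a linear SVM (cost C = 1, hyperparameters fixed in
advance, no per-subject tuning) is fit on the 80%, and validation
accuracy is recorded on the held-out 20%. The final hyperplane averages
the per-iteration coefficient vectors and intercepts. MES are computed,
by default, from a separate plane fit once on *all* epochs — using every
epoch for scoring — while the averaged plane underlies the reported
metric weights.

Given hyperplane coefficients $h_{1:n}$ and intercept $h_0$, the score of
an epoch's metric vector $m$ is the signed Euclidean distance

$$\mathrm{MES}(m) = \frac{h_{1:n} \cdot m + h_0}{|h_{1:n}|},$$

oriented so patient epochs score positive, and the relative contribution
of metric $i$ is

$$w_i = \frac{h_i^2}{\sum_j h_j^2},$$

nonnegative and summing to one.

Design choices where the protocol was genuinely open:

* **Standardization.** Metrics are z-scored with pooled-control mean/SD
  before fitting — linear-SVM coefficient magnitudes (hence the weights)
  are meaningless without a declared scaling. The scaling is stored
  inside the fitted object so `mes()` is self-contained.
* **Subsampling rule.** The general rule is "subsample controls to the
  patient epoch count"; a literal numeric divisor of the control pool is
  available as an override for designs where the pool-to-patient ratio is
  known and fixed.
* **Split semantics.** "80% training with cross-validation" is
  interpreted as a stratified 80/20 outer split with accuracy reported on
  the 20%; an inner CV adds nothing for fixed hyperparameters.
* **Averaging.** Coefficients are averaged raw (no per-iteration
  renormalization); a unit-norm averaging mode is available and flagged,
  since raw averaging can be scale-dominated.
* **Orientation.** If the averaged plane scores patient epochs lower on
  average, the plane is negated. The sign convention is asserted, so the
  mechanism must be explicit.

The shuffled-label control re-runs the identical pipeline after
permuting class labels. Labels are permuted at the subject level when
subject identities are present, at the epoch level otherwise. For
chance-level *guarantees* the epoch-level permutation is the sharper
instrument: subject-level shuffles in small cohorts occasionally land the
patient label on the one truly affected subject, which leaves a legitimate
heavy tail in the null. The two-state (e.g. stimulation On/Off) classifier
runs the same protocol within one subject and reports a pooled chance level
over several independent permutations, because a single permutation's
accuracy retains that permutation's sampling noise.

## Evaluation analyses

* **Percentile scan.** For each percentile 1–100, each subject's session
  MES is summarized at that percentile (linear interpolation between
  order statistics — the `type = 7` convention, fixed and documented) and
  Spearman-correlated with a clinical rating across subjects. The argmax
  percentile shows which part of the severity distribution the ratings
  track.
* **ROC/AUC.** The empirical ROC is integrated by the trapezoid rule;
  with ties the curve steps diagonally, which makes the integral equal the
  Mann-Whitney $U/(n_1 n_2)$ identity — a property the tests verify to
  1e-10. Pairwise patient-control AUCs fit a dedicated classifier per
  pair; pooled ROCs attach a label-resampling p-value with the
  $(k+1)/(B+1)$ estimator, which cannot return zero at finite $B$.
* **Phenotype rule.** The ratio of mean tremor item scores to mean
  postural-instability/gait-difficulty item scores classifies phenotype:
  above 1.5 tremor-dominant, below 1 PIGD, between (inclusive) mixed. A
  zero denominator with nonzero tremor is tremor-dominant by convention;
  which clinical items enter each mean is data (a configurable item map),
  not code.
* **Weight profiles.** Per-subject metric weights in long format with
  group means, the input to group-comparison statistics (the external
  mixed-model machinery itself is out of scope).

## Problem sizes

The package's own verification runs use, as their standard conditions,
sessions of 15 trials × 25 s (≈ 360–375 epochs per subject) for the
chance-level, exclusion, and weight-profile analyses — on a cohort of 20
controls and 5 subjects per patient group — and 9-trial sessions for the
within-subject two-state contrast. Unit tests use smaller sessions where
only the closed-form behaviour of a single component is at stake. Those
sizes are this package's choices; larger cohorts only sharpen the same
comparisons.

## Known limitations

* The simulator's clean controls inflate standardized separations; MES
  magnitudes are not comparable to clinical values.
* Band-edge tremor frequencies (near 3 or 10 Hz) are under-estimated by
  the zero-phase band-pass, as discussed above.
* The pursuit model keeps a slowed cursor on a straight chase toward the
  lagged target; it does not model corner-cutting strategies, so extreme
  `speed_scale` values produce larger positional errors than a strategic
  human would show.
* Gait, speech, facial, lower-limb and non-dominant-hand symptoms are
  outside the task's reach by construction.

## A minimal run

```{r example, eval = FALSE}
cfg <- path_config(n_trials = 3, trial_duration = 10)
cohort <- simulate_cohort(n_control = 4, n_pd = 2, n_et = 2, cfg, seed = 1)
metrics <- compute_metrics(cohort)

fit <- fit_mes_classifier(metrics, patient_label = "pd", n_iter = 50, seed = 2)
glance(fit)
tidy(fit)

scored <- mes(metrics, fit)
scored |> group_by(group) |> summarise(mean_mes = mean(mes))
```
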