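---
title: "Models and methods behind digiphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind digiphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`digiphen` implements a complete digital-phenotyping pipeline for adolescent
mood studies: a synthetic generator of raw smartphone streams with known
ground truth, extraction of thirteen passive phenotypes, EMA (ecological
momentary assessment) scheduling and adherence accounting, and the
statistical pathway linking phenotypes to daily mood ratings and
questionnaire outcomes. This vignette explains the models, the defaults and
why they were chosen, the numerical conventions, and what the simulation
results do and do not establish.

## The study design being emulated

The reference design is a 4-week parallel two-group deployment: 19 control
and 17 intervention adolescents, 28 observation days, up to 8 EMA prompts per
day (waking, before school, lunchtime, after school, before and after private
tutoring, before bedtime, and a conditional prompt when the phone is used for
more than 30 minutes after midnight), a 48-cell half-hour lifestyle grid, and
questionnaires at days 0, 14 and 28: the DASS-21 (three 7-item subscales
scored 0--3, raw sums in 0--21), a 22-item self-efficacy scale (1--5), a
30-item time-management scale (1--5), and a 21-item usability questionnaire
(1--7) for the intervention group at the final wave.

## Passive phenotypes

**Location.** Speeds are time-derivatives of consecutive GPS fixes
(haversine distance, spherical Earth of radius 6371 km). Intervals slower
than 1 km/h are stationary; a speed exactly at the threshold counts as
moving (the boundary is unstated in the reference design, so it is fixed
deterministically). Stationary points are clustered into significant places
by K-means; k is the smallest number of clusters whose maximum
point-to-centroid distance is below 500 m (capped at 10), a coverage rule
that mirrors common significant-place practice while remaining fully
testable. The five features are total distance and total time over moving
intervals, `log(var(lat) + var(lon) + 1e-10)` (the epsilon keeps motionless
days finite), the Shannon entropy of the place dwell fractions in nats, and
entropy divided by `log(k)` (defined as 0 for a single place). Dwell time of
a stationary interval is attributed to the cluster of its leading fix.

**Sleep.** Daytime is 07:00--23:00 and nighttime 23:00--07:00, both
half-open so daytime + nighttime minutes always equal the total. Sleep
crossing midnight is clipped to calendar dates before summation, so daily
aggregates never double count. When no sleep records exist, a screen-gap
heuristic infers them: screen-off gaps of at least 60 minutes are
candidates, and for each nightly rest window (21:00 to 11:00 the next day)
the candidate with the largest overlap becomes that night's sleep, clipped
to the window. The selection step matters: adolescents also leave the phone
untouched for the whole school day, and that gap overlaps the morning tail
of the rest window; taking the longest gap per night (the convention of
phone-log sleep estimation) removes this failure mode. Gaps lying entirely
inside 12:00--18:00 become naps. On synthetic data the inferred totals track
the ground truth with a mean absolute error around 14% of mean sleep, most
of it from naps shorter than the 60-minute gap threshold.

**Phone log.** Usage episodes are unlock-to-lock pairs; episodes crossing
midnight are split across dates. Per day the pipeline reports total, daytime
and nighttime usage, lock duration (1440 minus usage, so the two always
conserve the day) and the number of unlock events stamped on the date.

## The synthetic cohort

The generator is first-class, tested code: every downstream stage is
validated against its known ground truth.

**Latent distress.** Each participant carries a latent daily state per
construct (depression, anxiety, stress): a participant intercept (SD 0.3,
plus configurable group offsets) plus a stationary AR(1) process with
autocorrelation 0.5 --- day-to-day mood fluctuates but is not memoryless.
EMA ratings discretise latent value plus Gaussian noise (SD 0.6) at fixed
cut-points -1.5, -0.5, 0.5, 1.5 into the 1--5 scale.

**Behaviour.** Days follow an anchor-place routine: home at night, school
08:30--15:30 on weekdays, evening tutoring (probability 0.8) on weekdays and
an afternoon outing (probability 0.6) on weekends, with 15-minute linear
transits and Gaussian GPS jitter (20 m, 5-minute sampling). Nights have a
pre-bed phone session ending at sleep onset and a short on-waking session
--- a deliberate realism choice that also makes the screen-gap heuristic
informative. Night sleep lasts 480 +/- 30 minutes; weekday waking is capped
at 08:20. Daytime phone sessions arrive at ~22/day in awake, out-of-class
windows with exponential durations (mean 7 minutes).

**Couplings.** A configuration maps each construct to signed coefficients on
behavioural drivers, per SD of latent distress: night-usage minutes
(20 min/SD), night-sleep duration (40 min/SD), nap and outing propensity
(1.5 logit/SD), session count and duration (0.3 and 0.2 on the log scale).
The default couplings are weak (|c| 0.10--0.15) so that pooled feature--EMA
correlations land in the |r| ~ 0.1--0.2 range typical of daily
digital-phenotype data. Because behaviour is generated from the same latent
state as the ratings, recovered correlation signs are known a priori; the
generator also produces realistic *indirect* pathways (e.g. less late-night
use brings sleep onset forward and lengthens nighttime sleep), which is why
the full correlation grid shows a few coherent off-target cells.

**Randomness.** All draws flow from one root seed through per-participant
substreams, themselves split into behaviour, GPS-jitter, EMA and
questionnaire phases, so identical configurations give byte-identical
datasets and dropping the GPS stream (a large share of the cost) leaves
every other stream unchanged.

**What the generator does not emulate.** Levy-flight mobility, weather and
term calendars, notification fatigue, mood-adjective semantics, and any
dropout process. Passing tests therefore demonstrate the pipeline's
correctness and its statistical calibration under this generative model, not
the effect sizes to be expected from a real cohort.

## Statistical pathway

Outliers are removed per feature with the 1.5 x IQR fence; quartiles use
linear interpolation of order statistics (`quantile type 7`), which makes
the fences reproducible (for `1..9, 100` they are -3.5 and 14.5, excluding
only 100). Missing values are never imputed. Correlations pool all
participant-days into one Pearson coefficient per feature x construct cell
(13 x 3 grid) with a two-sided p from the t transform; a within-person
centred variant and a Benjamini--Hochberg column exist but are off by
default, matching the per-cell alpha = .05 convention of the reference
analysis. Pooling repeated days does mildly inflate the effective sample
size; under a zero-coupling simulation the grid's realised type-I rate is
about 0.055 at alpha = .05 (50 seeds), within the pre-registered acceptance
band 0.025--0.085.

Baseline group differences use the pooled-variance t test plus a
Mann--Whitney U (U = min(U1, U2), normal approximation with tie correction,
no continuity correction). The 2 x 3 mixed ANOVA uses the classical
split-plot decomposition with observed (weighted) marginal means --- verified
identical to `aov` with an `Error(id)` stratum on balanced and unbalanced
designs --- and sphericity is assumed, reproducing the uncorrected integer
degrees of freedom convention ((2, 68) for 36 participants). Scheffe
pairwise contrasts are computed only when the omnibus F is significant and
share its error term, so they can never contradict it. Cohen's d is defined
on baseline-to-post change scores with the pooled change SD (the exact
formula is unstated in the reference design; this choice is declared here).

**Power.** The repeated-measures calculator searches the smallest per-group
n whose noncentral-F power reaches the target. The effect family and the
repeated-measures correlation rho are explicit parameters because a printed
sample size cannot be reproduced without them; with the between-subjects
family, Cohen's f = 0.33, rho = 0.5, alpha = .05 and power 80%, the
calculator returns exactly 26 per group (power 0.7996 at 25, 0.8154 at 26),
matching the reference design's figure.

## Problem sizes used in the test suite

The coupling-recovery studies run at the emulated study's own dimensions:
negative-coupling recovery uses 100 seeds of the full 19 + 17 x 28 design
(phone features only, GPS stream skipped for cost --- participant count, not
day count, dominates the between-person variance of the pooled r), and the
strong positive coupling recovery uses 100 seeds of 30 participants x 28
days (sleep features only). Type-I calibration, which depends only on the
null being true, uses 50 seeds of a smaller 12 x 14 cohort with 10-minute
GPS sampling so the full 13-feature grid stays cheap. With |r| above 0.15 at
around a thousand pooled days, detection power at these sizes is effectively
1, so the replicate fractions test calibration rather than luck.

## Known limitations

Correlations treat participant-days as exchangeable; a multilevel model
would be the right tool for inference on real data and is deliberately out
of scope. The ANOVA assumes sphericity by design. The screen-gap sleep
heuristic cannot see naps shorter than its gap threshold and mistimes sleep
onset by the pre-bed phone habit it relies on. The usability questionnaire
is scored but feeds no downstream inference.
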