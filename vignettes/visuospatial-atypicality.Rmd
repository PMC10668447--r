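---
title: "Detecting visuospatial atypicality in VR visual-search gameplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting visuospatial atypicality in VR visual-search gameplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectvr)
```

## The problem

After a brain injury, visuospatial attention problems — most prominently
unilateral spatial neglect, a bias toward ipsilesional space that makes
contralesional objects hard to orient toward and act upon — are routinely
screened with pen-and-paper tests of limited sensitivity and specificity.
Immersive virtual reality motivates free head, eye and hand search over a
much wider field, and logs every orientation sample and selection. This
package implements a normative-modelling analysis of such gameplay: it
reduces telemetry to a fixed vector of attention metrics per player and
asks, metric by metric, whether a player's value lies outside the range
that both a control group and a patient group establish as typical. The
output is deliberately called *visuospatial atypicality*, never a
diagnosis: the same player can be typical or atypical depending on the
gameplay of the reference groups, and atypical patterns are not
necessarily pathological.

## Telemetry and geometry

Gameplay is a cue/array visual search on a sphere centred at the headset.
On each trial a central cue is selected, a search array appears, and the
trial ends when any element — target or distractor — is selected; players
who cannot find the target are instructed to select a distractor (a
"give-up" selection, counted incorrect with no special error type).
Array elements sit on concentric rings (eccentricities in multiples of
12.5°, within-ring spacing 15°, 2-m radius). Headset and controller
forward vectors are converted to a pair of signed angles relative to the
calibrated forward axis — `lateral` (positive right) and `vertical`
(positive up). In the conventional clinical labelling the horizontal
angle is called *latitude* and the vertical angle *longitude*; the
package uses the unambiguous lateral/vertical names internally and keeps
the latitude/longitude labels in `metric_names()` for figure parity. The
mapping is a single documented constant: if a data source uses the
opposite assignment, swap the frame columns at import.

The default game is the six-level, 19.5-minute preset: tutorial (0.5 min,
excluded from analysis), axes (3.0), stimuli (4.5), depth (6.0, elements
on 2-m and 4-m surfaces), full field (4.5, four rings), free viewing
(1.0, no trials). Two open points in the level geometry are configurable
rather than hard-coded: the single-ring eccentricity of the eight-element
levels (default 15°, the value quoted for those levels, although it sits
oddly beside the 12.5°-spaced ring system) and the fourth full-field ring
(assumed 50°).

## The fourteen attention metrics

Six primary metrics are computed per game level:

* **accuracy** (%) — percent correct trials;
* **RT** (s) — mean reaction time of correct trials after within-player
  outlier trimming;
* **headset / controller latitude and longitude means** (°) — arithmetic
  means of the orientation angles over search-phase (array) frames; cue
  frames are excluded. The free-viewing level has no trials and
  contributes raycast metrics only.

RT trimming uses the player's own Tukey fences: a trial RT is an outlier
when it lies strictly beyond `[Q1 − 1.5 IQR, Q3 + 1.5 IQR]` of the
player's correct-trial RTs, computed in one pass (no iterative
re-fencing — re-applying the rule to its own kept set is a different
computation and may flag anew). Strict inequalities mean zero-IQR data
flags nothing. Trimming is applied separately per level for the level
metrics, and once over all pooled trials for the spatial-preference
scores (pooled-before-split: the fences are estimated on the pooled
correct trials, then the survivors are divided into contrast sides).

Eight pooled spatial-preference difference scores contrast quadrants and
eccentricities, pooling trials across levels. Targets are assigned to
quadrants by the dominant axis of their position; exact ties
(|lateral| = |vertical|, including the origin) belong to neither quadrant
and are excluded. Subtraction order fixes the signs so that positive
quadrant scores always mean a right/up advantage: accuracy is
right − left (up − down), RT is left − right (down − up). For the
adjacent-eccentricity contrasts (12.5° vs 25.0°, 25.0° vs 37.5°) the
direction of subtraction is not recoverable from convention alone; this
package defines positive as a *central* advantage (accuracy central −
peripheral, RT peripheral − central) and exposes
`options(neglectvr.ecc_sign = -1)` to flip it. Any metric cell without a
qualifying observation is missing, never zero-imputed.

## The atypicality rule

For each metric (× level for the per-level metrics) quartiles are
estimated separately in the control and patient reference groups, and a
player's value is atypical when it falls strictly outside the 1.5 × IQR
Tukey fences of **both** groups:

$$B = \big[(M < Q1_c - 1.5\,IQR_c) \lor (M > Q3_c + 1.5\,IQR_c)\big]
\land \big[(M < Q1_p - 1.5\,IQR_p) \lor (M > Q3_p + 1.5\,IQR_p)\big].$$

The conjunction is the point of the method: a value must be extreme
relative to the behaviour of *both* clinically relevant populations, so
the false-positive rate can never exceed that of either single-group
Tukey rule, and when the groups coincide the rule reduces exactly to the
ordinary one. Per-level Booleans are averaged over the player's
non-missing levels into a proportion in [0, 1]; pooled metrics contribute
one Boolean. The player × metric table of these proportions is the
summary matrix, and a player's mean over non-missing cells is their mean
atypicality.

Three estimation choices are configurable because the original
convention is not fully pinned down:

* **Quartile method** — linear interpolation (type 7), the convention
  that reproduces the shipped intake table's printed IQRs (patient ages
  Q1 = 47, Q3 = 68, IQR = 21; FIM cognition IQR = 1.8); set
  `options(neglectvr.quantile_type = )` to change it.
* **Self-inclusion** — by default the evaluated player is included in
  their own group's quartiles, the straightforward reading of a
  group-quartile rule; `build_summary_matrix(leave_one_out = TRUE)`
  holds each player out instead (more sensitive for small groups, where
  an extreme player can stretch their own fences).
* **Fence grain** — fences are estimated per metric × level, which makes
  the "mean across levels" a mean of comparable Booleans. Groups smaller
  than two give undefined quartiles: affected cells are missing with a
  warning, never silently typical.

## Group-level statistics

Typicality counts (atypical/typical × patients/controls) are summed at
the finest available Boolean — per player × metric × level, the default
`"boolean"` grain; the `"cell"` grain counts each summary-matrix cell
once instead, a cell being atypical when its proportion exceeds zero.
The 2 × 2 table is tested with an uncorrected Pearson chi-square (the
`correct` flag adds Yates' correction). Midpoints are compared with
Wilcoxon rank-sum / signed-rank tests and variances with Levene's test
centred at the median (the Brown–Forsythe variant, robust under the
non-Gaussian distributions this data produces; centring at the mean is a
flag). No multiple-testing correction is applied.

One numerical decision deserves a note. The usual normal approximation
for the Wilcoxon p-value is poor exactly where this analysis lives —
samples of 9 and 13 with heavy midrank ties (mean atypicality is often
exactly 0 for many players): against the exact permutation distribution
the approximation can be off by more than 0.1. The package therefore
computes the exact tie-aware permutation p (a subset-sum / sign-flip
dynamic programme over doubled midranks) whenever the combined sample
has at most 40 observations, and falls back to the tie-corrected normal
approximation beyond. The reported statistic conventions are documented
on each function: the standardised deviate for the rank-sum test, the
less-frequent-sign rank sum for the signed-rank test.

## Questionnaires and demographics

Feasibility instruments are scored as administered around gameplay: a
single-category simulator-sickness rating (1 = no symptoms … 7 =
vomiting; eligibility requires strictly below 4, moderate nausea); the
25-item GEQ-R with four factor means (positive affect, competence,
negativity, flow — the item-to-factor mapping ships as an editable CSV
because the instrument's published mapping is not distributed here); the
10-item SUS with standard scoring (odd items score − 1, even items
5 − score, sum × 2.5) and lower-inclusive acceptability bands
(acceptable ≥ 70, marginal ≥ 50); and FIM normalisation by item counts
(13 motor, 5 cognition, 18 total). The screening rule combines the
sickness cut-off with an orientation-to-time-and-space score of at least
6 of 10.

## The gameplay simulator

No clinical dataset ships with the package, so a generative agent model
(`simulate_session()`, `simulate_cohort()`) produces telemetry with the
statistical structure the analysis assumes: cue/array trials on the
spherical grids, orientation traces at the tracking rate (90 Hz by
default), lateralised orienting bias, hemifield accuracy deficits, RT
slowing, and give-up distractor selections. The behavioural model is the
simulator's own — the field's literature describes no quantitative model
to copy — and was chosen as the simplest mechanism that produces
bias-dependent raycast and performance effects:

* **Scan path** — at each step the agent inspects an uninspected element
  with probability ∝ `exp(−d / temperature)`, `d` being the distance
  from the agent's effective origin (current orientation shifted by the
  orienting bias). The default temperature of 75° makes spatial guidance
  deliberately weak, which keeps the inspected-element average near the
  grid centre.
* **Head model** — the head carries a fraction (`head_gain`, default
  0.25, as in seated viewing where the eyes do most of the work) of the
  gaze shift about the agent's preferred direction, so the session-mean
  headset lateral angle is an approximately unbiased estimator of
  `lateral_bias`. This is a design constraint, not an accident: the
  package's calibration property requires injected biases of 5–30° to be
  recovered within ±2° from 100 trials, and both defaults above were
  fixed to satisfy it by construction before any acceptance measurement.
* **Deficit gradients** — inspecting the target detects it with
  probability `1 − miss_slope × (degrees into the neglected hemifield)`,
  and elements inspected in that hemifield incur extra dwell
  (`contralesional_rt_slope`). After `give_up_after` inspections the
  agent selects the inspected distractor nearest its preferred
  direction.
* **Timing** — dwell per element defaults to 0.35 s with 0.1 s noise,
  selection adds a 0.4 s motor constant, cues take 0.8 s; levels run
  until their minimum duration, as in the game.

The default cohort generators mirror the study conditions: 9 controls
and 13 patients, of whom 3 carry a left-neglect-like profile (rightward
bias of 10–25°, matching the case-report magnitude of roughly 9–25°
rightward orientation, plus miss and slowing gradients) and the rest
generalised slowing without lateralised deficit; controls carry only a
small orienting idiosyncrasy (SD 1.5°). All randomness flows through a
per-player child seed derived from the master seed, so cohorts are
byte-reproducible.

What the simulator does **not** emulate: saccade-level eye movements,
biomechanical head/hand dynamics, learning or fatigue across levels,
discontinuation midway through a session (real matrices have missing
levels), and any claim of behavioural realism beyond the statistical
structure needed to exercise the pipeline. Passing tests on simulated
cohorts therefore validates the *analysis* — estimator correctness, sign
conventions, calibration of the outlier rule — not the clinical
sensitivity of the gameplay itself.

## Verification strategy and problem sizes

The package's tests pair every estimator with an independent oracle:
quartiles and fences against a hand-written interpolation formula on
1000 random vectors; rank-test p-values against full `combn`/sign-grid
enumeration; the chi-square against its closed form; Levene's statistic
against a direct ANOVA on absolute deviations; and a six-player fixture
cohort whose fourteen metrics and seven constructed flags were computed
by hand. Calibration properties run on simulated cohorts at the study's
9 + 13 group sizes with a shortened single-level game and a reduced
tracking rate (5 Hz): 200 null cohorts verify that the conjunction's
flag rate never exceeds the single-group Tukey rate (which holds
observation-wise, by construction), and 50 cohorts per bias level verify
that lateral-metric flag rates are non-decreasing over injected biases
of 0–30°. These sizes were chosen so the whole battery runs in a few
minutes while keeping Monte-Carlo error well below the effects asserted.

## Limitations

The atypicality label is sample-referential and was prototyped on a
small, heterogeneous cohort; fences estimated from 9 + 13 players move
with every added player, and nothing here validates the label against
functional outcomes. The analysis weights all fourteen metrics equally
although they are unlikely to carry equal functional significance.
Deposited clinical telemetry is distributed separately and reproduction
of the published group statistics is contingent on matching the original
quartile and counting conventions; the configuration flags above exist
precisely to sweep those conventions.
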