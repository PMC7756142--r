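---
title: "Kinematics and statistics of shared-avatar dyadic reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics and statistics of shared-avatar dyadic reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two people jointly control a single virtual body — a *shared avatar*
whose hand is the pointwise mean of their two hands — their motor behaviour
can change: the avatar's reach may become straighter and smoother than either
individual's, reaction may become faster, and the individuals' own hands may
drift apart even as the avatar stays on target.  Distinguishing a genuine
behavioural change from a pure arithmetic consequence of averaging two noisy
trajectories is the central inferential problem: averaging two independent
noisy reaches *always* reduces path deviation and jerk (noise variance
halves), so those metrics cannot by themselves demonstrate cooperation.  The
inter-participant distance (IP) between the two members' hands can: under
pure averaging it is identical across conditions, whereas genuine
strategy change inflates it.

`sharedreach` implements the full analysis chain for such experiments: a
synthetic dyad-experiment generator, the avatar trajectory model, the reach
kinematics, and the repeated-measures statistical battery, joined into a
reproducible pipeline.

## The avatar model

Both members' hand paths are carried as uniformly sampled 3-D trajectories.
`align_time_base()` puts two recordings on one clock (intersection of
supports, linear interpolation, never extrapolating), and
`average_trajectories()` forms the avatar as

$$p_{av}(t) = w\,p_a(t) + (1 - w)\,p_b(t), \qquad w = \tfrac12 .$$

Averaging is done on the hand (end-effector) position in Cartesian space.
An arm-posture average (joint space) could differ, but every analysed
quantity here is a hand statistic, so hand-space averaging is the assumption
that matters and it is stated openly.  The weight is fixed at 0.5 in the
shared-body design; the argument exists for extensions.

## Kinematic statistics

For each segmented reach (target appearance to target touch; the touch rule
is point-in-cube on the hand sample):

* **Reach deviation (D)** — trajectory path length minus the straight-line
  distance between its endpoints (metres; 0 for a straight reach).  A pure
  path property: invariant to rigid motions and time reparameterisation.
* **Mean hand jerk (J)** — mean magnitude of the third time-derivative of
  position (m s^-3), by default the five-point central third difference
  \((p_{i+2}-2p_{i+1}+2p_{i-1}-p_{i-2})/(2\,\mathrm{d}t^3)\).  "Average
  jerk" admits several estimators; the magnitude-mean is unit-interpretable
  and ordering-equivalent with the integrated forms on our data, and the
  estimator is pluggable (`jerk_estimator`).
* **Reaction time (RT)** — time from target appearance until hand speed
  first exceeds 10 % of its within-trial maximum (strict crossing, central
  difference speed).
* **Task time (TT)** — target appearance to touch.
* **Target error (TE)** — distance from the reach endpoint to the target
  centre.
* **Inter-participant distance (IP)** — time-averaged distance between the
  two members' hands, overall and over three equal-duration phases of the
  reach window.  When the two members' windows end at different times the
  default spans the common onset to the later touch, holding the earlier
  finisher at its endpoint (`ip_window = "union"`); the intersection
  convention is available.  By construction the overall value equals the
  duration-weighted mean of the phase values.

Kinematic quantities are aggregated to **dyad-level** units (the human value
of a dyad is the mean of its two members' per-participant means; the avatar
contributes one value per dyad), while ratings stay at **participant level**
— this is what the repeated-measures degrees of freedom of the analysis
(t(9), W(19), F(2, 18)) force.

## The synthetic dyad generator

`generate_dyad_experiment()` emulates the study design: 10 dyads
(20 participants), two conditions (solo body vs shared body) of 4 sessions
each in counter-balanced alternating order (odd dyads start solo, even dyads
shared), cube targets drawn from a frontal workspace box, both members
always seeing the same target, and agency (0–100 %) and ownership (−3..+3)
ratings after each condition.

Each reach is a quintic minimum-jerk path from a home position to the target
centre — the normative model of point-to-point reaching, with zero boundary
velocity and acceleration and peak speed \(1.875\,L/T\) — onset-delayed by a
participant reaction-time draw, plus:

* a participant-specific lateral **bow** \(a\,\sin^2(\pi\tau)\)
  (`curvature_amp`, default 0.04 m): natural path curvature.  The squared
  sine keeps boundary velocities zero, so the bow never trips the RT
  threshold by itself;
* smooth Gaussian **motor noise** (`noise_sd` 0.0015 m), low-pass filtered
  with a zero-phase Gaussian kernel (`noise_smooth_tau` 0.07 s) so numerical
  third derivatives remain finite and pre-movement speed stays far below
  the 10 %-of-peak RT threshold;
* in the shared condition, the cooperative strategy: each member subtracts
  `strategy_gain` (0.6) times the **dyad-mean bow**.  This straightens the
  avatar by \(1-\text{gain}\) while leaving the difference between the two
  members' hands unchanged — the member does not simply straighten their own
  path, they correct the avatar's.  With gain 1 and zero noise the avatar is
  exactly the straight minimum-jerk path, whatever the members' bows;
* an anti-correlated **divergence** \(\pm a_d\,w(\tau)\) (`divergence_amp`
  0.07 m) along the lateral axis: the two members' preferred avatar paths
  conflict, so their own hands drift apart while the divergence cancels
  exactly in the avatar.  The default weight is the smoothstep
  \(w = 3\tau^2 - 2\tau^3\) (monotone 0→1 with zero boundary velocity, so it
  adds no spurious numerical jerk and builds up through mid-reach; a power
  weight \(\tau^p\) is available for comparison);
* endpoint scatter inflated by `te_inflation` (1.35) in the shared
  condition via a smooth ramped offset — individual accuracy degrades while
  the avatar's endpoint scatter, which averages two independent inflated
  offsets, stays at about \(1.35/\sqrt2 \approx 0.95\) of the solo level;
* a reaction-time facilitation (`rt_shared_gain` 0.025 s) and a 3 % movement
  slowdown (`shared_slowdown`) in the shared condition: the generative
  stand-ins for faster joint reactions with roughly unchanged total task
  time.

In the shared condition the trial ends when the **avatar** touches the
target; the members' own hands need not (and because of the divergence often
do not) enter the cube.  This is what makes the members' own target error
the largest of the three cases while the avatar's stays at the solo level.
Reaches whose avatar (or solo hand) never touches are counted and excluded,
never silently dropped.

Movement time is drawn per trial (it is mostly set by the common target
distance) with a small per-member jitter (sd 0.03 s), and reaction times
combine a participant trait (`rt_sd` 0.015 s) with trial jitter; larger
member timing offsets would dominate IP through an along-path gap and mask
the lateral structure the analysis is about.

Ratings are linked to kinematics with the simplest monotone model admitting
the reported correlation signs: shared-condition ownership is linear in the
dyad's avatar reach deviation (slope `rating_link_slope` per SD, noise
`rating_noise_sd`, clipped and rounded to the Likert scale), and the agency
change is linear in minus the standardised jerk change.  Agency draws centre
on 85 % (solo) and 62 % (shared) — below 100 % and strictly above 50 %
respectively.

### The averaging-only null

`averaging_null_config()` zeroes every condition asymmetry
(`strategy_gain`, `divergence_amp`, `te_inflation = 1`, `rt_shared_gain`,
`shared_slowdown`): participants behave identically in both conditions and
the avatar differs from its members only through averaging.  Under this null
the package's tests verify that avatar D and J still fall below the members'
(noise averaging) while the IP condition effect stays non-significant — the
logic by which IP, not D or J, discriminates genuine cooperation.

### What the generator does not emulate

No biomechanical arm model, joint-angle kinematics, muscle or impedance
dynamics, visual feedback loops, learning across sessions, or fatigue.
Passing tests demonstrate that the *analysis* machinery recovers the
structure the generator encodes; they do not validate claims about real
motion-capture data beyond the estimators' correctness on their closed-form
oracles.

## The statistical battery

`run_test_battery()` mirrors the study's per-figure analysis plan.  Every
analysis passes a Shapiro–Wilk gate at `alpha` (0.05): the parametric branch
(paired t with Cohen's d; one-way repeated-measures ANOVA with Mauchly's
sphericity check and Holm-adjusted paired-t post hocs) when no involved
sample deviates from normality, otherwise the rank branch (Wilcoxon
signed-rank with the matched-pairs rank-biserial effect size
\((W^+-W^-)/(W^++W^-)\); ANOVA on aligned-rank-transformed data with Tukey
post hocs).

Implementation notes and deliberate choices:

* **Wilcoxon**: zero differences are dropped before ranking (19 positive
  differences among 20 pairs give \(W = 19\cdot20/2 = 190\)); exact p by
  full enumeration of sign assignments (via the signed-rank null
  distribution) for up to 25 untied differences, tie-corrected normal
  approximation with continuity correction otherwise; two-sided throughout.
* **ART**: per the aligned-rank procedure, each effect's response is aligned
  (raw minus fixed-effect cell mean, plus the estimated effect of interest)
  and ranked as one column; the repeated-measures F test then runs on the
  ranks.  For a one-way design this reduces to rank ANOVA.  Partial eta
  squared for ART effects is computed from aligned-rank sums of squares
  (equivalently the \(F\,df_1/(F\,df_1+df_2)\) identity on the rank scale).
* **Post hoc df**: the Kenward–Roger approximation is not reimplemented.
  For balanced complete within-subject designs with compound symmetry the
  classical error df \((k-1)(n-1)\) coincide with it (t(18) for 3 levels and
  10 dyads), so Tukey contrasts use classical df and every report notes the
  substitution.
* **Cohen's d for paired t**: the default is \(d_z = \bar d/s_d\); the
  averaged-variance convention is available (`d_type = "av"`).  Published
  "d" values for paired designs follow no single convention, so the choice
  is explicit and configurable.
* **Spearman**: Pearson correlation of average ranks; exact p for n ≤ 9
  without ties, t approximation otherwise.

## Pipeline, formats, reproducibility

`run_pipeline()` drives simulate → metrics → battery from a single YAML/JSON
config (seed mandatory) and writes `metrics.tsv`, `ip.tsv`,
`stats_report.tsv`/`.txt` and `manifest.json` (config hash, seed, package
version, excluded-trial counts).  Every emitted byte except time stamps is
determined by config + seed.  The trajectory CSV dialect is one row per
sample (`dyad_id, participant_id, actor, condition, session, trial, t_s,
x_m, y_m, z_m, target_*`), UTF-8, decimal point, metres, right-handed
coordinates with +y facing forward.  `cli_main()` (and the installed
`inst/cli/sharedreach` script) exposes subcommands
`simulate | metrics | stats | report | all` with exit codes 0 (ok),
2 (parse error), 3 (incomplete design), 4 (no data).

## Numerical choices and degenerate inputs

* Sampling period 0.01 s (100 Hz) by default; capture rate is configurable.
* Derivatives by central differences; no smoothing is applied to synthetic
  data (the noise is band-limited by construction), and a smoothing cutoff
  is left to the caller for real recordings.
* The RT crossing is strict (>) and searched from the onset; a trial whose
  peak speed is zero raises a typed error rather than returning NA.
* Constant samples, all-zero paired differences, singular within-subject
  covariances and incomplete designs all raise classed conditions
  (`sharedreach_degenerate_sample`, `sharedreach_incomplete_design`, ...)
  that the CLI maps to exit codes.
* F statistics with zero effect sums of squares are reported as 0 (with
  partial eta squared 0) rather than NaN.

## Problem sizes used in the shipped checks

The package's own Monte-Carlo verification uses the default study geometry
(10 dyads, 4 sessions per condition) with 12 reaches per session — enough
for stable per-cell means while keeping a full simulated experiment around
1.5 s — with 100 seeded replicates for the regime-level properties and 2000
replicates per configuration for type-I-error calibration at n = 10 and
n = 20.  The per-session trial count is a config field; a 5-minute session
at a realistic pace would hold several times more reaches, which only
tightens the cell means.

## Known limitations

* The generator's cooperative mechanism (mean-bow compensation plus smooth
  anti-correlated divergence) is one of many that reproduce the qualitative
  regime; parameter estimates from it are not claims about any real dyad.
* Hand-space (not joint-space) averaging is assumed throughout.
* The ART eta-squared convention on the rank scale is stated, not the only
  possible one; published values computed on other scales will differ.
* No adapter is provided for any specific motion-capture deposit format;
  real data must be converted to the trajectory CSV dialect first.
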