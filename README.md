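# sharedreach

Kinematic and statistical analysis of **shared-avatar dyadic reaching**:
experiments in which two people jointly control one virtual body whose hand
is the average of their own hand movements.

## The scientific problem

When a dyad shares an avatar, the avatar's reaches can become straighter and
smoother than either member's own, its reaction faster, and its endpoint
accuracy preserved — even while the members' own hands drift apart and their
individual accuracy degrades.  The inferential difficulty is that averaging
two independent noisy trajectories *always* reduces path deviation and jerk
(noise variance halves), so improvements in those metrics alone cannot
demonstrate cooperation.  The discriminating statistic is the
**inter-participant distance (IP)** between the two members' hands: under a
pure averaging null it is identical across conditions; genuine strategy
change inflates it, concentrated near the target.

`sharedreach` implements the full chain for such studies, for motor-control
and virtual-embodiment researchers:

* **Avatar model** — trajectory alignment onto a common time base and
  pointwise averaging: `p_av(t) = (p_a(t) + p_b(t)) / 2`.
* **Kinematics** — reach segmentation by target touch and the standard
  statistics per reach:
  * reach deviation `D` = path length − straight-line distance (m),
  * mean hand jerk `J` = mean |third derivative of position| (m s⁻³),
  * reaction time `RT` = target onset → first crossing of 10 % of peak
    hand speed (s),
  * task time `TT` = target onset → touch (s),
  * target error `TE` = endpoint-to-target-centre distance (m),
  * inter-participant distance `IP`, overall and over three equal-duration
    movement phases (m).
* **Statistics** — the repeated-measures battery: Shapiro–Wilk normality
  gating; Wilcoxon signed-rank tests with exact small-sample p values and
  the matched-pairs rank-biserial effect size `(W⁺ − W⁻)/(W⁺ + W⁻)`; paired
  t tests with Cohen's d; one- and two-way repeated-measures ANOVA with the
  aligned rank transform (ART) for non-normal data; Holm and Tukey post hoc
  adjustment; partial eta squared `F·df₁/(F·df₁ + df₂)`; Spearman rank
  correlation.
* **Synthetic dyad generator** — a fully specified generative model of the
  study design (10 dyads, 2 conditions × 4 counter-balanced sessions, cube
  targets, minimum-jerk reaches with natural curvature, motor noise, and a
  cooperative shared-condition strategy), so the entire pipeline is testable
  without any experimental data, including the averaging-only null.
* **Pipeline** — one config file → metrics TSV, IP table, statistics report
  and manifest, deterministic under the seed; plus a small CLI
  (`inst/cli/sharedreach`).

## Worked example

```r
library(sharedreach)

exp <- generate_dyad_experiment(sim_config(seed = 1))
exp
#> <dyad_experiment: 10 dyads, 1920 human reaches, 480 avatar reaches, 0 excluded (no touch), seed 1>

bat <- run_test_battery(exp$metrics, exp$ratings)
bat
#> Shared-avatar reaching battery (10 dyads, 20 participants, gate alpha = 0.05)
#> Note: post hoc df are classical balanced-design df (Kenward-Roger not applied).
#>
#> -- sense of agency: solo vs shared [branch: t]
#> paired_t: stat = 6.737, df = (19), p = 1.94e-06, d = 1.506
#>    solo vs 100%: paired_t: stat = -8.065, df = (19), p = 1.48e-07, d = -1.803
#>    shared vs 50%: paired_t: stat = 3.494, df = (19), p = 0.00243, d = 0.781
#>
#> -- sense of ownership: solo vs shared [branch: wilcoxon]
#> wilcoxon_signed_rank: stat = 146.000, df = (17), p = 0.000921, d(rb) = 0.908
#>
#> -- reach deviation D [branch: parametric]
#> mauchly_sphericity: stat = 0.199, df = (2), p = 0.00155
#> rm_anova_oneway: stat = 187.177, df = ( 2, 18), p = 9e-13, eta_p^2 = 0.954
#> Post hoc contrasts (holm adjustment):
#>                      contrast statistic df     p_raw     p_adj effect_size
#>     solo_human - shared_human     5.975  9 2.089e-04 2.089e-04       1.889
#>    solo_human - shared_avatar    52.285  9 1.720e-12 5.161e-12      16.534
#>  shared_human - shared_avatar     9.728  9 4.499e-06 8.998e-06       3.076
#> ...
```

Reading the output: participants report less agency over the shared avatar
than over their own (t(19) = 6.7) yet still clearly above their actual 50 %
control weight; the three-level deviation ANOVA over (solo human, shared
human, shared avatar) dyad means shows the avatar's path is straighter than
either human case, and the humans themselves straighten in the shared
condition (Holm-adjusted paired contrasts, df 9 = dyads − 1).

A tidy table of every test is `summary(bat)`; `run_pipeline()` writes the
same results as TSV/text artifacts, and `make_figures()` draws the
means-±-SE bar panels and the embodiment–kinematics scatter plots.

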