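Package: sharedreach
Title: Kinematic and Statistical Analysis of Shared-Avatar Dyadic Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of arm-reaching experiments in which two
    participants jointly control a shared virtual avatar whose hand is the
    average of their own hand movements.  Provides a synthetic dyad-experiment
    generator, trajectory averaging on a common time base, the standard reach
    kinematics (reach deviation, mean hand jerk, reaction time, task time,
    target error, and phase-wise inter-participant distance), and the
    repeated-measures statistical battery used in shared-embodiment studies:
    Shapiro-Wilk normality gating, Wilcoxon signed-rank tests with
    matched-pairs rank-biserial effect sizes, paired t tests, one- and two-way
    repeated-measures ANOVA with the aligned rank transform for non-normal
    data, Holm and Tukey post hoc adjustment, partial eta squared, and
    Spearman rank correlation.  A small pipeline driver turns a single config
    file into metrics tables, a statistics report and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
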