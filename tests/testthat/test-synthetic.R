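# The synthetic dyad generator: design counts, determinism, strategy
# contracts, divergence structure, and the rating links.

test_that("experiment counts follow the design", {
  exp <- generate_dyad_experiment(sim_config(n_dyads = 2, trials_per_session = 5,
                                             n_sessions_per_condition = 4,
                                             seed = 5))
  actors <- vapply(exp$trials, function(t) t$participant_id, character(1))
  # 2 dyads x 2 members x 2 conditions x 4 sessions x 5 trials
  expect_equal(sum(actors != "avatar") + nrow(exp$excluded[
    exp$excluded$participant_id != "avatar", , drop = FALSE]), 160L)
  # one avatar reach per shared dyad-trial
  expect_equal(sum(actors == "avatar") + sum(exp$excluded$participant_id == "avatar"),
               2L * 4L * 5L)
  # ratings: one row per participant per condition
  expect_equal(nrow(exp$ratings), 2L * 2L * 2L)
})

test_that("condition order is counter-balanced across dyads", {
  exp <- generate_dyad_experiment(sim_config(n_dyads = 2, trials_per_session = 1,
                                             seed = 8))
  first_cond <- function(d) {
    tr <- Filter(function(t) t$dyad_id == d & t$session == 1 &
                   t$participant_id != "avatar", exp$trials)
    unique(vapply(tr, function(t) t$condition, character(1)))
  }
  expect_setequal(first_cond(1), c("solo", "shared"))  # both appear in session 1
  # odd dyads start solo, even dyads start shared: check via trial ordering
  conds <- vapply(exp$trials, function(t) t$condition, character(1))
  d1 <- conds[vapply(exp$trials, function(t) t$dyad_id == 1, logical(1))]
  d2 <- conds[vapply(exp$trials, function(t) t$dyad_id == 2, logical(1))]
  expect_equal(d1[1], "solo")
  expect_equal(d2[1], "shared")
})

test_that("same seed reproduces the experiment exactly", {
  e1 <- generate_dyad_experiment(sim_config(n_dyads = 2, trials_per_session = 2,
                                            seed = 99))
  e2 <- generate_dyad_experiment(sim_config(n_dyads = 2, trials_per_session = 2,
                                            seed = 99))
  expect_identical(lapply(e1$trials, function(t) t$trajectory$xyz),
                   lapply(e2$trials, function(t) t$trajectory$xyz))
  expect_identical(e1$ratings, e2$ratings)
  e3 <- generate_dyad_experiment(sim_config(n_dyads = 2, trials_per_session = 2,
                                            seed = 100))
  expect_false(identical(e1$ratings, e3$ratings))
})

test_that("noiseless straight reaches have zero deviation and closed-form jerk", {
  cfg <- sim_config(n_dyads = 1, trials_per_session = 2, noise_sd = 0,
                    curvature_amp = 0, divergence_amp = 0, te_inflation = 1,
                    seed = 3)
  exp <- generate_dyad_experiment(cfg)
  solo <- Filter(function(t) t$condition == "solo", exp$trials)
  for (tr in solo) {
    expect_lt(reach_deviation(tr), 1e-9)
    truth <- attr(tr, "truth")
    L <- sqrt(sum((tr$target$position - cfg$home)^2))
    T <- truth$duration
    # the trial window covers the movement only up to cube entry; average the
    # closed-form |jerk| over the covered span and the full sample count
    tau_touch <- min((tr$touch_time - truth$rt) / T, 1)
    n_all <- nrow(tr$trajectory$xyz)
    j_exp <- integrate(function(tau) (L / T^3) * abs(60 - 360 * tau + 360 * tau^2),
                       0, tau_touch)$value * T / (n_all * tr$trajectory$dt)
    expect_equal(mean_jerk(tr), j_exp, tolerance = 0.05)
  }
})

test_that("strategy contracts hold", {
  cfg <- sim_config(noise_sd = 0, divergence_amp = 0, strategy_gain = 1,
                    te_inflation = 1, seed = 1)
  b <- reach_base(cfg$home, c(0.1, 0.65, 1.1), rt = 0.2, duration = 0.7,
                  dt = cfg$dt)
  s1 <- apply_strategy(b, "shared", cfg, bow_angle = 0.4, div_sign = 1,
                       partner_bow_angle = 2.5)
  s2 <- apply_strategy(b, "shared", cfg, bow_angle = 2.5, div_sign = -1,
                       partner_bow_angle = 0.4)
  # gain 1, no divergence, no noise: the average is the straight base exactly
  av <- average_trajectories(s1, s2)
  expect_equal(av$xyz, b$traj$xyz, tolerance = 1e-12)
  # null strategy: same seed gives identical solo and shared outputs
  cfg0 <- sim_config(strategy_gain = 0, divergence_amp = 0, te_inflation = 1,
                     seed = 1)
  set.seed(42); solo <- apply_strategy(b, "solo", cfg0, bow_angle = 1)
  set.seed(42); shared <- apply_strategy(b, "shared", cfg0, bow_angle = 1)
  expect_identical(solo$xyz, shared$xyz)
  expect_error(apply_strategy(b, "duet", cfg0),
               class = "sharedreach_invalid_argument")
})

test_that("divergence grows over phases as the weight dictates", {
  # zero noise / bow: inter-hand distance is exactly 2 a w(tau); with the
  # power weight w = tau^2 the phase means follow the closed form
  cfg <- sim_config(noise_sd = 0, curvature_amp = 0, divergence_amp = 0.05,
                    divergence_weight = "power", divergence_power = 2,
                    te_inflation = 1, seed = 2)
  b <- reach_base(cfg$home, c(0.0, 0.65, 1.1), rt = 0, duration = 0.6,
                  dt = cfg$dt, t_total = 0.6)
  s1 <- apply_strategy(b, "shared", cfg, bow_angle = 0, div_sign = 1)
  s2 <- apply_strategy(b, "shared", cfg, bow_angle = 0, div_sign = -1)
  target <- target_spec(c(0.0, 0.65, 1.1), 10)  # huge cube: full window kept
  ip <- interpersonal_distance(
    reach_trial(s1, target, 0, 0.6, condition = "shared"),
    reach_trial(s2, target, 0, 0.6, condition = "shared"))
  phase_mean_w <- vapply(0:2, function(k)
    integrate(function(tau) tau^2, k / 3, (k + 1) / 3)$value * 3, numeric(1))
  expect_equal(ip$phases, 2 * 0.05 * phase_mean_w, tolerance = 0.05)
  # Monte-Carlo with motor noise: phase3 / phase1 ratio near the closed form
  cfgn <- sim_config(noise_sd = 5e-4, curvature_amp = 0, divergence_amp = 0.05,
                     divergence_weight = "power", divergence_power = 2,
                     te_inflation = 1, seed = 2)
  set.seed(31)
  rat <- replicate(200, {
    t1 <- apply_strategy(b, "shared", cfgn, 0, 1)
    t2 <- apply_strategy(b, "shared", cfgn, 0, -1)
    ipn <- interpersonal_distance(
      reach_trial(t1, target, 0, 0.6, condition = "shared"),
      reach_trial(t2, target, 0, 0.6, condition = "shared"))
    ipn$phases[3] / ipn$phases[1]
  })
  expect_equal(mean(rat), phase_mean_w[3] / phase_mean_w[1], tolerance = 0.1 *
                 phase_mean_w[3] / phase_mean_w[1])
})

test_that("rating links behave as configured", {
  set.seed(123)
  summ <- data.frame(participant_id = rep(sprintf("p%02d", 1:20), 2),
                     dyad_id = rep(rep(1:10, each = 2), 2),
                     condition = rep(c("solo", "shared"), each = 20),
                     J = c(rnorm(20, 25), rnorm(20, 24)),
                     D_avatar = c(rep(NA, 20),
                                  qnorm(ppoints(20), 0.006, 0.002)))
  cfg0 <- sim_config(rating_link_slope = 0, rating_noise_sd = 0, seed = 1)
  set.seed(9)
  r0 <- generate_ratings(summ, cfg0)
  expect_true(all(r0$agency[r0$condition == "shared"] == cfg0$agency_shared_mean))
  expect_true(all(r0$ownership %in% -3:3))
  # strict monotone link: perfect rank correlation before Likert rounding
  cfg1 <- sim_config(rating_link_slope = 0.9, rating_noise_sd = 0, seed = 1)
  set.seed(9)
  r1 <- generate_ratings(summ, cfg1, round_likert = FALSE)
  sh <- r1[r1$condition == "shared", ]
  expect_equal(spearman(sh$ownership,
                        summ$D_avatar[summ$condition == "shared"])$statistic, 1)
  # recovered correlation under noise matches the noisy-monotone model
  cfg2 <- sim_config(seed = 1)  # slope 0.9, noise 0.8
  set.seed(10)
  rhos <- replicate(200, {
    r <- generate_ratings(summ, cfg2, round_likert = FALSE)
    shr <- r[r$condition == "shared", ]
    spearman(shr$ownership, summ$D_avatar[summ$condition == "shared"])$statistic
  })
  rho_pearson <- 0.9 / sqrt(0.9^2 + 0.8^2)
  rho_spearman <- (6 / pi) * asin(rho_pearson / 2)  # bivariate-normal conversion
  expect_equal(mean(rhos), rho_spearman, tolerance = 0.08)
  # missing condition for a participant
  expect_error(generate_ratings(summ[-1, ], cfg2),
               class = "sharedreach_invalid_argument")
  # ranges always respected
  exp <- tiny_experiment(seed = 17)
  expect_true(all(exp$ratings$agency >= 0 & exp$ratings$agency <= 100))
  expect_true(all(exp$ratings$ownership %in% -3:3))
})

test_that("averaging-only null: avatar D and J fall below the members", {
  exp <- generate_dyad_experiment(averaging_null_config(seed = 77))
  agg_h <- aggregate_metrics(exp$metrics, level = "dyad", actor = "human")
  agg_a <- aggregate_metrics(exp$metrics, level = "dyad", actor = "avatar")
  sh <- agg_h[agg_h$condition == "shared", ]
  expect_lt(mean(agg_a$D), mean(sh$D))
  expect_lt(mean(agg_a$J), mean(sh$J))
  # and solo behaviour equals shared behaviour distributionally: means close
  so <- agg_h[agg_h$condition == "solo", ]
  expect_equal(mean(sh$D), mean(so$D), tolerance = 0.1)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(dt = 0), class = "sharedreach_invalid_argument")
  expect_error(sim_config(strategy_gain = 1.2), class = "sharedreach_invalid_argument")
  expect_error(sim_config(te_inflation = 0.9), class = "sharedreach_invalid_argument")
  expect_error(sim_config(reach_duration_range = c(0.9, 0.6)),
               class = "sharedreach_invalid_argument")
  expect_error(sim_config(noise_sd = -1), class = "sharedreach_invalid_argument")
  expect_error(sim_config(agency_shared_mean = 45),
               class = "sharedreach_invalid_argument")
})
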