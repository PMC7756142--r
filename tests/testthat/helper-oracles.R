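# Independent oracles and small fixtures used across the suite.

# Brute-force exact two-sided p for the signed-rank statistic: enumerate all
# 2^m sign assignments of the observed |d| ranks (independent of psignrank).
brute_signrank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Repeated-measures one-way ANOVA through aov() + Error() as an independent
# route to the closed-form implementation.
aov_rm_oneway <- function(Y) {
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(nrow(Y)), ncol(Y))),
                   cond = factor(rep(seq_len(ncol(Y)), each = nrow(Y))))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"],
       df = c(tab["cond", "Df"], tab["Residuals", "Df"]))
}

# small, fast experiment for structural tests
tiny_experiment <- function(seed = 11, n_dyads = 2, trials = 3) {
  generate_dyad_experiment(sim_config(n_dyads = n_dyads,
                                      trials_per_session = trials,
                                      seed = seed))
}

# straight-line constant-speed trajectory helper
line_traj <- function(from, to, n, t0 = 0, dt = 0.01) {
  s <- seq(0, 1, length.out = n)
  trajectory(t0 + (seq_len(n) - 1) * dt,
             cbind(from[1] + (to[1] - from[1]) * s,
                   from[2] + (to[2] - from[2]) * s,
                   from[3] + (to[3] - from[3]) * s))
}
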