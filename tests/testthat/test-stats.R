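# The statistical battery's building blocks.

test_that("Shapiro-Wilk gate wrapper", {
  r <- shapiro_wilk(c(-1, 0, 1))
  expect_equal(r$statistic, 1, tolerance = 1e-6)
  expect_error(shapiro_wilk(rep(2, 10)), class = "sharedreach_degenerate_sample")
  expect_error(shapiro_wilk(c(1, 2)), class = "sharedreach_invalid_argument")
})

test_that("signed-rank statistic, zeros, and rank-biserial effect size", {
  # 19 positive nonzero differences among 20 pairs (one zero dropped):
  # W = 19 * 20 / 2 = 190, effect size +1
  x <- c(0, 1:19)
  r <- wilcoxon_signed_rank(x, mu = 0)
  expect_equal(r$statistic, 190)
  expect_equal(r$df, 19)
  expect_equal(r$effect_size, 1)
  expect_lt(r$p, 0.001)
  expect_equal(r$n_zero, 1L)
  # mirrored: all negative
  rneg <- wilcoxon_signed_rank(-x, mu = 0)
  expect_equal(rneg$statistic, 0)
  expect_equal(rneg$effect_size, -1)
  expect_lt(rneg$p, 0.001)
  # hand-enumerated small case: differences {+1, -2, +3}
  r3 <- wilcoxon_signed_rank(c(1, -2, 3), mu = 0)
  expect_equal(r3$statistic, 4)  # ranks 1 and 3 positive
  expect_equal(r3$effect_size, (4 - 2) / 6)
  expect_error(wilcoxon_signed_rank(rep(0, 5), mu = 0),
               class = "sharedreach_degenerate_sample")
})

test_that("exact signed-rank p equals full sign enumeration (m <= 12)", {
  set.seed(6)
  for (m in c(4, 7, 10, 12)) {
    d <- round(rnorm(m, 0.3), 3)
    d <- d[d != 0]
    r <- wilcoxon_signed_rank(d, mu = 0)
    expect_true(r$exact)
    expect_equal(r$p, brute_signrank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with stats::wilcox.test and obeys rank identities", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(r$statistic, unname(ref$statistic))
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    # W+ + W- = m(m+1)/2
    d <- x - y
    rk <- rank(abs(d))
    expect_equal(sum(rk[d > 0]) + sum(rk[d < 0]), n * (n + 1) / 2)
  }
  # ties route to the corrected normal approximation
  xt <- c(1, 1, 2, 2, 3, 3, 4, 4, -1, -2)
  rt <- wilcoxon_signed_rank(xt, mu = 0)
  expect_false(rt$exact)
  ref <- suppressWarnings(wilcox.test(xt, exact = FALSE, correct = TRUE))
  expect_equal(rt$p, ref$p.value, tolerance = 1e-12)
})

test_that("paired t and Cohen's d", {
  r <- paired_t(c(1, 2, 3), mu = 0)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$effect_size, 2)
  # antisymmetric differences give t = 0
  expect_equal(paired_t(c(-2, 2, -1, 1), mu = 0)$statistic, 0)
  expect_error(paired_t(c(3, 3, 3), mu = 1),
               class = "sharedreach_degenerate_sample")
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15)
  ref <- t.test(x, y, paired = TRUE)
  mine <- paired_t(x, y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("one-way repeated-measures ANOVA matches aov() and the eta identity", {
  set.seed(12)
  Y <- matrix(rnorm(30), 10, 3) + rnorm(10) + rep(c(0, 0.5, 1), each = 10)
  mine <- rm_anova_oneway(Y)
  ref <- aov_rm_oneway(Y)
  expect_equal(mine$statistic, ref$F, tolerance = 1e-10)
  expect_equal(mine$p, ref$p, tolerance = 1e-10)
  expect_equal(mine$df, ref$df)
  expect_equal(mine$df, c(2, 18))  # 3 conditions x 10 units
  expect_equal(mine$effect_size,
               partial_eta_sq(mine$statistic, 2, 18), tolerance = 1e-12)
  # identical columns: F = 0
  Y0 <- matrix(rnorm(10), 10, 3)
  z <- rm_anova_oneway(cbind(Y0[, 1], Y0[, 1], Y0[, 1]))
  expect_equal(z$statistic, 0)
  expect_equal(z$effect_size, 0)
  expect_error(rm_anova_oneway(rbind(Y, c(NA, 1, 2))),
               class = "sharedreach_incomplete_design")
})

test_that("partial eta squared reproduces the printed one-way triples", {
  expect_equal(partial_eta_sq(19.278, 2, 18), 0.682, tolerance = 0.001)
  expect_equal(partial_eta_sq(37.238, 2, 18), 0.805, tolerance = 0.001)
  expect_equal(partial_eta_sq(117.839, 2, 18), 0.929, tolerance = 0.001)
})

test_that("two-way repeated-measures ANOVA matches aov()", {
  set.seed(13)
  n <- 10
  d <- expand.grid(unit = factor(1:n), a = factor(1:2), b = factor(1:4))
  d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.4 + rnorm(n)[d$unit]
  mine <- rm_anova_twoway(d, factors = c("a", "b"))
  ref <- summary(aov(y ~ a * b + Error(unit / (a * b)), data = d))
  refA <- ref[["Error: unit:a"]][[1]]
  refB <- ref[["Error: unit:b"]][[1]]
  refAB <- ref[["Error: unit:a:b"]][[1]]
  expect_equal(mine$a$statistic, refA["a", "F value"], tolerance = 1e-10)
  expect_equal(mine$b$statistic, refB["b", "F value"], tolerance = 1e-10)
  expect_equal(mine[["a:b"]]$statistic, refAB["a:b", "F value"], tolerance = 1e-10)
  expect_equal(mine$a$df, c(1, 9))
  expect_equal(mine$b$df, c(3, 27))
  expect_error(rm_anova_twoway(d[-1, ], factors = c("a", "b")),
               class = "sharedreach_incomplete_design")
})

test_that("Mauchly's sphericity test matches stats::mauchly.test", {
  set.seed(5)
  Y <- matrix(rnorm(30), 10, 3) + rnorm(10)
  mine <- mauchly_sphericity(Y)
  ref <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(mauchly_sphericity(matrix(rnorm(20), 10, 2)),
               class = "sharedreach_invalid_argument")
  expect_error(mauchly_sphericity(matrix(rnorm(9), 3, 3)),
               class = "sharedreach_degenerate_sample")
})

test_that("Holm adjustment: hand case, bounds, monotonicity", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.02, 4)), rep(min(4 * 0.02, 1), 4))
  set.seed(3)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "sharedreach_invalid_argument")
})

test_that("ART alignment: rank completeness and removal of other effects", {
  # 2x2 within design, 6 units, pure main effect of A plus subject shifts
  d <- expand.grid(unit = factor(1:6), a = factor(1:2), b = factor(1:2))
  d$y <- 2 * (d$a == "2") + as.numeric(d$unit) / 10
  out <- art_transform(d, factors = c("a", "b"))
  N <- nrow(d)
  for (e in c("a", "b", "a:b")) {
    expect_equal(sum(out[[paste0("rank_", e)]]), N * (N + 1) / 2)
  }
  # aligned columns for effects other than A have equal cell means
  for (e in c("b", "a:b")) {
    al <- out[[paste0("aligned_", e)]]
    cm <- tapply(al, interaction(d$a, d$b), mean)
    expect_lt(diff(range(cm)), 1e-12)
  }
  # the aligned column for A reproduces the A effect pattern
  alA <- out$aligned_a
  cmA <- tapply(alA, d$a, mean)
  expect_equal(unname(cmA["2"] - cmA["1"]), 2, tolerance = 1e-12)
})

test_that("ART ranks match an independently coded reference on a fixed table", {
  set.seed(44)
  d <- expand.grid(unit = factor(1:6), a = factor(1:2), b = factor(1:2))
  d$y <- round(rnorm(nrow(d)), 2)
  out <- art_transform(d, factors = c("a", "b"))
  # reference: direct textbook formulas, coded independently of the package
  g <- mean(d$y)
  cell <- tapply(d$y, list(d$a, d$b), mean)
  ma <- tapply(d$y, d$a, mean); mb <- tapply(d$y, d$b, mean)
  resid <- d$y - cell[cbind(d$a, d$b)]
  ref_a <- rank(resid + (ma[d$a] - g))
  ref_b <- rank(resid + (mb[d$b] - g))
  ref_ab <- rank(resid + (cell[cbind(d$a, d$b)] - ma[d$a] - mb[d$b] + g))
  expect_equal(out$rank_a, ref_a, ignore_attr = TRUE)
  expect_equal(out$rank_b, ref_b, ignore_attr = TRUE)
  expect_equal(out[["rank_a:b"]], ref_ab, ignore_attr = TRUE)
})

test_that("ART ANOVA df bookkeeping and agreement with the parametric route", {
  set.seed(15)
  # one-way: 3 levels, 10 units -> df (2, 18)
  d1 <- expand.grid(unit = factor(1:10), level = factor(1:3))
  d1$y <- rnorm(30) + 2 * (d1$level == "3")
  fit1 <- art_rm_anova(d1, factors = "level")
  expect_equal(fit1$effects$level$df, c(2, 18))
  # one-way ART is rank ANOVA: F equals the parametric F on ranks of raw y
  Yr <- matrix(rank(d1$y)[order(d1$level, d1$unit)], 10, 3)
  expect_equal(fit1$effects$level$statistic, rm_anova_oneway(Yr)$statistic,
               tolerance = 1e-10)
  # two-way: 2 conditions x 4 sessions, 10 units -> session df (3, 27)
  d2 <- expand.grid(unit = factor(1:10), condition = factor(1:2),
                    session = factor(1:4))
  d2$y <- rnorm(80) + 0.8 * (d2$condition == "2")
  fit2 <- art_rm_anova(d2, factors = c("condition", "session"))
  expect_equal(fit2$effects$condition$df, c(1, 9))
  expect_equal(fit2$effects$session$df, c(3, 27))
  expect_equal(fit2$effects[["condition:session"]]$df, c(3, 27))
})

test_that("ART and parametric ANOVA agree under normal data with a large effect", {
  set.seed(16)
  agree <- replicate(500, {
    Y <- matrix(rnorm(30), 10, 3) + rnorm(10) +
      rep(c(0, 1.2, 2.4), each = 10)
    d <- data.frame(unit = factor(rep(1:10, 3)),
                    level = factor(rep(1:3, each = 10)), y = as.vector(Y))
    p_art <- art_rm_anova(d, factors = "level")$effects$level$p
    p_par <- rm_anova_oneway(Y)$p
    (p_art < 0.05) == (p_par < 0.05)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("Tukey post hoc on aligned ranks", {
  set.seed(17)
  d <- expand.grid(unit = factor(1:10), level = factor(c("s", "h", "a")))
  d$y <- rnorm(30) + 3 * (d$level == "a")
  fit <- art_rm_anova(d, factors = "level")
  ph <- tukey_posthoc(fit)
  expect_equal(nrow(ph$contrasts), 3L)  # k = 3 -> 3 pairwise contrasts
  expect_true(all(ph$contrasts$p_adj >= ph$contrasts$p_raw - 1e-12))
  expect_equal(ph$contrasts$df, rep(18, 3))
  # contrasts involving the shifted level are significant, the other is not
  lab <- ph$contrasts$contrast
  expect_true(all(ph$contrasts$p_adj[grepl("a", lab)] < 0.05))
  # two identical levels give adjusted p near 1
  d2 <- d
  d2$y <- rnorm(30) + 5 * (d2$level == "a")
  d2$y[d2$level == "h"] <- d2$y[d2$level == "s"] + rnorm(10, 0, 1e-3)
  ph2 <- tukey_posthoc(art_rm_anova(d2, factors = "level"))
  expect_gt(ph2$contrasts$p_adj[ph2$contrasts$contrast == "h - s"], 0.8)
})

test_that("Tukey familywise error stays near alpha under the null", {
  set.seed(18)
  fwe <- replicate(800, {
    d <- data.frame(unit = factor(rep(1:10, 3)),
                    level = factor(rep(1:3, each = 10)),
                    y = rnorm(30) + rnorm(10))
    ph <- tukey_posthoc(art_rm_anova(d, factors = "level"))
    any(ph$contrasts$p_adj < 0.05)
  })
  # alpha + 3 MC standard errors
  expect_lte(mean(fwe), 0.05 + 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("Spearman correlation: hand ranks and exact small-n p", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10))$statistic, -1)
  r <- spearman(c(1, 2, 3, 4), c(10, 30, 20, 40))
  expect_equal(r$statistic, 0.8)
  ref <- cor.test(c(1, 2, 3, 4), c(10, 30, 20, 40), method = "spearman",
                  exact = TRUE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), class = "sharedreach_degenerate_sample")
  set.seed(19)
  x <- rnorm(25); y <- x + rnorm(25)
  big <- spearman(x, y)
  reft <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(big$statistic, unname(reft$estimate), tolerance = 1e-12)
  expect_equal(big$p, reft$p.value, tolerance = 1e-6)
})

test_that("posthoc holm table wraps pairwise paired t tests", {
  set.seed(20)
  Y <- cbind(s = rnorm(10, 1), h = rnorm(10, 0.5), a = rnorm(10))
  ph <- holm_posthoc(Y)
  expect_equal(nrow(ph$contrasts), 3L)
  expect_equal(ph$adjustment, "holm")
  r <- paired_t(Y[, "s"], Y[, "h"])
  row <- ph$contrasts[ph$contrasts$contrast == "s - h", ]
  expect_equal(row$statistic, r$statistic)
  expect_equal(ph$contrasts$p_adj, holm_adjust(ph$contrasts$p_raw))
})
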