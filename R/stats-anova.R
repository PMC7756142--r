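# Repeated-measures ANOVA machinery: closed-form one- and two-way
# within-subject F tests, Mauchly's sphericity test, the aligned rank
# transform (ART) for non-normal data, and Holm / Tukey post hoc tables.

as_rm_matrix <- function(values) {
  Y <- as.matrix(values)
  if (!is.numeric(Y)) stop_invalid("values must be numeric")
  if (anyNA(Y)) stop_incomplete("missing cells in repeated-measures table")
  Y
}

#' One-way repeated-measures ANOVA
#'
#' Balanced within-subject one-way ANOVA on a units-by-levels table:
#' F with df (k-1, (k-1)(n-1)) against the level-by-subject interaction, and
#' partial eta squared
#' \eqn{\eta_p^2 = SS_{effect}/(SS_{effect}+SS_{error})
#'   \equiv F\,df_1/(F\,df_1 + df_2)}.
#'
#' @param values numeric matrix or data frame, one row per unit (dyad or
#'   participant), one column per level; complete and balanced.
#' @return \code{stat_result} with extra fields \code{ss_effect},
#'   \code{ss_error}.
#' @export
rm_anova_oneway <- function(values) {
  Y <- as_rm_matrix(values)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) stop_invalid("need at least 2 units and 2 levels")
  g <- mean(Y)
  col_m <- colMeans(Y); row_m <- rowMeans(Y)
  ss_eff <- n * sum((col_m - g)^2)
  ss_subj <- k * sum((row_m - g)^2)
  ss_tot <- sum((Y - g)^2)
  ss_err <- ss_tot - ss_eff - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- if (ss_eff <= 0) 0 else (ss_eff / df1) / (ss_err / df2)
  eta <- if (ss_eff <= 0) 0 else ss_eff / (ss_eff + ss_err)
  stat_result("rm_anova_oneway", Fv, c(df1, df2),
              stats::pf(Fv, df1, df2, lower.tail = FALSE),
              effect_size = eta, effect_size_type = "partial_eta_sq",
              ss_effect = ss_eff, ss_error = ss_err, n = n, k = k)
}

#' Partial eta squared from F and its degrees of freedom
#'
#' \eqn{\eta_p^2 = F\,df_1 / (F\,df_1 + df_2)}; algebraically identical to
#' \eqn{SS_{effect}/(SS_{effect}+SS_{error})} for the balanced
#' repeated-measures F ratio.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared in [0, 1].
#' @export
partial_eta_sq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Two-way repeated-measures ANOVA (both factors within)
#'
#' Balanced complete two-way within-subject design; each effect is tested
#' against its own interaction with subjects (F_A = MS_A / MS_{A x S}, etc.).
#'
#' @param data data frame with columns \code{unit}, the two factor columns
#'   and \code{y}.
#' @param factors character vector naming the two within factors.
#' @param y name of the response column (default \code{"y"}).
#' @param unit name of the unit column (default \code{"unit"}).
#' @return named list of three \code{stat_result}s: the two main effects and
#'   the interaction (\code{"A:B"} keyed by the factor names).
#' @export
rm_anova_twoway <- function(data, factors, y = "y", unit = "unit") {
  if (length(factors) != 2L) stop_invalid("'factors' must name two columns")
  need <- c(unit, factors, y)
  if (!all(need %in% names(data))) stop_invalid("missing columns in 'data'")
  u <- factor(data[[unit]]); A <- factor(data[[factors[1]]])
  B <- factor(data[[factors[2]]]); v <- as.numeric(data[[y]])
  if (anyNA(v)) stop_incomplete("missing response values")
  tab <- table(u, A, B)
  if (any(tab != 1L)) stop_incomplete("design is not complete and balanced (one observation per unit x cell)")
  n <- nlevels(u); ka <- nlevels(A); kb <- nlevels(B)
  g <- mean(v)
  m_a <- tapply(v, A, mean); m_b <- tapply(v, B, mean)
  m_ab <- tapply(v, list(A, B), mean)
  m_s <- tapply(v, u, mean)
  m_sa <- tapply(v, list(u, A), mean); m_sb <- tapply(v, list(u, B), mean)
  ss_a <- n * kb * sum((m_a - g)^2)
  ss_b <- n * ka * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, kb)) -
                      outer(rep(1, ka), m_b) + g)^2)
  ss_s <- ka * kb * sum((m_s - g)^2)
  ss_sa <- kb * sum((m_sa - outer(m_s, rep(1, ka)) -
                       outer(rep(1, n), m_a) + g)^2)
  ss_sb <- ka * sum((m_sb - outer(m_s, rep(1, kb)) -
                       outer(rep(1, n), m_b) + g)^2)
  ss_tot <- sum((v - g)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  mk <- function(name, ss_e, df1, ss_r, df2) {
    Fv <- if (ss_e <= 0) 0 else (ss_e / df1) / (ss_r / df2)
    eta <- if (ss_e <= 0) 0 else ss_e / (ss_e + ss_r)
    stat_result(name, Fv, c(df1, df2),
                stats::pf(Fv, df1, df2, lower.tail = FALSE),
                effect_size = eta, effect_size_type = "partial_eta_sq",
                ss_effect = ss_e, ss_error = ss_r, n = n)
  }
  res <- list(
    mk(factors[1], ss_a, ka - 1, ss_sa, (ka - 1) * (n - 1)),
    mk(factors[2], ss_b, kb - 1, ss_sb, (kb - 1) * (n - 1)),
    mk(paste(factors, collapse = ":"), ss_ab, (ka - 1) * (kb - 1),
       ss_sab, (ka - 1) * (kb - 1) * (n - 1)))
  names(res) <- c(factors, paste(factors, collapse = ":"))
  res
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of the within-subject covariance on k >= 3 levels via the
#' Mauchly W statistic on orthonormalised contrasts with the standard
#' chi-square approximation.
#'
#' @param values units-by-levels numeric matrix, n > k rows.
#' @return \code{stat_result} with W as statistic and chi-square df.
#' @export
mauchly_sphericity <- function(values) {
  Y <- as_rm_matrix(values)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 3L) stop_invalid("Mauchly's test needs at least 3 levels")
  if (n <= k) stop_degenerate("need more units than levels")
  p <- k - 1
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")     # orthonormal contrasts
  M <- t(C) %*% stats::cov(Y) %*% C
  dM <- det(M)
  if (!is.finite(dM) || dM <= 0) stop_degenerate("singular within-subject covariance")
  W <- dM / (sum(diag(M)) / p)^p
  dd <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * dd * log(W)
  df <- p * (p + 1) / 2 - 1
  stat_result("mauchly_sphericity", W, df,
              stats::pchisq(chi2, df, lower.tail = FALSE),
              chi_sq = chi2, n = n, k = k)
}

#' Aligned rank transform (ART)
#'
#' For each requested effect in a complete balanced factorial, the response
#' is aligned by stripping every other effect -- aligned value = (raw - cell
#' mean) + estimated effect of interest, with cells defined by the full
#' crossing of the fixed factors -- and the aligned column is then ranked as
#' a whole (average ranks on ties).  ANOVA on these ranks gives a
#' non-parametric factorial test.
#'
#' @param data long data frame with columns \code{unit}, the factor
#'   column(s), and \code{y}.
#' @param factors character vector of 1 or 2 factor column names.
#' @param effect which effect to align for: one factor name or
#'   \code{"A:B"}; default is all effects.
#' @param y,unit column names.
#' @return \code{data} with one extra pair of columns per effect:
#'   \code{aligned_<effect>} and \code{rank_<effect>}.
#' @export
art_transform <- function(data, factors, effect = NULL, y = "y", unit = "unit") {
  if (!length(factors) %in% 1:2) stop_invalid("'factors' must name 1 or 2 columns")
  need <- c(unit, factors, y)
  if (!all(need %in% names(data))) stop_invalid("missing columns in 'data'")
  v <- as.numeric(data[[y]])
  if (anyNA(v)) stop_incomplete("missing response values")
  fs <- lapply(factors, function(f) factor(data[[f]]))
  names(fs) <- factors
  u <- factor(data[[unit]])
  tab <- table(do.call(interaction, c(list(u), fs)))
  if (any(tab != 1L)) stop_incomplete("design is not complete and balanced")
  g <- mean(v)
  cell <- if (length(fs) == 1L) fs[[1]] else interaction(fs[[1]], fs[[2]])
  cell_m <- stats::ave(v, cell)
  effects <- if (length(fs) == 1L) factors
             else c(factors, paste(factors, collapse = ":"))
  if (!is.null(effect)) {
    if (!all(effect %in% effects)) stop_invalid("unknown effect")
    effects <- effect
  }
  for (e in effects) {
    est <- if (e %in% factors) {
      stats::ave(v, fs[[e]]) - g
    } else {
      m_a <- stats::ave(v, fs[[1]]); m_b <- stats::ave(v, fs[[2]])
      cell_m - m_a - m_b + g
    }
    aligned <- (v - cell_m) + est
    data[[paste0("aligned_", e)]] <- aligned
    data[[paste0("rank_", e)]] <- rank(aligned)
  }
  data
}

#' Repeated-measures ANOVA with the aligned rank transform
#'
#' Runs, for each effect of a 1- or 2-factor within-subject design, the
#' corresponding repeated-measures F test on that effect's aligned ranks
#' (see \code{\link{art_transform}}).  Partial eta squared is computed from
#' the aligned-rank sums of squares.
#'
#' @inheritParams art_transform
#' @return object of class \code{art_anova}: list with \code{effects} (named
#'   list of \code{stat_result}), the transformed \code{data}, and design
#'   metadata; feed to \code{\link{tukey_posthoc}} for all-pairs contrasts.
#' @export
art_rm_anova <- function(data, factors, y = "y", unit = "unit") {
  data <- art_transform(data, factors, y = y, unit = unit)
  u <- factor(data[[unit]])
  res <- list()
  if (length(factors) == 1L) {
    f <- factors[1]
    Y <- rank_matrix(data[[paste0("rank_", f)]], u, factor(data[[f]]))
    r <- rm_anova_oneway(Y)
    r$test_name <- paste0("art_rm_anova[", f, "]")
    res[[f]] <- r
  } else {
    for (e in c(factors, paste(factors, collapse = ":"))) {
      two <- rm_anova_twoway(
        data.frame(unit = u, a = data[[factors[1]]], b = data[[factors[2]]],
                   y = data[[paste0("rank_", e)]]),
        factors = c("a", "b"))
      names(two) <- c(factors, paste(factors, collapse = ":"))
      r <- two[[e]]
      r$test_name <- paste0("art_rm_anova[", e, "]")
      res[[e]] <- r
    }
  }
  structure(list(effects = res, data = data, factors = factors,
                 y = y, unit = unit), class = "art_anova")
}

rank_matrix <- function(r, u, f) {
  Y <- tapply(r, list(u, f), function(z) z[1])
  as_rm_matrix(Y)
}

#' @export
print.art_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA with aligned rank transform\n")
  for (r in x$effects) print(r)
  invisible(x)
}

#' Post hoc contrast table
#'
#' @param contrasts data frame with columns \code{contrast},
#'   \code{statistic}, \code{df}, \code{p_raw}, \code{p_adj},
#'   \code{effect_size}.
#' @param adjustment \code{"holm"} or \code{"tukey"}.
#' @return object of class \code{posthoc_table}.
#' @export
posthoc_table <- function(contrasts, adjustment = c("holm", "tukey")) {
  adjustment <- match.arg(adjustment)
  structure(list(contrasts = contrasts, adjustment = adjustment),
            class = "posthoc_table")
}

#' @export
print.posthoc_table <- function(x, ...) {
  cat(sprintf("Post hoc contrasts (%s adjustment):\n", x$adjustment))
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey all-pairs post hoc contrasts on aligned ranks
#'
#' All pairwise level contrasts of one effect of a fitted
#' \code{\link{art_rm_anova}} model, using the studentized-range (Tukey)
#' adjustment.  The error term is the effect-by-subject interaction mean
#' square of the aligned ranks with classical balanced-design degrees of
#' freedom (k-1)(n-1); in balanced compound-symmetric designs these coincide
#' with the Kenward-Roger approximate df, which is not reimplemented here
#' (the substitution is noted in reports).
#'
#' @param model an \code{art_anova} fit.
#' @param effect effect name (default: the single factor).
#' @return \code{\link{posthoc_table}} with t statistics
#'   (\eqn{t = q/\sqrt 2}) and Tukey-adjusted p values; the effect size is
#'   the level-mean difference of aligned ranks over the root error mean
#'   square.
#' @export
tukey_posthoc <- function(model, effect = NULL) {
  if (!inherits(model, "art_anova")) stop_invalid("'model' must be an art_anova fit")
  if (is.null(effect)) {
    if (length(model$factors) != 1L) stop_invalid("specify 'effect' for two-way fits")
    effect <- model$factors[1]
  }
  if (!effect %in% model$factors)
    stop_invalid("post hoc contrasts are defined for main effects")
  f <- factor(model$data[[effect]])
  k <- nlevels(f)
  if (k < 2L) stop_invalid("need at least 2 levels")
  u <- factor(model$data[[model$unit]])
  r <- model$data[[paste0("rank_", effect)]]
  # collapse over the other factor, if any, to the unit x level means
  Y <- tapply(r, list(u, f), mean)
  Y <- as_rm_matrix(Y)
  n <- nrow(Y)
  g <- mean(Y)
  ss_eff <- n * sum((colMeans(Y) - g)^2)
  ss_subj <- k * sum((rowMeans(Y) - g)^2)
  ss_err <- sum((Y - g)^2) - ss_eff - ss_subj
  df2 <- (k - 1) * (n - 1)
  mse <- ss_err / df2
  m <- colMeans(Y)
  pairs <- utils::combn(levels(f), 2)
  rows <- apply(pairs, 2, function(pr) {
    dmean <- m[pr[1]] - m[pr[2]]
    se <- sqrt(2 * mse / n)
    tval <- dmean / se
    q <- abs(tval) * sqrt(2)
    data.frame(contrast = paste(pr[1], "-", pr[2]),
               statistic = tval, df = df2,
               p_raw = 2 * stats::pt(-abs(tval), df2),
               p_adj = stats::ptukey(q, k, df2, lower.tail = FALSE),
               effect_size = dmean / sqrt(mse))
  })
  posthoc_table(do.call(rbind, rows), "tukey")
}

#' Holm-adjusted pairwise paired-t post hoc contrasts
#'
#' All pairwise paired t tests between the columns of a units-by-levels
#' table, with step-down Holm adjustment; the parametric post hoc used after
#' a significant one-way repeated-measures ANOVA.
#'
#' @param values units-by-levels numeric matrix or data frame.
#' @param d_type Cohen's d convention, passed to \code{\link{paired_t}}.
#' @return \code{\link{posthoc_table}}.
#' @export
holm_posthoc <- function(values, d_type = "dz") {
  Y <- as_rm_matrix(values)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("L", seq_len(ncol(Y)))
  pairs <- utils::combn(colnames(Y), 2)
  rows <- apply(pairs, 2, function(pr) {
    r <- paired_t(Y[, pr[1]], Y[, pr[2]], d_type = d_type)
    data.frame(contrast = paste(pr[1], "-", pr[2]),
               statistic = r$statistic, df = r$df, p_raw = r$p,
               effect_size = r$effect_size)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- holm_adjust(tab$p_raw)
  posthoc_table(tab[c("contrast", "statistic", "df", "p_raw", "p_adj",
                      "effect_size")], "holm")
}
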