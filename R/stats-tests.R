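# Univariate tests of the battery: normality gate, signed-rank with
# rank-biserial effect size, paired t, Spearman correlation, Holm adjustment.

#' Statistical test result container
#'
#' @param test_name character label.
#' @param statistic test statistic.
#' @param df degrees of freedom (length 1 or 2); may be NA.
#' @param p two-sided p value.
#' @param effect_size effect size value (may be NA).
#' @param effect_size_type one of \code{"rank_biserial"},
#'   \code{"cohen_d_paired"}, \code{"partial_eta_sq"}, \code{"spearman_rho"},
#'   or NA.
#' @param ... extra named fields stored alongside (e.g. \code{exact},
#'   \code{n}).
#' @return object of class \code{stat_result}.
#' @export
stat_result <- function(test_name, statistic, df, p, effect_size = NA_real_,
                        effect_size_type = NA_character_, ...) {
  if (!is.na(p) && (p < 0 || p > 1)) stop_invalid("p outside [0, 1]")
  structure(c(list(test_name = test_name, statistic = as.numeric(statistic),
                   df = as.numeric(df), p = as.numeric(p),
                   effect_size = as.numeric(effect_size),
                   effect_size_type = effect_size_type), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  es <- if (is.na(x$effect_size)) "" else
    sprintf(", %s = %.3f", switch(x$effect_size_type,
                                  rank_biserial = "d(rb)",
                                  cohen_d_paired = "d",
                                  partial_eta_sq = "eta_p^2",
                                  spearman_rho = "rho",
                                  "es"), x$effect_size)
  cat(sprintf("%s: stat = %.3f, df = (%s), p = %s%s\n", x$test_name,
              x$statistic, dfs, format.pval(x$p, digits = 3), es))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around \code{stats::shapiro.test} returning a
#' \code{\link{stat_result}}; used as the parametric/non-parametric gate of
#' the battery (non-parametric branch taken when p < alpha).
#'
#' @param x numeric sample, 3 to 5000 values.
#' @return \code{stat_result} with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    stop_invalid("shapiro_wilk needs between 3 and 5000 observations")
  if (stats::sd(x) == 0) stop_degenerate("sample is constant")
  sw <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", sw$statistic, NA_real_, sw$p.value, n = length(x))
}

#' Wilcoxon signed-rank test with matched-pairs rank-biserial effect size
#'
#' Paired (\code{x} vs \code{y}) or one-sample (\code{x} vs \code{mu}) form.
#' Zero differences are dropped before ranking; ties in \code{|d|} receive
#' average ranks.  The statistic is \eqn{W^+}, the sum of ranks of positive
#' differences (so 19 positive differences among 20 pairs with one zero give
#' \eqn{W = 190}).  The two-sided p value is exact (full enumeration of the
#' \eqn{2^m} sign assignments, evaluated through the signed-rank null
#' distribution) for m <= 25 untied differences, and a tie-corrected normal
#' approximation with continuity correction otherwise.  The effect size is
#' the matched-pairs rank-biserial correlation
#' \eqn{(W^+ - W^-)/(W^+ + W^-)}, which is +1/-1 when all nonzero
#' differences share one sign.
#'
#' @param x numeric sample.
#' @param y optional paired sample.
#' @param mu null value for the one-sample form (default 0).
#' @return \code{stat_result}; \code{df} is the number m of nonzero
#'   differences, extra fields \code{exact} and \code{n_zero}.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0) {
  d <- if (!is.null(y)) {
    if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
    as.numeric(x) - as.numeric(y)
  } else as.numeric(x) - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop_degenerate("all paired differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- !ties && m <= 25L
  if (exact) {
    p <- 2 * min(stats::psignrank(w_pos, m),
                 stats::psignrank(w_pos - 1, m, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu_w <- m * (m + 1) / 4
    tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (w_pos - mu_w - 0.5 * sign(w_pos - mu_w)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  stat_result("wilcoxon_signed_rank", w_pos, m, p,
              effect_size = (w_pos - w_neg) / (w_pos + w_neg),
              effect_size_type = "rank_biserial",
              exact = exact, n_zero = n_zero)
}

#' Paired (or one-sample) t test with Cohen's d
#'
#' \eqn{t = \bar d / (s_d/\sqrt n)} on the paired differences, df = n - 1.
#' The default effect size is \eqn{d_z = \bar d / s_d}; \code{d_type = "av"}
#' uses the average-variance convention
#' \eqn{\bar d / ((s_x + s_y)/2)} (conventions differ across papers and the
#' choice is configurable).
#'
#' @param x numeric sample.
#' @param y optional paired sample.
#' @param mu null value for the one-sample form.
#' @param d_type \code{"dz"} (default) or \code{"av"}.
#' @return \code{stat_result}.
#' @export
paired_t <- function(x, y = NULL, mu = 0, d_type = c("dz", "av")) {
  d_type <- match.arg(d_type)
  d <- if (!is.null(y)) {
    if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
    as.numeric(x) - as.numeric(y)
  } else as.numeric(x) - mu
  n <- length(d)
  if (n < 2L) stop_invalid("paired_t needs at least 2 pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop_degenerate("paired differences have zero variance")
  tval <- mean(d) / (sd_d / sqrt(n))
  es <- if (d_type == "av" && !is.null(y))
    mean(d) / ((stats::sd(x) + stats::sd(y)) / 2) else mean(d) / sd_d
  stat_result("paired_t", tval, n - 1, 2 * stats::pt(-abs(tval), n - 1),
              effect_size = es, effect_size_type = "cohen_d_paired", n = n)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of average-ranked data; exact p for n <= 9 without
#' ties, t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return \code{stat_result} with rho as both statistic and effect size.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop_invalid("spearman needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("constant input to spearman")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  stat_result("spearman", rho, n - 2, p, effect_size = rho,
              effect_size_type = "spearman_rho", n = n)
}

#' Holm step-down p-value adjustment
#'
#' Step-down Holm procedure with monotonicity enforcement (delegates to
#' \code{stats::p.adjust}).  Adjusted values are never below the raw values
#' and are monotone in raw-p order.
#'
#' @param pvalues numeric vector of p values in [0, 1].
#' @return adjusted p values in the input order.
#' @export
holm_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_invalid("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
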