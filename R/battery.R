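# The full statistical battery: for each analysis a Shapiro-Wilk gate at
# alpha routes to the parametric branch (paired t / repeated-measures ANOVA
# with Holm post hoc) or the rank-based branch (Wilcoxon signed-rank /
# ANOVA with aligned rank transform and Tukey post hoc), mirroring the
# figure-by-figure analyses of shared-avatar reaching studies.
# Kinematic analyses use dyads as units, rating analyses use participants.

metric_wide <- function(agg_h, agg_a, metric) {
  solo <- agg_h[agg_h$condition == "solo", ]
  shared <- agg_h[agg_h$condition == "shared", ]
  shared <- shared[match(solo$dyad_id, shared$dyad_id), ]
  av <- agg_a[match(solo$dyad_id, agg_a$dyad_id), ]
  m <- cbind(solo_human = solo[[metric]], shared_human = shared[[metric]],
             shared_avatar = av[[metric]])
  rownames(m) <- paste0("dyad", solo$dyad_id)
  m
}

gate_normality <- function(cols, alpha) {
  sw <- lapply(asplit(cols, 2), shapiro_wilk)
  names(sw) <- colnames(cols)
  list(tests = sw,
       parametric = all(vapply(sw, function(r) r$p, numeric(1)) >= alpha))
}

paired_analysis <- function(x, y = NULL, mu = 0, alpha = 0.05, d_type = "dz",
                            label = "") {
  d <- if (!is.null(y)) x - y else x - mu
  gate <- shapiro_wilk(d)
  if (gate$p < alpha) {
    res <- wilcoxon_signed_rank(x, y, mu)
    branch <- "wilcoxon"
  } else {
    res <- paired_t(x, y, mu, d_type = d_type)
    branch <- "t"
  }
  list(label = label, gate = gate, branch = branch, result = res)
}

oneway_analysis <- function(wide, alpha = 0.05, d_type = "dz", label = "") {
  gate <- gate_normality(wide, alpha)
  if (gate$parametric) {
    sph <- mauchly_sphericity(wide)
    res <- rm_anova_oneway(wide)
    ph <- holm_posthoc(wide, d_type = d_type)
    list(label = label, gate = gate, branch = "parametric", sphericity = sph,
         anova = res, posthoc = ph)
  } else {
    long <- data.frame(unit = rep(rownames(wide), ncol(wide)),
                       level = rep(colnames(wide), each = nrow(wide)),
                       y = as.vector(wide))
    fit <- art_rm_anova(long, factors = "level")
    list(label = label, gate = gate, branch = "art",
         anova = fit$effects[["level"]], posthoc = tukey_posthoc(fit))
  }
}

#' Run the complete statistical battery
#'
#' Reproduces the study's analysis plan on an experiment's metrics and
#' ratings: agency and ownership condition contrasts (plus agency vs the
#' actual 100\%/50\% control weights), one-way repeated-measures analyses of
#' reach deviation, mean jerk and target error across (solo human, shared
#' human, shared avatar), task-time and reaction-time contrasts between solo
#' human and shared avatar, inter-participant distance overall and per
#' phase, the two-way condition-by-session IP analysis, and the two rank
#' correlations linking embodiment to kinematics (ownership vs avatar D;
#' agency change vs jerk change).  Every analysis is routed through a
#' Shapiro-Wilk gate at \code{alpha}.
#'
#' @param metrics a \code{\link{compute_metrics}} result.
#' @param ratings rating data frame (see \code{\link{generate_ratings}}).
#' @param alpha gate level for normality routing (default 0.05).
#' @param d_type Cohen's d convention for t tests.
#' @return object of class \code{reach_battery}: named list of analyses
#'   (keys \code{agency}, \code{ownership}, \code{deviation}, \code{jerk},
#'   \code{task_time}, \code{reaction_time}, \code{target_error}, \code{ip},
#'   \code{ip_phases}, \code{ip_sessions}, \code{corr_ownership_D},
#'   \code{corr_agency_J}).
#' @export
run_test_battery <- function(metrics, ratings, alpha = 0.05, d_type = "dz") {
  if (!inherits(metrics, "reach_metrics"))
    stop_invalid("'metrics' must be a compute_metrics() result")
  agg_h <- aggregate_metrics(metrics, level = "dyad", actor = "human")
  agg_a <- aggregate_metrics(metrics, level = "dyad", actor = "avatar")
  b <- list()

  # --- ratings (participant-level units) ---------------------------------
  rs <- ratings[ratings$condition == "solo", ]
  rh <- ratings[ratings$condition == "shared", ]
  rh <- rh[match(rs$participant_id, rh$participant_id), ]
  ag <- paired_analysis(rs$agency, rh$agency, alpha = alpha, d_type = d_type,
                        label = "sense of agency: solo vs shared")
  ag$vs_weights <- list(
    solo_vs_100 = with_branch(rs$agency, mu = 100, branch = ag$branch,
                              d_type = d_type),
    shared_vs_50 = with_branch(rh$agency, mu = 50, branch = ag$branch,
                               d_type = d_type))
  b$agency <- ag
  b$ownership <- paired_analysis(rs$ownership, rh$ownership, alpha = alpha,
                                 d_type = d_type,
                                 label = "sense of ownership: solo vs shared")

  # --- kinematics (dyad-level units) -------------------------------------
  b$deviation <- oneway_analysis(metric_wide(agg_h, agg_a, "D"), alpha, d_type,
                                 "reach deviation D")
  b$jerk <- oneway_analysis(metric_wide(agg_h, agg_a, "J"), alpha, d_type,
                            "mean hand jerk J")
  b$target_error <- oneway_analysis(metric_wide(agg_h, agg_a, "TE"), alpha,
                                    d_type, "target error TE")
  tt <- metric_wide(agg_h, agg_a, "TT")
  b$task_time <- paired_analysis(tt[, "solo_human"], tt[, "shared_avatar"],
                                 alpha = alpha, d_type = d_type,
                                 label = "task time: solo human vs shared avatar")
  rt <- metric_wide(agg_h, agg_a, "RT")
  b$reaction_time <- paired_analysis(rt[, "solo_human"], rt[, "shared_avatar"],
                                     alpha = alpha, d_type = d_type,
                                     label = "reaction time: solo human vs shared avatar")

  # --- inter-participant distance ----------------------------------------
  ipd <- aggregate_ip(metrics)
  ips <- ipd[ipd$condition == "solo", ]
  iph <- ipd[ipd$condition == "shared", ]
  iph <- iph[match(ips$dyad_id, iph$dyad_id), ]
  b$ip <- paired_analysis(iph$overall, ips$overall, alpha = alpha,
                          d_type = d_type,
                          label = "inter-participant distance: shared vs solo")
  b$ip_phases <- lapply(1:3, function(k) {
    paired_analysis(iph[[paste0("phase", k)]], ips[[paste0("phase", k)]],
                    alpha = alpha, d_type = d_type,
                    label = sprintf("IP phase %d: shared vs solo", k))
  })
  ipse <- aggregate_ip(metrics, by_session = TRUE)
  cells <- split(ipse$overall, interaction(ipse$condition, ipse$session))
  cell_p <- vapply(cells, function(v) shapiro_wilk(v)$p, numeric(1))
  long <- data.frame(unit = paste0("dyad", ipse$dyad_id),
                     condition = ipse$condition,
                     session = factor(ipse$session), y = ipse$overall)
  if (any(cell_p < alpha)) {
    fit <- art_rm_anova(long, factors = c("condition", "session"))
    b$ip_sessions <- list(label = "IP: condition x session", branch = "art",
                          gate_p = cell_p, effects = fit$effects)
  } else {
    b$ip_sessions <- list(label = "IP: condition x session",
                          branch = "parametric", gate_p = cell_p,
                          effects = rm_anova_twoway(long,
                                                    c("condition", "session")))
  }

  # --- embodiment-kinematics correlations (participants) ------------------
  pa <- aggregate_metrics(metrics, level = "participant", actor = "human")
  d_av <- agg_a$D[match(rh$dyad_id, agg_a$dyad_id)]
  b$corr_ownership_D <- list(
    label = "ownership (shared) vs avatar reach deviation",
    result = spearman(rh$ownership, d_av))
  pj_s <- pa[pa$condition == "solo", ]
  pj_h <- pa[pa$condition == "shared", ]
  pj_h <- pj_h[match(pj_s$participant_id, pj_h$participant_id), ]
  dj <- pj_h$J[match(rs$participant_id, pj_h$participant_id)] -
    pj_s$J[match(rs$participant_id, pj_s$participant_id)]
  b$corr_agency_J <- list(
    label = "agency change (shared - solo) vs jerk change",
    result = spearman(rh$agency - rs$agency, dj))

  structure(list(analyses = b, alpha = alpha, d_type = d_type,
                 n_dyads = nrow(tt), n_participants = nrow(rs)),
            class = "reach_battery")
}

with_branch <- function(x, mu, branch, d_type) {
  if (branch == "wilcoxon") wilcoxon_signed_rank(x, mu = mu)
  else paired_t(x, mu = mu, d_type = d_type)
}

#' @export
print.reach_battery <- function(x, ...) {
  cat(sprintf("Shared-avatar reaching battery (%d dyads, %d participants, gate alpha = %g)\n",
              x$n_dyads, x$n_participants, x$alpha))
  cat("Note: post hoc df are classical balanced-design df (Kenward-Roger not applied).\n")
  a <- x$analyses
  pr1 <- function(an) {
    cat(sprintf("\n-- %s [branch: %s]\n", an$label, an$branch))
    print(an$result)
    if (!is.null(an$vs_weights)) {
      cat("   solo vs 100%: "); print(an$vs_weights$solo_vs_100)
      cat("   shared vs 50%: "); print(an$vs_weights$shared_vs_50)
    }
  }
  pr_ow <- function(an) {
    cat(sprintf("\n-- %s [branch: %s]\n", an$label, an$branch))
    if (!is.null(an$sphericity)) print(an$sphericity)
    print(an$anova)
    print(an$posthoc)
  }
  pr1(a$agency); pr1(a$ownership)
  pr_ow(a$deviation); pr_ow(a$jerk); pr_ow(a$target_error)
  pr1(a$task_time); pr1(a$reaction_time); pr1(a$ip)
  for (ph in a$ip_phases) pr1(ph)
  cat(sprintf("\n-- %s [branch: %s]\n", a$ip_sessions$label, a$ip_sessions$branch))
  for (r in a$ip_sessions$effects) print(r)
  cat(sprintf("\n-- %s\n", a$corr_ownership_D$label))
  print(a$corr_ownership_D$result)
  cat(sprintf("\n-- %s\n", a$corr_agency_J$label))
  print(a$corr_agency_J$result)
  invisible(x)
}

#' Tidy data frame of battery results
#'
#' @param object a \code{reach_battery}.
#' @param ... unused.
#' @return data frame with one row per test: analysis, branch, test, df,
#'   statistic, p, effect size (type), adjustment.
#' @export
summary.reach_battery <- function(object, ...) {
  rows <- list()
  add <- function(analysis, branch, r, adjustment = "none", contrast = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, contrast = as.character(contrast), branch = branch,
      test = r$test_name, statistic = r$statistic,
      df1 = r$df[1], df2 = if (length(r$df) > 1) r$df[2] else NA_real_,
      p = r$p, effect_size = r$effect_size,
      effect_size_type = as.character(r$effect_size_type),
      adjustment = adjustment)
  }
  add_ph <- function(analysis, branch, ph) {
    for (i in seq_len(nrow(ph$contrasts))) {
      cc <- ph$contrasts[i, ]
      rows[[length(rows) + 1L]] <<- data.frame(
        analysis = analysis, contrast = cc$contrast, branch = branch,
        test = paste0("posthoc_", ph$adjustment), statistic = cc$statistic,
        df1 = cc$df, df2 = NA_real_, p = cc$p_adj,
        effect_size = cc$effect_size, effect_size_type = "contrast_d",
        adjustment = ph$adjustment)
    }
  }
  a <- object$analyses
  add("agency", a$agency$branch, a$agency$result)
  add("agency_vs_100", a$agency$branch, a$agency$vs_weights$solo_vs_100)
  add("agency_vs_50", a$agency$branch, a$agency$vs_weights$shared_vs_50)
  add("ownership", a$ownership$branch, a$ownership$result)
  for (nm in c("deviation", "jerk", "target_error")) {
    an <- a[[nm]]
    if (!is.null(an$sphericity)) add(nm, an$branch, an$sphericity)
    add(nm, an$branch, an$anova)
    add_ph(nm, an$branch, an$posthoc)
  }
  add("task_time", a$task_time$branch, a$task_time$result)
  add("reaction_time", a$reaction_time$branch, a$reaction_time$result)
  add("ip", a$ip$branch, a$ip$result)
  for (k in 1:3) add(paste0("ip_phase", k), a$ip_phases[[k]]$branch,
                     a$ip_phases[[k]]$result)
  for (nm in names(a$ip_sessions$effects))
    add("ip_sessions", a$ip_sessions$branch, a$ip_sessions$effects[[nm]],
        contrast = nm)
  add("corr_ownership_D", "spearman", a$corr_ownership_D$result)
  add("corr_agency_J", "spearman", a$corr_agency_J$result)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
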