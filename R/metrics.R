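# Per-trial metric extraction and the study-level aggregation rules:
# kinematic statistics are analysed at the dyad level (n = dyads; human
# value = mean of the two members' per-participant means, avatar one value
# per dyad), ratings at the participant level (n = participants).

#' Compute all per-trial metrics of an experiment
#'
#' Evaluates D, J, RT, TT and TE for every segmented reach and the
#' inter-participant distance (overall + three phases) for every dyad trial
#' on which both members' reaches are available.
#'
#' @param x a \code{\link{generate_dyad_experiment}} result or a list of
#'   \code{\link{reach_trial}} objects.
#' @param jerk_estimator passed to \code{\link{mean_jerk}}.
#' @param ip_window passed to \code{\link{interpersonal_distance}}.
#' @return object of class \code{reach_metrics}: list with data frames
#'   \code{metrics} (one row per reach) and \code{ip} (one row per dyad
#'   trial).
#' @export
compute_metrics <- function(x, jerk_estimator = "central", ip_window = "union") {
  trials <- if (inherits(x, "dyad_experiment")) x$trials else x
  if (!length(trials)) stop_no_data("no trials to analyse")
  n <- length(trials)
  metrics <- data.frame(
    dyad_id = vapply(trials, function(t) as.integer(t$dyad_id), integer(1)),
    participant_id = vapply(trials, function(t) t$participant_id, character(1)),
    actor = vapply(trials, function(t)
      if (identical(t$participant_id, "avatar")) "avatar" else "human",
      character(1)),
    condition = vapply(trials, function(t) t$condition, character(1)),
    session = vapply(trials, function(t) as.integer(t$session), integer(1)),
    trial = vapply(trials, function(t) as.integer(t$trial_index), integer(1)))
  vals <- t(vapply(trials, trial_metrics, numeric(5),
                   jerk_estimator = jerk_estimator))
  metrics <- cbind(metrics, as.data.frame(vals))
  # inter-participant distance: pair human members within dyad/cond/session/trial
  hi <- which(metrics$actor == "human")
  key <- paste(metrics$dyad_id[hi], metrics$condition[hi],
               metrics$session[hi], metrics$trial[hi], sep = "|")
  groups <- split(hi, key)
  groups <- groups[lengths(groups) == 2L]    # drop pairs with an excluded member
  np <- length(groups)
  vals <- matrix(NA_real_, np, 4L)
  idx1 <- integer(np)
  for (g in seq_len(np)) {
    idx <- groups[[g]]
    r <- interpersonal_distance(trials[[idx[1]]], trials[[idx[2]]],
                                window = ip_window)
    vals[g, ] <- c(r$overall, r$phases)
    idx1[g] <- idx[1]
  }
  ip <- data.frame(dyad_id = metrics$dyad_id[idx1],
                   condition = metrics$condition[idx1],
                   session = metrics$session[idx1],
                   trial = metrics$trial[idx1],
                   overall = vals[, 1], phase1 = vals[, 2],
                   phase2 = vals[, 3], phase3 = vals[, 4])
  rownames(ip) <- NULL
  structure(list(metrics = metrics, ip = ip), class = "reach_metrics")
}

#' @export
print.reach_metrics <- function(x, ...) {
  cat(sprintf("<reach_metrics: %d reaches (%d avatar), %d dyad trials with IP>\n",
              nrow(x$metrics), sum(x$metrics$actor == "avatar"), nrow(x$ip)))
  invisible(x)
}

#' Aggregate per-trial metrics to analysis units
#'
#' Pools trial-level metrics to per-unit condition means.  At
#' \code{level = "participant"} the unit is the participant; at
#' \code{level = "dyad"} the human value is the mean of the two members'
#' per-participant means and the avatar contributes one value per dyad.
#'
#' @param metrics the \code{metrics} data frame of
#'   \code{\link{compute_metrics}} (or a \code{reach_metrics} object).
#' @param level \code{"dyad"} or \code{"participant"}.
#' @param actor \code{"human"} or \code{"avatar"}.
#' @return data frame with columns \code{unit}, \code{dyad_id},
#'   \code{condition}, and the metric means \code{D, J, RT, TT, TE}.
#' @export
aggregate_metrics <- function(metrics, level = c("dyad", "participant"),
                              actor = c("human", "avatar")) {
  level <- match.arg(level); actor <- match.arg(actor)
  if (inherits(metrics, "reach_metrics")) metrics <- metrics$metrics
  m <- metrics[metrics$actor == actor, , drop = FALSE]
  if (!nrow(m)) stop_no_data("no rows for requested actor")
  cols <- c("D", "J", "RT", "TT", "TE")
  # per-participant (or per-avatar-per-dyad) condition means first
  pkey <- interaction(m$participant_id, m$dyad_id, m$condition, drop = TRUE)
  pm <- do.call(rbind, lapply(split(m, pkey), function(g)
    cbind(data.frame(participant_id = g$participant_id[1],
                     dyad_id = g$dyad_id[1], condition = g$condition[1]),
          as.data.frame(as.list(colMeans(g[cols]))))))
  rownames(pm) <- NULL
  if (level == "participant" || actor == "avatar") {
    out <- pm
    out$unit <- if (actor == "avatar") paste0("dyad", out$dyad_id) else
      out$participant_id
  } else {
    dkey <- interaction(pm$dyad_id, pm$condition, drop = TRUE)
    out <- do.call(rbind, lapply(split(pm, dkey), function(g) {
      if (length(unique(g$participant_id)) != 2L)
        stop_incomplete(sprintf("dyad %s / %s lacks a member's data",
                                g$dyad_id[1], g$condition[1]))
      cbind(data.frame(participant_id = NA_character_, dyad_id = g$dyad_id[1],
                       condition = g$condition[1]),
            as.data.frame(as.list(colMeans(g[cols]))))
    }))
    rownames(out) <- NULL
    out$unit <- paste0("dyad", out$dyad_id)
  }
  check_conditions_complete(out, actor)
  out[order(out$dyad_id, out$condition),
      c("unit", "dyad_id", "participant_id", "condition", cols)]
}

check_conditions_complete <- function(df, actor) {
  want <- if (actor == "avatar") "shared" else c("solo", "shared")
  bad <- tapply(df$condition, df$unit, function(cc) !all(want %in% cc))
  if (any(bad))
    stop_incomplete(paste("missing condition cell for unit(s):",
                          paste(names(bad)[bad], collapse = ", ")))
  invisible(df)
}

#' Aggregate inter-participant distance to dyad level
#'
#' @param ip the \code{ip} data frame of \code{\link{compute_metrics}}.
#' @param by_session if TRUE, keep the session factor (for the two-way
#'   condition x session analysis); otherwise pool over sessions.
#' @return data frame of dyad x condition (x session) means of
#'   \code{overall, phase1..3}.
#' @export
aggregate_ip <- function(ip, by_session = FALSE) {
  if (inherits(ip, "reach_metrics")) ip <- ip$ip
  if (!nrow(ip)) stop_no_data("no IP rows")
  keys <- if (by_session) list(ip$dyad_id, ip$condition, ip$session)
          else list(ip$dyad_id, ip$condition)
  kk <- do.call(interaction, c(keys, drop = TRUE))
  out <- do.call(rbind, lapply(split(ip, kk), function(g) {
    base <- data.frame(dyad_id = g$dyad_id[1], condition = g$condition[1])
    if (by_session) base$session <- g$session[1]
    cbind(base, as.data.frame(as.list(
      colMeans(g[c("overall", "phase1", "phase2", "phase3")]))))
  }))
  rownames(out) <- NULL
  out[order(out$dyad_id, out$condition), ]
}

# participant-level summary feeding the rating generator: each participant's
# per-condition mean jerk plus the dyad's avatar reach deviation (shared).
participant_rating_summary <- function(met, participants) {
  pm <- aggregate_metrics(met, level = "participant", actor = "human")
  av <- aggregate_metrics(met, level = "dyad", actor = "avatar")
  pm$D_avatar <- av$D[match(pm$dyad_id, av$dyad_id)]
  pm$D_avatar[pm$condition != "shared"] <- NA_real_
  pm[c("participant_id", "dyad_id", "condition", "J", "D_avatar")]
}
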