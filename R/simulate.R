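# Synthetic dyadic reaching experiments with the statistical structure the
# analysis assumes: curved, noisy solo reaches; partner-compensating reaches
# in the shared condition; and embodiment ratings linked to kinematics.

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic dyad-reaching experiment:
#' 10 dyads (20 participants), two conditions (solo / shared) of 4 sessions
#' each in counter-balanced alternating order, 3-D right-hand trajectories
#' sampled at 100 Hz, cube targets drawn from a frontal workspace box,
#' agency (0-100) and ownership (-3..+3) ratings linked to the kinematics.
#'
#' Generative mechanism per reach: a quintic minimum-jerk base path from the
#' home position to the target centre, onset-delayed by a participant
#' reaction-time draw, plus (i) a participant-specific lateral "bow"
#' \code{curvature_amp * sin(pi tau)^2} (natural path curvature with zero
#' velocity at both movement boundaries), (ii) smooth
#' Gaussian motor noise, and in the shared condition (iii) subtraction of
#' \code{strategy_gain} times the dyad-mean bow (cooperative compensation
#' that straightens the avatar by \code{1 - strategy_gain} while leaving
#' the inter-member difference unchanged),
#' (iv) an anti-correlated divergence \code{+/- divergence_amp * w(tau)}
#' between the two members, with w increasing over the movement, so
#' inter-participant distance grows in phases 2-3, and (v) endpoint scatter inflated by
#' \code{te_inflation}.  With \code{strategy_gain = 1},
#' \code{divergence_amp = 0} and zero noise the two shared trajectories
#' average to the straight minimum-jerk path exactly.
#'
#' @param n_dyads number of dyads (default 10, i.e. 20 participants).
#' @param trials_per_session reaches per session (default 12).
#' @param n_sessions_per_condition sessions per condition (default 4).
#' @param dt sampling period in seconds (default 0.01, 100 Hz).
#' @param reach_duration_range min/max movement time draw (s).
#' @param rt_mean,rt_sd population mean and between-participant sd of
#'   reaction time (s); trial-to-trial jitter uses \code{rt_sd / 2}.
#' @param curvature_amp amplitude of the natural path bow (m).
#' @param noise_sd stationary sd of the smooth motor noise (m).
#' @param noise_smooth_tau Gaussian low-pass time constant of the noise (s),
#'   so numerical third derivatives stay finite.
#' @param strategy_gain shared-condition compensation toward a straight
#'   avatar path, in [0, 1].
#' @param divergence_amp amplitude of the late-phase anti-correlated
#'   divergence of the two hands in shared mode (m).
#' @param divergence_weight shape of the divergence weight w(tau):
#'   \code{"smoothstep"} (default) uses \code{w = 3 tau^2 - 2 tau^3},
#'   increasing from 0 to 1 with zero velocity at both movement boundaries
#'   (no spurious numerical jerk); \code{"power"} uses
#'   \code{w = tau^divergence_power}.  Either way the two hands diverge
#'   most near the target.
#' @param divergence_power exponent for \code{divergence_weight = "power"}.
#' @param te_inflation multiplier (>= 1) on individual endpoint scatter in
#'   shared mode.
#' @param rt_shared_gain reaction-time facilitation (s) of both members in
#'   the shared condition: a generative stand-in for the faster joint
#'   reactions observed with a shared avatar, on top of the earliest-mover
#'   (min-of-two) averaging benefit.
#' @param shared_slowdown fractional increase of movement time in the
#'   shared condition (cautious cooperative control); together with
#'   \code{rt_shared_gain} it leaves the avatar's total task time roughly
#'   unchanged while its reaction time improves.
#' @param rating_link_slope ownership-scale units per SD of avatar reach
#'   deviation (monotone rating link).
#' @param rating_noise_sd ownership-scale rating noise (sd).
#' @param agency_solo_mean,agency_shared_mean configured agency rating means
#'   (percent); the shared mean sits strictly between 50 and 100.
#' @param ownership_solo_mean,ownership_shared_mean configured ownership
#'   means (Likert units).
#' @param agency_link_slope,agency_noise_sd agency-scale (percent) link slope
#'   on the jerk change and noise sd; default 10x the ownership-scale values
#'   (the two scales differ by roughly that factor).
#' @param home hand start position (m).
#' @param workspace_lo,workspace_hi corners of the frontal target box (m).
#' @param target_edge target cube side (m).
#' @param hold_duration time the hand dwells at the endpoint after the reach
#'   (s), so the touch sample is always covered.
#' @param seed integer RNG seed; mandatory for reproducible runs.
#' @return validated object of class \code{sim_config}.
#' @export
sim_config <- function(n_dyads = 10L,
                       trials_per_session = 12L,
                       n_sessions_per_condition = 4L,
                       dt = 0.01,
                       reach_duration_range = c(0.6, 0.9),
                       rt_mean = 0.25, rt_sd = 0.015,
                       curvature_amp = 0.04,
                       noise_sd = 0.0015,
                       noise_smooth_tau = 0.07,
                       strategy_gain = 0.6,
                       divergence_amp = 0.07,
                       divergence_weight = c("smoothstep", "power"),
                       divergence_power = 2,
                       te_inflation = 1.35,
                       rt_shared_gain = 0.025,
                       shared_slowdown = 0.03,
                       rating_link_slope = 0.9,
                       rating_noise_sd = 0.8,
                       agency_solo_mean = 85,
                       agency_shared_mean = 62,
                       ownership_solo_mean = 1.5,
                       ownership_shared_mean = 0.2,
                       agency_link_slope = NULL,
                       agency_noise_sd = NULL,
                       home = c(0, 0.25, 1.05),
                       workspace_lo = c(-0.20, 0.55, 0.95),
                       workspace_hi = c(0.20, 0.75, 1.25),
                       target_edge = 0.06,
                       hold_duration = 0.08,
                       seed = 1L) {
  cfg <- list(n_dyads = as.integer(n_dyads),
              trials_per_session = as.integer(trials_per_session),
              n_sessions_per_condition = as.integer(n_sessions_per_condition),
              dt = dt, reach_duration_range = as.numeric(reach_duration_range),
              rt_mean = rt_mean, rt_sd = rt_sd,
              curvature_amp = curvature_amp, noise_sd = noise_sd,
              noise_smooth_tau = noise_smooth_tau,
              strategy_gain = strategy_gain,
              divergence_amp = divergence_amp,
              divergence_weight = match.arg(divergence_weight),
              divergence_power = divergence_power,
              te_inflation = te_inflation,
              rt_shared_gain = rt_shared_gain,
              shared_slowdown = shared_slowdown,
              rating_link_slope = rating_link_slope,
              rating_noise_sd = rating_noise_sd,
              agency_solo_mean = agency_solo_mean,
              agency_shared_mean = agency_shared_mean,
              ownership_solo_mean = ownership_solo_mean,
              ownership_shared_mean = ownership_shared_mean,
              agency_link_slope = if (is.null(agency_link_slope))
                10 * rating_link_slope else agency_link_slope,
              agency_noise_sd = if (is.null(agency_noise_sd))
                10 * rating_noise_sd else agency_noise_sd,
              home = as.numeric(home),
              workspace_lo = as.numeric(workspace_lo),
              workspace_hi = as.numeric(workspace_hi),
              target_edge = target_edge, hold_duration = hold_duration,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_dyads < 1L || trials_per_session < 1L || n_sessions_per_condition < 1L)
      stop_invalid("counts must be positive")
    if (dt <= 0) stop_invalid("'dt' must be positive")
    if (length(reach_duration_range) != 2L ||
        reach_duration_range[1] > reach_duration_range[2] ||
        reach_duration_range[1] < 2 * dt)
      stop_invalid("'reach_duration_range' must be (min, max) with min >= 2 dt")
    if (strategy_gain < 0 || strategy_gain > 1)
      stop_invalid("'strategy_gain' must lie in [0, 1]")
    if (min(rt_sd, curvature_amp, noise_sd, divergence_amp,
            rating_noise_sd, agency_noise_sd) < 0)
      stop_invalid("sd / amplitude parameters must be non-negative")
    if (te_inflation < 1) stop_invalid("'te_inflation' must be >= 1")
    if (divergence_power <= 0) stop_invalid("'divergence_power' must be positive")
    if (rt_shared_gain < 0) stop_invalid("'rt_shared_gain' must be non-negative")
    if (shared_slowdown < 0) stop_invalid("'shared_slowdown' must be non-negative")
    if (noise_smooth_tau <= 0) stop_invalid("'noise_smooth_tau' must be positive")
    if (target_edge <= 0) stop_invalid("'target_edge' must be positive")
    if (agency_shared_mean <= 50 || agency_shared_mean >= 100)
      stop_invalid("'agency_shared_mean' must lie strictly between 50 and 100")
    if (agency_solo_mean >= 100) stop_invalid("'agency_solo_mean' must be below 100")
    if (any(workspace_hi < workspace_lo)) stop_invalid("workspace box is inverted")
    if (is.na(seed)) stop_invalid("'seed' is mandatory")
  })
  invisible(cfg)
}

#' Averaging-only null configuration
#'
#' The null in which participants behave identically in the solo and shared
#' conditions and the avatar differs from its members only through the
#' averaging of two independent noisy reaches: \code{strategy_gain = 0},
#' \code{divergence_amp = 0}, \code{te_inflation = 1}.  Under this null the
#' avatar's expected reach deviation and jerk still fall below the members'
#' (independent noise averages out) while the inter-participant distance is
#' equal between conditions -- which is exactly why IP, not D or J, is the
#' discriminating statistic for a genuine behavioural change.
#'
#' @param ... passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
averaging_null_config <- function(...) {
  args <- list(...)
  args$strategy_gain <- 0
  args$divergence_amp <- 0
  args$te_inflation <- 1
  args$rt_shared_gain <- 0
  args$shared_slowdown <- 0
  do.call(sim_config, args)
}

unit_cross <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

#' Base (noiseless, strategy-free) reach over a trial grid
#'
#' Builds the deterministic skeleton of one trial: the hand rests at
#' \code{home}, starts a minimum-jerk reach to the target centre at
#' \code{rt}, completes it after \code{duration}, and holds the endpoint
#' until \code{t_total}.  Also carries the movement phase \code{tau}
#' (clamped to [0, 1]) and an orthonormal frame (lateral / up, both
#' orthogonal to the reach direction) used by \code{\link{apply_strategy}}.
#'
#' @param home,target_pos length-3 positions (m).
#' @param rt reach onset time (s).
#' @param duration movement time (s).
#' @param dt sampling period (s).
#' @param t_total trial length (s); default \code{rt + duration}.
#' @return object of class \code{reach_base}.
#' @export
reach_base <- function(home, target_pos, rt, duration, dt,
                       t_total = rt + duration) {
  home <- as.numeric(home); target_pos <- as.numeric(target_pos)
  if (duration < 2 * dt || dt <= 0) stop_invalid("invalid duration or dt")
  if (rt < 0) stop_invalid("'rt' must be non-negative")
  n <- floor(t_total / dt + 1e-9)
  times <- (0:n) * dt
  tau <- pmin(pmax((times - rt) / duration, 0), 1)
  s <- mj_s(tau)
  delta <- target_pos - home
  xyz <- cbind(home[1] + delta[1] * s, home[2] + delta[2] * s,
               home[3] + delta[3] * s)
  dir <- delta / sqrt(sum(delta^2))
  lateral <- unit_cross(dir, c(0, 0, 1))
  if (is.null(lateral)) lateral <- c(1, 0, 0)
  up <- unit_cross(lateral, dir)
  structure(list(traj = new_traj(times, xyz, dt), tau = tau,
                 lateral = lateral, up = up, rt = rt, duration = duration),
            class = "reach_base")
}

#' Apply a participant's condition-dependent movement strategy
#'
#' Turns a noiseless base reach into one member's simulated hand path.
#' In the solo condition the base is bowed by
#' \code{curvature_amp * sin(pi tau)^2} in the participant's habitual
#' direction and perturbed by smooth motor noise.  In the shared condition
#' the member cooperates on the \emph{avatar's} path: they subtract
#' \code{strategy_gain} times the dyad-mean bow (their own habitual bow
#' averaged with the partner's), which straightens the avatar by
#' \code{1 - strategy_gain} while leaving the difference between the two
#' members' hands unchanged; an anti-correlated divergence
#' \code{div_sign * divergence_amp * w(tau)} along the
#' lateral axis is added
#' (the two members take opposite signs, so it cancels in the avatar while
#' inflating inter-participant distance most in phases 2-3), and endpoint
#' scatter is multiplied by \code{te_inflation} via an extra ramped offset.
#' Independent smooth noise is added in both conditions, and the same
#' random draws are consumed in the same order in both, so with
#' \code{strategy_gain = 0}, \code{divergence_amp = 0} and
#' \code{te_inflation = 1} the shared output is identical to the solo
#' output under the same RNG state.
#'
#' @param base a \code{\link{reach_base}}.
#' @param condition \code{"solo"} or \code{"shared"}.
#' @param cfg a \code{\link{sim_config}}.
#' @param bow_angle participant's habitual bow direction (radians in the
#'   lateral/up plane).
#' @param div_sign +1 for one dyad member, -1 for the other.
#' @param partner_bow_angle the partner's habitual bow direction, used for
#'   the cooperative avatar-error compensation; defaults to the
#'   participant's own (pure self-compensation, i.e. the bow simply scaled
#'   by \code{1 - strategy_gain}).
#' @return a \code{\link{trajectory}}.
#' @export
apply_strategy <- function(base, condition, cfg, bow_angle = 0, div_sign = 1,
                           partner_bow_angle = bow_angle) {
  if (!inherits(base, "reach_base")) stop_invalid("'base' must be a reach_base")
  if (!is.character(condition) || !condition %in% c("solo", "shared"))
    stop_invalid("unknown condition label")
  shared <- condition == "shared"
  tau <- base$tau
  n <- length(tau)
  # identical draw order in both conditions (same seed => same draws)
  z <- stats::rnorm(3L)
  noise <- smooth_noise(n, cfg$dt, cfg$noise_sd, cfg$noise_smooth_tau)
  bow_dir <- cos(bow_angle) * base$lateral + sin(bow_angle) * base$up
  eff_dir <- if (shared) {
    partner_dir <- cos(partner_bow_angle) * base$lateral +
      sin(partner_bow_angle) * base$up
    bow_dir - cfg$strategy_gain * (bow_dir + partner_dir) / 2
  } else bow_dir
  xyz <- base$traj$xyz +
    outer(cfg$curvature_amp * sin(pi * tau)^2, eff_dir) + noise
  if (shared) {
    w <- if (identical(cfg$divergence_weight, "power")) tau^cfg$divergence_power
         else tau^2 * (3 - 2 * tau)       # smoothstep: C1 at both boundaries
    xyz <- xyz + outer(cfg$divergence_amp * div_sign * w, base$lateral)
    ramp <- sqrt(cfg$te_inflation^2 - 1) * cfg$noise_sd
    xyz <- xyz + outer(ramp * tau^2 * (3 - 2 * tau), z)
  }
  new_traj(base$traj$times, xyz, cfg$dt)
}

#' Generate a complete synthetic dyad-reaching experiment
#'
#' Simulates \code{n_dyads} dyads working through 2 conditions x
#' \code{n_sessions_per_condition} sessions x \code{trials_per_session}
#' reaches, in counter-balanced alternating condition order (odd dyads start
#' solo, even dyads start shared).  Both members always see the same target;
#' in the shared condition the avatar's hand is the pointwise average of the
#' two members' hands.  Each reach is segmented at the first sample inside
#' the target cube; reaches that never touch are counted and excluded.
#' Embodiment ratings are generated from the participants' own kinematics
#' via \code{\link{generate_ratings}}.  Fully deterministic under the
#' config seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return object of class \code{dyad_experiment}: list with \code{trials}
#'   (list of \code{\link{reach_trial}}, humans and avatars), \code{ratings}
#'   (data frame), \code{excluded} (data frame of no-touch reaches),
#'   \code{participants} (traits) and \code{config}.
#' @export
generate_dyad_experiment <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  set.seed(cfg$seed)
  n_part <- 2L * cfg$n_dyads
  participants <- data.frame(
    dyad_id = rep(seq_len(cfg$n_dyads), each = 2L),
    member = rep(1:2, cfg$n_dyads),
    participant_id = sprintf("d%02d_p%d", rep(seq_len(cfg$n_dyads), each = 2L),
                             rep(1:2, cfg$n_dyads)),
    bow_angle = stats::runif(n_part, 0, 2 * pi),
    rt_base = stats::rnorm(n_part, cfg$rt_mean, cfg$rt_sd))
  trials <- vector("list",
                   cfg$n_dyads * 8L * cfg$n_sessions_per_condition *
                     cfg$trials_per_session)  # upper bound; trimmed below
  excl <- list()
  ti <- 0L
  n_sess <- 2L * cfg$n_sessions_per_condition
  box <- rbind(cfg$workspace_lo, cfg$workspace_hi)
  for (d in seq_len(cfg$n_dyads)) {
    pd <- participants[participants$dyad_id == d, ]
    conds <- if (d %% 2L == 1L) rep(c("solo", "shared"), cfg$n_sessions_per_condition)
             else rep(c("shared", "solo"), cfg$n_sessions_per_condition)
    sess_count <- c(solo = 0L, shared = 0L)
    for (s in seq_len(n_sess)) {
      cond <- conds[s]
      sess_count[cond] <- sess_count[cond] + 1L
      sw <- sess_count[[cond]]
      for (tr in seq_len(cfg$trials_per_session)) {
        tpos <- stats::runif(3L, box[1, ], box[2, ])
        target <- target_spec(tpos, cfg$target_edge, onset_time = 0)
        rt2 <- pmax(0.1, stats::rnorm(2L, pd$rt_base, cfg$rt_sd / 2) -
                      (cond == "shared") * cfg$rt_shared_gain)
        # movement time is mostly set by the (shared) target distance;
        # members differ by a small individual jitter
        dur0 <- stats::runif(1L, cfg$reach_duration_range[1],
                             cfg$reach_duration_range[2])
        dur2 <- pmax(2 * cfg$dt, dur0 + stats::rnorm(2L, 0, 0.03)) *
          (1 + (cond == "shared") * cfg$shared_slowdown)
        t_total <- max(rt2 + dur2) + cfg$hold_duration
        member_traj <- vector("list", 2L)
        for (i in 1:2) {
          b <- reach_base(cfg$home, tpos, rt2[i], dur2[i], cfg$dt, t_total)
          member_traj[[i]] <- apply_strategy(b, cond, cfg, pd$bow_angle[i],
                                             div_sign = c(1, -1)[i],
                                             partner_bow_angle = pd$bow_angle[3L - i])
        }
        if (cond == "solo") {
          # each member's trial ends when their own (solo) avatar touches
          for (i in 1:2) {
            tri <- tryCatch(
              segment_reach(member_traj[[i]], target, dyad_id = d,
                            participant_id = pd$participant_id[i],
                            condition = cond, session = sw, trial_index = tr),
              sharedreach_no_touch_error = function(e) NULL)
            if (is.null(tri)) {
              excl[[length(excl) + 1L]] <-
                data.frame(dyad_id = d, participant_id = pd$participant_id[i],
                           condition = cond, session = sw, trial_index = tr,
                           reason = "no_touch")
            } else {
              attr(tri, "truth") <- list(rt = rt2[i], duration = dur2[i])
              ti <- ti + 1L
              trials[[ti]] <- tri
            }
          }
        } else {
          # the shared trial ends when the *avatar* touches the target: the
          # members' own hands need not (and often do not) enter the cube
          av <- average_trajectories(member_traj[[1]], member_traj[[2]])
          avt <- tryCatch(
            segment_reach(av, target, dyad_id = d, participant_id = "avatar",
                          condition = cond, session = sw, trial_index = tr),
            sharedreach_no_touch_error = function(e) NULL)
          if (is.null(avt)) {
            for (pid in c(pd$participant_id, "avatar"))
              excl[[length(excl) + 1L]] <-
                data.frame(dyad_id = d, participant_id = pid,
                           condition = cond, session = sw, trial_index = tr,
                           reason = "avatar_no_touch")
          } else {
            for (i in 1:2) {
              tri <- clip_trial(member_traj[[i]], target, avt$touch_time,
                                dyad_id = d,
                                participant_id = pd$participant_id[i],
                                condition = cond, session = sw,
                                trial_index = tr)
              attr(tri, "truth") <- list(rt = rt2[i], duration = dur2[i])
              ti <- ti + 1L
              trials[[ti]] <- tri
            }
            ti <- ti + 1L
            trials[[ti]] <- avt
          }
        }
      }
    }
  }
  trials <- trials[seq_len(ti)]
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dyad_id = integer(), participant_id = character(),
               condition = character(), session = integer(),
               trial_index = integer(), reason = character())
  exp <- structure(list(trials = trials, ratings = NULL,
                        excluded = excluded, participants = participants,
                        config = cfg),
                   class = "dyad_experiment")
  met <- compute_metrics(exp)
  exp$metrics <- met
  exp$ratings <- generate_ratings(participant_rating_summary(met, participants), cfg)
  exp
}

#' @export
print.dyad_experiment <- function(x, ...) {
  n_h <- sum(vapply(x$trials, function(t) t$participant_id != "avatar", logical(1)))
  cat(sprintf(paste0("<dyad_experiment: %d dyads, %d human reaches, ",
                     "%d avatar reaches, %d excluded (no touch), seed %d>\n"),
              x$config$n_dyads, n_h, length(x$trials) - n_h,
              nrow(x$excluded), x$config$seed))
  invisible(x)
}
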