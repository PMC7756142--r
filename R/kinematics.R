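# Reach segmentation and the per-trial kinematic statistics:
# reach deviation D, mean hand jerk J, reaction time RT, task time TT,
# target error TE, and phase-wise inter-participant distance IP.

#' Target cube specification
#'
#' @param position length-3 numeric, cube centre (m).
#' @param edge_length cube side (m), positive.
#' @param onset_time time at which the target appears (s), non-negative.
#' @return object of class \code{target_spec}.
#' @export
target_spec <- function(position, edge_length, onset_time = 0) {
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position)))
    stop_invalid("'position' must be a finite length-3 numeric vector")
  if (!is.numeric(edge_length) || edge_length <= 0)
    stop_invalid("'edge_length' must be positive")
  if (!is.numeric(onset_time) || onset_time < 0)
    stop_invalid("'onset_time' must be non-negative")
  structure(list(position = position, edge_length = edge_length,
                 onset_time = onset_time), class = "target_spec")
}

#' One segmented reach
#'
#' A single reach spanning target appearance to target touch, with its
#' identifying metadata.  \code{participant_id == "avatar"} marks the shared
#' avatar's reach.
#'
#' @param trajectory a \code{\link{trajectory}} clipped to
#'   \code{[onset_time, touch_time]}.
#' @param target a \code{\link{target_spec}}.
#' @param onset_time,touch_time event times (s), \code{onset < touch}.
#' @param dyad_id,participant_id,condition,session,trial_index metadata;
#'   \code{condition} is \code{"solo"} or \code{"shared"}.
#' @return object of class \code{reach_trial}.
#' @export
reach_trial <- function(trajectory, target, onset_time, touch_time,
                        dyad_id = NA_integer_, participant_id = NA_character_,
                        condition = NA_character_, session = NA_integer_,
                        trial_index = NA_integer_) {
  check_traj(trajectory)
  if (!inherits(target, "target_spec")) stop_invalid("'target' must be a target_spec")
  if (!(onset_time < touch_time)) stop_invalid("'onset_time' must precede 'touch_time'")
  if (!is.na(condition) && !condition %in% c("solo", "shared"))
    stop_invalid("'condition' must be \"solo\" or \"shared\"")
  structure(list(trajectory = trajectory, target = target,
                 onset_time = onset_time, touch_time = touch_time,
                 dyad_id = dyad_id, participant_id = participant_id,
                 condition = condition, session = session,
                 trial_index = trial_index),
            class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("<reach_trial %s dyad %s %s s%d t%d: onset %.3f s, touch %.3f s>\n",
              x$participant_id, as.character(x$dyad_id),
              ifelse(is.na(x$condition), "?", x$condition),
              as.integer(x$session), as.integer(x$trial_index),
              x$onset_time, x$touch_time))
  invisible(x)
}

in_cube <- function(xyz, target) {
  h <- target$edge_length / 2
  abs(xyz[, 1] - target$position[1]) <= h &
    abs(xyz[, 2] - target$position[2]) <= h &
    abs(xyz[, 3] - target$position[3]) <= h
}

#' Segment a raw trajectory into a reach
#'
#' The reach spans the appearance of the target to the hand's touching the
#' target.  Touch is the first sample at which the hand point lies within the
#' axis-aligned cube of side \code{edge_length} centred on the target; the
#' trajectory is clipped to \code{[onset, touch]}.
#'
#' @param raw a \code{\link{trajectory}} spanning the target onset.
#' @param target a \code{\link{target_spec}}.
#' @param ... metadata passed to \code{\link{reach_trial}}.
#' @return a \code{\link{reach_trial}}; if the hand never enters the cube a
#'   condition of class \code{sharedreach_no_touch_error} is signalled (such
#'   trials are counted and excluded upstream, never silently dropped).
#' @export
segment_reach <- function(raw, target, ...) {
  check_traj(raw)
  if (!inherits(target, "target_spec")) stop_invalid("'target' must be a target_spec")
  onset <- target$onset_time
  if (raw$times[1] > onset + 1e-9)
    stop_invalid("trajectory does not span the target onset")
  i0 <- which(raw$times >= onset - 1e-9)[1]
  hit <- which(in_cube(raw$xyz, target) & seq_len(nrow(raw$xyz)) >= i0)
  # require the hand to start outside the cube: ignore leading in-cube samples
  # only if the target spawned on the hand (degenerate); first entry otherwise
  if (length(hit) == 0L)
    stop_no_touch("hand never touches the target cube")
  it <- hit[1]
  if (it == i0) {
    # hand already inside at onset: treat first sample after onset as touch
    it <- i0 + 1L
    if (it > length(raw$times)) stop_no_touch("hand never touches the target cube")
  }
  idx <- i0:it
  reach_trial(new_traj(raw$times[idx], raw$xyz[idx, , drop = FALSE], raw$dt),
              target, onset_time = raw$times[i0], touch_time = raw$times[it], ...)
}

# clip a raw trajectory to [onset, t_end] without a touch requirement; used
# for the members' hands in the shared condition, whose trial ends when the
# avatar (not their own hand) touches the target
clip_trial <- function(raw, target, t_end, ...) {
  onset <- target$onset_time
  i0 <- which(raw$times >= onset - 1e-9)[1]
  it <- max(which(raw$times <= t_end + 1e-9))
  if (is.na(i0) || it <= i0) stop_invalid("empty clip window")
  idx <- i0:it
  reach_trial(new_traj(raw$times[idx], raw$xyz[idx, , drop = FALSE], raw$dt),
              target, onset_time = raw$times[i0], touch_time = raw$times[it],
              ...)
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Reach deviation D
#'
#' Difference between the length of the hand movement trajectory and the
#' straight line joining its start and end points; zero for a perfectly
#' straight reach and non-negative by the triangle inequality.  D is a pure
#' path property: invariant to rigid motions and to time reparameterisation.
#'
#' @param trial a \code{\link{reach_trial}} (or bare \code{trajectory}).
#' @return deviation in metres.
#' @export
reach_deviation <- function(trial) {
  traj <- as_traj(trial)
  p <- traj$xyz
  path <- sum(row_norms(diff(p)))
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  max(path - chord, 0)
}

as_traj <- function(x) {
  if (inherits(x, "reach_trial")) x$trajectory
  else { check_traj(x); x }
}

#' Mean hand jerk J
#'
#' Mean over interior samples of the magnitude of the numerically
#' differentiated third derivative of hand position, in m s^-3.  The default
#' estimator is the five-point central third difference
#' \eqn{(p_{i+2} - 2p_{i+1} + 2p_{i-1} - p_{i-2}) / (2\,dt^3)}; a three-step
#' forward difference is available via \code{estimator = "forward"}.  Lower
#' values mean smoother movement.
#'
#' @param trial a \code{\link{reach_trial}} or \code{trajectory} with uniform
#'   sampling and at least 5 samples (4 for the forward estimator).
#' @param estimator \code{"central"} (default) or \code{"forward"}.
#' @return mean jerk magnitude in m s^-3.
#' @export
mean_jerk <- function(trial, estimator = c("central", "forward")) {
  estimator <- match.arg(estimator)
  traj <- as_traj(trial)
  p <- traj$xyz
  n <- nrow(p)
  dt <- traj$dt
  if (estimator == "central") {
    if (n < 5L) stop_invalid("mean_jerk needs at least 5 samples")
    i <- 3:(n - 2)
    j3 <- (p[i + 2, , drop = FALSE] - 2 * p[i + 1, , drop = FALSE] +
             2 * p[i - 1, , drop = FALSE] - p[i - 2, , drop = FALSE]) / (2 * dt^3)
  } else {
    if (n < 4L) stop_invalid("mean_jerk needs at least 4 samples")
    j3 <- diff(p, differences = 3) / dt^3
  }
  mean(row_norms(j3))
}

traj_speed <- function(traj) {
  p <- traj$xyz
  n <- nrow(p)
  if (n < 3L) return(row_norms(diff(p)) / traj$dt)
  v <- matrix(0, n, 3L)
  v[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / (2 * traj$dt)
  v[1, ] <- (p[2, ] - p[1, ]) / traj$dt
  v[n, ] <- (p[n, ] - p[n - 1, ]) / traj$dt
  row_norms(v)
}

#' Reaction time RT
#'
#' Time between the appearance of the target and the moment hand speed first
#' exceeds 10\% of its within-trial maximum.  Speed is the central first
#' difference of position; the crossing is strict (\code{>}) and searched from
#' the onset onwards.
#'
#' @param trial a segmented \code{\link{reach_trial}}.
#' @param threshold fraction of peak speed, default 0.1.
#' @return reaction time in seconds.
#' @export
reaction_time <- function(trial, threshold = 0.1) {
  if (!inherits(trial, "reach_trial")) stop_invalid("'trial' must be a reach_trial")
  sp <- traj_speed(trial$trajectory)
  vmax <- max(sp)
  if (vmax <= 0) stop_undefined_rt("trajectory has zero peak speed")
  i <- which(sp > threshold * vmax)[1]
  if (is.na(i)) stop_undefined_rt("speed never exceeds threshold")
  trial$trajectory$times[i] - trial$onset_time
}

#' Task time TT
#'
#' Time between the appearance of the target and the hand's touching the
#' target.
#'
#' @param trial a segmented \code{\link{reach_trial}}.
#' @return task time in seconds.
#' @export
task_time <- function(trial) {
  if (!inherits(trial, "reach_trial")) stop_invalid("'trial' must be a reach_trial")
  trial$touch_time - trial$onset_time
}

#' Target error TE
#'
#' Distance between the endpoint of the reach and the centre of the target
#' cube.
#'
#' @param trial a segmented \code{\link{reach_trial}}.
#' @return error in metres.
#' @export
target_error <- function(trial) {
  if (!inherits(trial, "reach_trial")) stop_invalid("'trial' must be a reach_trial")
  p <- trial$trajectory$xyz
  sqrt(sum((p[nrow(p), ] - trial$target$position)^2))
}

#' Inter-participant distance IP, overall and by movement phase
#'
#' Time-averaged Euclidean distance between the two members' hands during a
#' reach, reported overall and over \code{n_phases} equal-duration parts of
#' the movement.  When the members touch at different times the default
#' (\code{window = "union"}) spans the common onset to the later touch,
#' holding the earlier finisher at its endpoint, so the phases stay
#' well-defined; \code{window = "intersection"} clips to the earlier touch.
#'
#' @param trial_a,trial_b segmented \code{\link{reach_trial}}s of the two dyad
#'   members for the same target.
#' @param n_phases number of equal-duration phases (default 3).
#' @param window \code{"union"} (default) or \code{"intersection"}.
#' @return object of class \code{ip_result}: list with \code{overall} (m),
#'   \code{phases} (length \code{n_phases}, m) and \code{window} used.  The
#'   overall value equals the duration-weighted mean of the phase values by
#'   construction.
#' @export
interpersonal_distance <- function(trial_a, trial_b, n_phases = 3L,
                                   window = c("union", "intersection")) {
  window <- match.arg(window)
  if (!inherits(trial_a, "reach_trial") || !inherits(trial_b, "reach_trial"))
    stop_invalid("inputs must be reach_trial objects")
  ta <- trial_a$trajectory; tb <- trial_b$trajectory
  if (abs(ta$dt - tb$dt) > 1e-9) stop_alignment("sampling periods differ")
  dt <- ta$dt
  t0 <- max(ta$times[1], tb$times[1])
  t1 <- if (window == "union") max(ta$times[length(ta$times)], tb$times[length(tb$times)])
        else min(ta$times[length(ta$times)], tb$times[length(tb$times)])
  if (t1 - t0 < dt) stop_alignment("reach windows do not overlap")
  m <- floor((t1 - t0) / dt + 1e-9) + 1L
  if (abs(ta$times[1] - tb$times[1]) < 1e-9) {
    # same lattice: index + endpoint padding instead of interpolation
    d <- ip_dist_aligned(ta$xyz, tb$xyz, m)
  } else {
    grid <- seq(t0, t0 + dt * (m - 1L), by = dt)
    pa <- hold_interp(ta, grid)
    pb <- hold_interp(tb, grid)
    d <- row_norms(pa - pb)
  }
  # equal-duration thirds by sample index; every sample in exactly one phase
  cuts <- ceiling(seq_len(n_phases) * m / n_phases)
  lo <- c(1L, head(cuts, -1L) + 1L)
  phases <- vapply(seq_len(n_phases),
                   function(k) mean(d[lo[k]:cuts[k]]), numeric(1))
  wts <- (cuts - lo + 1L) / m
  structure(list(overall = sum(wts * phases), phases = phases,
                 window = window, n_samples = m),
            class = "ip_result")
}

pad_xyz <- function(p, m) {
  n <- nrow(p)
  if (n >= m) return(p[seq_len(m), , drop = FALSE])
  rbind(p, p[rep.int(n, m - n), , drop = FALSE])
}

ip_dist_aligned <- function(pa, pb, m) {
  pa <- pad_xyz(pa, m)
  pb <- pad_xyz(pb, m)
  dd <- pa - pb
  sqrt(.rowSums(dd * dd, m, 3L))
}

# linear interpolation clamped to the trajectory's endpoints (hold rule)
hold_interp <- function(traj, grid) {
  vapply(1:3, function(j)
    stats::approx(traj$times, traj$xyz[, j], xout = grid, rule = 2)$y,
    numeric(length(grid)))
}

#' All per-trial metrics for one reach
#'
#' Single-pass evaluation of \code{\link{reach_deviation}},
#' \code{\link{mean_jerk}}, \code{\link{reaction_time}},
#' \code{\link{task_time}} and \code{\link{target_error}} (numerically
#' identical to calling them individually).
#'
#' @param trial a segmented \code{\link{reach_trial}}.
#' @param jerk_estimator passed to \code{\link{mean_jerk}}.
#' @return named numeric vector with elements \code{D}, \code{J}, \code{RT},
#'   \code{TT}, \code{TE}.
#' @export
trial_metrics <- function(trial, jerk_estimator = "central") {
  traj <- trial$trajectory
  p <- traj$xyz
  n <- nrow(p)
  dt <- traj$dt
  dp <- diff(p)
  seg <- sqrt(.rowSums(dp * dp, n - 1L, 3L))
  D <- max(sum(seg) - sqrt(sum((p[n, ] - p[1, ])^2)), 0)
  if (jerk_estimator == "central") {
    if (n < 5L) stop_invalid("mean_jerk needs at least 5 samples")
    i <- 3:(n - 2)
    j3 <- (p[i + 2, , drop = FALSE] - 2 * p[i + 1, , drop = FALSE] +
             2 * p[i - 1, , drop = FALSE] - p[i - 2, , drop = FALSE]) / (2 * dt^3)
  } else {
    if (n < 4L) stop_invalid("mean_jerk needs at least 4 samples")
    j3 <- diff(dp, differences = 2) / dt^3
  }
  J <- mean(sqrt(.rowSums(j3 * j3, nrow(j3), 3L)))
  # central-difference speed, one-sided at the ends (as traj_speed)
  sp <- numeric(n)
  sp[2:(n - 1)] <- sqrt(.rowSums((p[3:n, , drop = FALSE] -
                                    p[1:(n - 2), , drop = FALSE])^2,
                                 n - 2L, 3L)) / (2 * dt)
  sp[1] <- seg[1] / dt
  sp[n] <- seg[n - 1] / dt
  vmax <- max(sp)
  if (vmax <= 0) stop_undefined_rt("trajectory has zero peak speed")
  RT <- traj$times[which(sp > 0.1 * vmax)[1]] - trial$onset_time
  c(D = D, J = J, RT = RT,
    TT = trial$touch_time - trial$onset_time,
    TE = sqrt(sum((p[n, ] - trial$target$position)^2)))
}
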