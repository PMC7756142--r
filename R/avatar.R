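# Shared-avatar construction: put two hand paths on one clock and average them.

#' Align two trajectories onto a common uniform time base
#'
#' Online, both hands are sampled on one clock; offline data may not be.  The
#' common grid is the intersection of the two time supports at the inputs'
#' sampling period; both trajectories are linearly interpolated onto it (no
#' extrapolation).  Inputs already on the same grid are returned unchanged.
#'
#' @param a,b \code{\link{trajectory}} objects with equal sampling periods.
#' @return list with elements \code{a} and \code{b}, both on the shared grid.
#' @export
align_time_base <- function(a, b) {
  check_traj(a); check_traj(b)
  if (abs(a$dt - b$dt) > 1e-9)
    stop_invalid("trajectories have different sampling periods")
  if (same_grid(a, b)) return(list(a = a, b = b))
  dt <- a$dt
  lo <- max(a$times[1], b$times[1])
  hi <- min(a$times[length(a$times)], b$times[length(b$times)])
  if (hi - lo < dt - 1e-12)
    stop_alignment("time supports overlap by fewer than 2 samples")
  grid <- seq(lo, lo + dt * floor((hi - lo) / dt + 1e-9), by = dt)
  list(a = interp_traj(a, grid), b = interp_traj(b, grid))
}

interp_traj <- function(traj, grid) {
  xyz <- vapply(1:3, function(j)
    stats::approx(traj$times, traj$xyz[, j], xout = grid, rule = 1)$y,
    numeric(length(grid)))
  trajectory(grid, xyz)
}

same_grid <- function(a, b) {
  length(a$times) == length(b$times) &&
    max(abs(a$times - b$times)) < 1e-9
}

check_traj <- function(x) {
  if (!inherits(x, "reach_trajectory"))
    stop_invalid("expected a 'reach_trajectory' object")
  invisible(x)
}

#' Average two trajectories into the shared avatar's hand path
#'
#' The shared avatar's hand position is the pointwise (equally weighted) mean
#' of the two members' hand positions on a common time base:
#' \eqn{p_{av}(t) = w\,p_a(t) + (1-w)\,p_b(t)} with \eqn{w = 1/2}.  Averaging
#' is done on the hand (end-effector) position in Cartesian space, since every
#' analysed quantity is a hand statistic.
#'
#' @param a,b \code{\link{trajectory}} objects on the same time base (use
#'   \code{\link{align_time_base}} first otherwise).
#' @param weight weight of member \code{a}; fixed at 0.5 in the shared-body
#'   design, exposed for extension.
#' @return A \code{\link{trajectory}} on the same time base.
#' @export
average_trajectories <- function(a, b, weight = 0.5) {
  check_traj(a); check_traj(b)
  if (!is.numeric(weight) || weight < 0 || weight > 1)
    stop_invalid("'weight' must be in [0, 1]")
  if (!same_grid(a, b))
    stop_invalid("trajectories are not on the same time base; call align_time_base()")
  new_traj(a$times, weight * a$xyz + (1 - weight) * b$xyz, a$dt)
}
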