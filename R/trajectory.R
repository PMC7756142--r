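#' Uniformly sampled 3-D hand trajectory
#'
#' Container for a hand path sampled uniformly in time: a strictly increasing
#' time vector with constant spacing and one 3-D position (metres) per stamp.
#' All hand, partner and avatar paths in the package are carried in this form.
#'
#' @param times numeric vector of sample times in seconds, uniformly spaced,
#'   length at least 2.
#' @param xyz numeric matrix with one row per time stamp and three columns
#'   (x, y, z) in metres.
#' @return An object of class \code{reach_trajectory}: a list with elements
#'   \code{times}, \code{xyz} and \code{dt}.
#' @export
trajectory <- function(times, xyz) {
  if (!is.numeric(times) || length(times) < 2L)
    stop_invalid("'times' must be a numeric vector of length >= 2")
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != length(times))
    stop_invalid("'xyz' must be a numeric matrix with 3 columns and one row per time stamp")
  if (any(!is.finite(times)) || any(!is.finite(xyz)))
    stop_invalid("trajectory contains non-finite values")
  dts <- diff(times)
  dt <- stats::median(dts)
  if (dt <= 0 || max(abs(dts - dt)) >= 1e-9)
    stop_invalid("'times' must be strictly increasing with uniform spacing")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(times = as.numeric(times), xyz = xyz, dt = dt),
            class = "reach_trajectory")
}

# fast constructor for internal hot paths: inputs already validated upstream
new_traj <- function(times, xyz, dt) {
  structure(list(times = times, xyz = xyz, dt = dt),
            class = "reach_trajectory")
}

#' @export
print.reach_trajectory <- function(x, ...) {
  cat(sprintf("<reach_trajectory: %d samples, dt = %g s, span [%.3f, %.3f] s>\n",
              length(x$times), x$dt, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_samples <- function(traj) length(traj$times)

# Quintic minimum-jerk position profile s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
mj_s <- function(tau) tau^3 * (10 + tau * (-15 + 6 * tau))
# ds/dtau; peak value 1.875 at tau = 1/2
mj_sdot <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
# d3s/dtau3
mj_sdddot <- function(tau) 60 - 360 * tau + 360 * tau^2

#' Minimum-jerk point-to-point trajectory
#'
#' The quintic profile that minimises integrated squared hand jerk for a
#' point-to-point reach: position
#' \eqn{p(\tau) = start + (end-start)(10\tau^3 - 15\tau^4 + 6\tau^5)} with
#' \eqn{\tau = t/duration}.  Velocity and acceleration vanish at both
#' boundaries; peak speed is \eqn{1.875\,L/T} at mid-reach.  This is the
#' noiseless base path of the simulator and the normative model of human
#' reaching.
#'
#' @param start,end numeric length-3 start and end positions (metres).
#' @param duration movement time in seconds; must be at least \code{2 * dt}.
#' @param dt sampling period in seconds.
#' @return A \code{\link{trajectory}} sampled at \code{0, dt, 2 dt, ...}
#'   covering \code{[0, duration]}.
#' @examples
#' tr <- min_jerk_traj(c(0, 0, 0), c(0.3, 0, 0), duration = 0.6, dt = 0.01)
#' max(sqrt(rowSums(apply(tr$xyz, 2, diff)^2)) / tr$dt)  # ~ 1.875 * 0.3 / 0.6
#' @export
min_jerk_traj <- function(start, end, duration, dt) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L)
    stop_invalid("'start' and 'end' must be length-3 numeric vectors")
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0)
    stop_invalid("'duration' and 'dt' must be positive")
  if (duration < 2 * dt)
    stop_invalid("'duration' must be at least 2 * dt")
  n <- floor(duration / dt + 1e-9)
  times <- (0:n) * dt
  tau <- times / duration
  s <- mj_s(tau)
  xyz <- cbind(x = start[1] + (end[1] - start[1]) * s,
               y = start[2] + (end[2] - start[2]) * s,
               z = start[3] + (end[3] - start[3]) * s)
  new_traj(times, xyz, dt)
}

#' Smooth (low-pass filtered) Gaussian motor noise
#'
#' Gaussian white noise convolved with a zero-phase Gaussian kernel of width
#' \code{tau} and rescaled to stationary standard deviation \code{sd}, so that
#' numerical third derivatives of the perturbed path remain finite as
#' \code{dt} shrinks.  Returns an n-by-3 matrix (independent per axis).
#'
#' @param n number of samples.
#' @param dt sampling period (s).
#' @param sd stationary standard deviation of the noise (m).
#' @param tau kernel time constant (s).
#' @return numeric n x 3 matrix.
#' @export
smooth_noise <- function(n, dt, sd, tau) {
  if (n < 1L) stop_invalid("'n' must be positive")
  if (sd < 0 || tau <= 0 || dt <= 0) stop_invalid("invalid noise parameters")
  if (sd == 0) {
    stats::rnorm(3L * n)            # consume the same draws as the sd > 0 path
    return(matrix(0, n, 3L))
  }
  half <- max(1L, ceiling(3 * tau / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = tau)
  k <- k / sqrt(sum(k^2))           # unit l2 norm: stationary sd preserved
  z <- matrix(stats::rnorm(3L * (n + 2L * half)), ncol = 3L)
  f <- stats::filter(z, k, method = "convolution", sides = 2)
  sd * matrix(as.numeric(f[(half + 1):(half + n), ]), ncol = 3L)
}
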