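# Embodiment rating generator: agency (0-100 %) and ownership (-3..+3
# Likert) drawn around configured condition means, with monotone links to
# the participant's own kinematics so that (i) ownership in the shared
# condition correlates positively with the avatar's reach deviation and
# (ii) the agency change correlates negatively with the jerk change.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate embodiment ratings from kinematic summaries
#'
#' One agency and one ownership rating per participant and condition.
#' Agency in the shared condition is drawn around
#' \code{agency_shared_mean} (strictly between 50 and 100) minus
#' \code{agency_link_slope} times the standardised jerk change
#' (J shared - J solo), so participants whose own hand became jerkier report
#' less agency; agency in the solo condition is drawn around
#' \code{agency_solo_mean} (below 100).  Ownership in the shared condition
#' is a linear monotone link of the participant's avatar reach deviation
#' (slope \code{rating_link_slope} per SD) plus noise, clipped and rounded
#' to the -3..+3 Likert scale.
#'
#' @param summary data frame with one row per participant x condition and
#'   columns \code{participant_id}, \code{dyad_id}, \code{condition}
#'   (\code{"solo"}/\code{"shared"}), \code{J}, and \code{D_avatar} (the
#'   dyad's avatar reach deviation; needed on shared rows).
#' @param cfg a \code{\link{sim_config}}.
#' @param round_likert discretise ownership to integer Likert steps
#'   (default TRUE); FALSE exposes the underlying continuous monotone link
#'   (useful to verify its rank correlation is exactly 1 at zero noise,
#'   which rounding-induced ties would otherwise mask).
#' @return data frame with columns \code{participant_id}, \code{dyad_id},
#'   \code{condition}, \code{agency} (percent in [0, 100]) and
#'   \code{ownership} (integer in [-3, 3]).
#' @export
generate_ratings <- function(summary, cfg, round_likert = TRUE) {
  need <- c("participant_id", "dyad_id", "condition", "J", "D_avatar")
  if (!all(need %in% names(summary))) stop_invalid("missing columns in 'summary'")
  has_both <- tapply(summary$condition, summary$participant_id,
                     function(cc) all(c("solo", "shared") %in% cc))
  if (!all(has_both))
    stop_invalid(paste("missing condition for participant(s):",
                       paste(names(has_both)[!has_both], collapse = ", ")))
  solo <- summary[summary$condition == "solo", ]
  shared <- summary[summary$condition == "shared", ]
  shared <- shared[match(solo$participant_id, shared$participant_id), ]
  np <- nrow(solo)
  dJ <- zscore(shared$J - solo$J)
  zD <- zscore(shared$D_avatar)
  agency_solo <- clip(stats::rnorm(np, cfg$agency_solo_mean,
                                   cfg$agency_noise_sd), 0, 100)
  agency_shared <- clip(cfg$agency_shared_mean - cfg$agency_link_slope * dJ +
                          stats::rnorm(np, 0, cfg$agency_noise_sd), 0, 100)
  own_solo <- clip(stats::rnorm(np, cfg$ownership_solo_mean,
                                cfg$rating_noise_sd), -3, 3)
  own_shared <- clip(cfg$ownership_shared_mean + cfg$rating_link_slope * zD +
                       stats::rnorm(np, 0, cfg$rating_noise_sd), -3, 3)
  if (round_likert) {
    own_solo <- round(own_solo)
    own_shared <- round(own_shared)
  }
  out <- rbind(
    data.frame(participant_id = solo$participant_id, dyad_id = solo$dyad_id,
               condition = "solo", agency = agency_solo, ownership = own_solo),
    data.frame(participant_id = solo$participant_id, dyad_id = solo$dyad_id,
               condition = "shared", agency = agency_shared,
               ownership = own_shared))
  rownames(out) <- NULL
  out
}
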