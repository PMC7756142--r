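# Trajectory / ratings CSV dialect and tidy outputs.
#
# Trajectory CSV: one row per sample, UTF-8, "." decimal, header required:
#   dyad_id, participant_id, actor{human|avatar}, condition{solo|shared},
#   session, trial, t_s, x_m, y_m, z_m,
#   target_x_m, target_y_m, target_z_m, target_edge_m, target_onset_s
# Coordinates are right-handed metres, participant-facing +y forward
# (convention documented, not asserted).

traj_csv_cols <- c("dyad_id", "participant_id", "actor", "condition",
                   "session", "trial", "t_s", "x_m", "y_m", "z_m",
                   "target_x_m", "target_y_m", "target_z_m",
                   "target_edge_m", "target_onset_s")

#' Write reach trials to the trajectory CSV dialect
#'
#' @param trials list of \code{\link{reach_trial}} objects (or a
#'   \code{dyad_experiment}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trials, path) {
  if (inherits(trials, "dyad_experiment")) trials <- trials$trials
  blocks <- lapply(trials, function(tr) {
    n <- length(tr$trajectory$times)
    data.frame(dyad_id = tr$dyad_id, participant_id = tr$participant_id,
               actor = if (identical(tr$participant_id, "avatar")) "avatar" else "human",
               condition = tr$condition, session = tr$session,
               trial = tr$trial_index, t_s = tr$trajectory$times,
               x_m = tr$trajectory$xyz[, 1], y_m = tr$trajectory$xyz[, 2],
               z_m = tr$trajectory$xyz[, 3],
               target_x_m = tr$target$position[1],
               target_y_m = tr$target$position[2],
               target_z_m = tr$target$position[3],
               target_edge_m = tr$target$edge_length,
               target_onset_s = tr$target$onset_time)
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Read reach trials from the trajectory CSV dialect
#'
#' Validates the schema and rebuilds one \code{\link{reach_trial}} per
#' (dyad, participant, condition, session, trial) block.  Rows are assumed
#' already segmented (spanning onset to touch); use \code{resegment = TRUE}
#' to re-apply the touch rule instead.
#'
#' @param path CSV file in the package dialect.
#' @param resegment re-run \code{\link{segment_reach}} on each block.
#' @return list of \code{\link{reach_trial}} objects.
#' @export
read_trajectories <- function(path, resegment = FALSE) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_parse(paste("cannot parse CSV:",
                                                      conditionMessage(e))))
  missing_cols <- setdiff(traj_csv_cols, names(df))
  if (length(missing_cols))
    stop_parse(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  num_cols <- c("t_s", "x_m", "y_m", "z_m", "target_x_m", "target_y_m",
                "target_z_m", "target_edge_m", "target_onset_s")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop_parse(sprintf("non-numeric values in column %s (e.g. line %d)",
                         cc, bad[1] + 1L))
    if (anyNA(v))
      stop_parse(sprintf("missing values in column %s (e.g. line %d)",
                         cc, which(is.na(v))[1] + 1L))
    df[[cc]] <- v
  }
  if (!all(df$condition %in% c("solo", "shared")))
    stop_parse("column condition must be 'solo' or 'shared'")
  if (!all(df$actor %in% c("human", "avatar")))
    stop_parse("column actor must be 'human' or 'avatar'")
  key <- interaction(df$dyad_id, df$participant_id, df$condition,
                     df$session, df$trial, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$t_s), ]
    target <- target_spec(c(g$target_x_m[1], g$target_y_m[1], g$target_z_m[1]),
                          g$target_edge_m[1], g$target_onset_s[1])
    traj <- trajectory(g$t_s, cbind(g$x_m, g$y_m, g$z_m))
    if (resegment)
      segment_reach(traj, target, dyad_id = g$dyad_id[1],
                    participant_id = g$participant_id[1],
                    condition = g$condition[1], session = g$session[1],
                    trial_index = g$trial[1])
    else
      reach_trial(traj, target, onset_time = g$t_s[1],
                  touch_time = g$t_s[nrow(g)], dyad_id = g$dyad_id[1],
                  participant_id = g$participant_id[1],
                  condition = g$condition[1], session = g$session[1],
                  trial_index = g$trial[1])
  })
}

#' Write / read the ratings CSV
#'
#' Columns: participant_id, dyad_id, condition, agency, ownership.
#'
#' @param ratings data frame as from \code{\link{generate_ratings}}.
#' @param path file path.
#' @return \code{path} (write) or the validated data frame (read).
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "dyad_id", "condition", "agency", "ownership")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_parse(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  if (any(df$agency < 0 | df$agency > 100, na.rm = TRUE))
    stop_parse("agency outside [0, 100]")
  if (any(df$ownership < -3 | df$ownership > 3, na.rm = TRUE))
    stop_parse("ownership outside [-3, 3]")
  df
}

#' Write the tidy metrics / IP tables as TSV
#'
#' @param metrics a \code{\link{compute_metrics}} result.
#' @param metrics_path,ip_path output paths.
#' @return invisibly, the two paths.
#' @export
write_metrics_tsv <- function(metrics, metrics_path, ip_path) {
  long <- stats::reshape(metrics$metrics, direction = "long",
                         varying = c("D", "J", "RT", "TT", "TE"),
                         v.names = "value", timevar = "metric",
                         times = c("D", "J", "RT", "TT", "TE"))
  long <- long[order(long$dyad_id, long$participant_id, long$condition,
                     long$session, long$trial, long$metric),
               c("dyad_id", "participant_id", "actor", "condition",
                 "session", "trial", "metric", "value")]
  utils::write.table(long, metrics_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(metrics$ip, ip_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(metrics_path, ip_path))
}
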