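# Pipeline driver: one config file -> simulate (or load) -> segment ->
# avatar -> metrics -> statistics -> report + figures, reproducibly.

#' Build / load a run configuration
#'
#' A run config is a list with fields \code{mode} ("simulate" or
#' "analyze"), \code{sim} (\code{\link{sim_config}} fields, simulate mode),
#' \code{io} (paths: \code{trajectories}, \code{ratings} for analyze mode;
#' \code{out_dir} for artifacts), \code{kinematics}
#' (\code{jerk_estimator}, \code{ip_window}), \code{stats} (\code{alpha},
#' \code{d_type}) and \code{seed}.  YAML and JSON files are supported.
#'
#' @param x path to a YAML/JSON file, or a list.
#' @param seed optional seed override (e.g. from the command line).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(x, seed = NULL) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop_parse(sprintf("config file not found: %s", x))
    if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else if (is.list(x)) x else stop_invalid("config must be a path or a list")
  cfg$mode <- if (is.null(cfg$mode)) "simulate" else cfg$mode
  if (!cfg$mode %in% c("simulate", "analyze"))
    stop_invalid("mode must be 'simulate' or 'analyze'")
  if (!is.null(seed)) cfg$seed <- seed
  if (cfg$mode == "simulate") {
    sim <- as.list(cfg$sim)
    if (!is.null(cfg$seed)) sim$seed <- cfg$seed
    if (is.null(sim$seed)) stop_invalid("'seed' is mandatory for simulate mode")
    cfg$sim <- do.call(sim_config, sim)
    cfg$seed <- cfg$sim$seed
  } else {
    if (is.null(cfg$io$trajectories) || !file.exists(cfg$io$trajectories))
      stop_parse("analyze mode needs an existing io$trajectories path")
    if (!is.null(cfg$io$ratings) && !file.exists(cfg$io$ratings))
      stop_parse("io$ratings path does not exist")
  }
  k <- cfg$kinematics
  cfg$kinematics <- list(
    jerk_estimator = if (is.null(k$jerk_estimator)) "central" else k$jerk_estimator,
    ip_window = if (is.null(k$ip_window)) "union" else k$ip_window)
  s <- cfg$stats
  alpha <- if (is.null(s$alpha)) 0.05 else as.numeric(s$alpha)
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  cfg$stats <- list(alpha = alpha,
                    d_type = if (is.null(s$d_type)) "dz" else s$d_type)
  structure(cfg, class = "run_config")
}

# deterministic config fingerprint without external digest dependencies
# (polynomial rolling hash mod 2^31 - 1)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "io")]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' simulate mode: generate the synthetic experiment, compute metrics and the
#' statistical battery.  analyze mode: read trajectory (and optional
#' ratings) CSVs instead.  Writes four artifacts to \code{out_dir}:
#' \code{metrics.tsv}, \code{ip.tsv}, \code{stats_report.tsv} (plus a
#' human-readable \code{stats_report.txt}) and \code{manifest.json}
#' (config hash, seed, package version, excluded-trial counts).  Everything
#' except time stamps is fully determined by config + seed.
#'
#' @param cfg a \code{\link{run_config}} (or path / list coercible to one).
#' @param out_dir output directory; default the config's
#'   \code{io$out_dir}, or no files if neither is given.
#' @param seed optional seed override.
#' @param figures also write figure PDFs (default FALSE; see
#'   \code{\link{make_figures}}).
#' @return object of class \code{reach_run}: list with \code{experiment}
#'   (simulate mode), \code{trials}, \code{metrics}, \code{ratings},
#'   \code{battery}, \code{excluded}, \code{config}, \code{artifacts}.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, seed = NULL, figures = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg, seed = seed)
  else if (!is.null(seed)) cfg <- run_config(unclass(cfg), seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, sharedreach_error = function(e) {
      e$message <- sprintf("[%s] %s", name, conditionMessage(e))
      stop(e)
    })
  }
  if (cfg$mode == "simulate") {
    experiment <- stage("simulate", generate_dyad_experiment(cfg$sim))
    trials <- experiment$trials
    ratings <- experiment$ratings
    excluded <- experiment$excluded
  } else {
    experiment <- NULL
    trials <- stage("read", read_trajectories(cfg$io$trajectories))
    ratings <- if (!is.null(cfg$io$ratings))
      stage("read", read_ratings(cfg$io$ratings)) else NULL
    excluded <- data.frame()
  }
  metrics <- if (!is.null(experiment$metrics) &&
                   cfg$kinematics$jerk_estimator == "central" &&
                   cfg$kinematics$ip_window == "union") {
    experiment$metrics      # already computed with default options
  } else {
    stage("metrics",
          compute_metrics(trials,
                          jerk_estimator = cfg$kinematics$jerk_estimator,
                          ip_window = cfg$kinematics$ip_window))
  }
  battery <- if (!is.null(ratings))
    stage("stats", run_test_battery(metrics, ratings,
                                    alpha = cfg$stats$alpha,
                                    d_type = cfg$stats$d_type)) else NULL
  if (is.null(out_dir)) out_dir <- cfg$io$out_dir
  artifacts <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(out_dir, "metrics.tsv")
    ip <- file.path(out_dir, "ip.tsv")
    write_metrics_tsv(metrics, mp, ip)
    artifacts <- c(metrics = mp, ip = ip)
    if (!is.null(battery)) {
      sp <- file.path(out_dir, "stats_report.tsv")
      utils::write.table(summary(battery), sp, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      tp <- file.path(out_dir, "stats_report.txt")
      con <- file(tp, "w"); sink(con); print(battery); sink(); close(con)
      artifacts <- c(artifacts, stats_tsv = sp, stats_txt = tp)
    }
    manifest <- list(
      package = "sharedreach",
      version = as.character(utils::packageVersion("sharedreach")),
      mode = cfg$mode, seed = cfg$seed, config_hash = config_hash(cfg),
      n_trials = length(trials), n_excluded_no_touch = nrow(excluded),
      alpha = cfg$stats$alpha)
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    artifacts <- c(artifacts, manifest = mf)
  }
  run <- structure(list(experiment = experiment, trials = trials,
                        metrics = metrics, ratings = ratings,
                        battery = battery, excluded = excluded,
                        config = cfg, artifacts = artifacts),
                   class = "reach_run")
  if (figures && !is.null(out_dir))
    run$artifacts <- c(run$artifacts, make_figures(run, out_dir))
  run
}

#' @export
print.reach_run <- function(x, ...) {
  cat(sprintf("<reach_run: %s mode, %d trials, %d excluded>\n",
              x$config$mode, length(x$trials), nrow(x$excluded)))
  if (!is.null(x$battery)) print(x$battery)
  invisible(x)
}

#' Condition means with standard errors over analysis units
#'
#' @param values named list of per-unit vectors.
#' @return data frame with mean and SE (sd over units / sqrt(n)).
#' @export
mean_se <- function(values) {
  data.frame(group = names(values),
             mean = vapply(values, mean, numeric(1)),
             se = vapply(values, function(v) stats::sd(v) / sqrt(length(v)),
                         numeric(1)),
             n = vapply(values, length, numeric(1)))
}

#' Figures analogous to the study's result panels
#'
#' Bar plots of unit-level means +/- SE (agency/ownership by condition; D,
#' J, TE across solo human / shared human / shared avatar; TT and RT solo
#' human vs shared avatar; IP overall and by phase) and the two rank
#' correlation scatter plots.  Written as PDFs.
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @param dir output directory.
#' @return named character vector of files written.
#' @export
make_figures <- function(run, dir) {
  if (is.null(run$metrics) || !nrow(run$metrics$metrics))
    stop_no_data("empty metrics table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  agg_h <- aggregate_metrics(run$metrics, level = "dyad", actor = "human")
  agg_a <- aggregate_metrics(run$metrics, level = "dyad", actor = "avatar")
  files <- character()
  bar <- function(fname, values, ylab, main) {
    f <- file.path(dir, fname)
    grDevices::pdf(f, width = 4.5, height = 4)
    ms <- mean_se(values)
    bp <- graphics::barplot(ms$mean, names.arg = ms$group, ylab = ylab,
                            main = main,
                            ylim = c(min(0, min(ms$mean - ms$se)),
                                     1.15 * max(ms$mean + ms$se)))
    graphics::arrows(bp, ms$mean - ms$se, bp, ms$mean + ms$se,
                     angle = 90, code = 3, length = 0.05)
    grDevices::dev.off()
    files[fname] <<- f
  }
  three <- function(metric) {
    w <- metric_wide(agg_h, agg_a, metric)
    list("solo\nhuman" = w[, 1], "shared\nhuman" = w[, 2],
         "shared\navatar" = w[, 3])
  }
  bar("fig_deviation.pdf", three("D"), "reach deviation D (m)",
      "Reach deviation")
  bar("fig_jerk.pdf", three("J"), "mean hand jerk (m/s^3)", "Mean hand jerk")
  bar("fig_target_error.pdf", three("TE"), "target error (m)", "Target error")
  w_tt <- metric_wide(agg_h, agg_a, "TT"); w_rt <- metric_wide(agg_h, agg_a, "RT")
  bar("fig_task_time.pdf", list("solo\nhuman" = w_tt[, 1],
                                "shared\navatar" = w_tt[, 3]),
      "task time (s)", "Task time")
  bar("fig_reaction_time.pdf", list("solo\nhuman" = w_rt[, 1],
                                    "shared\navatar" = w_rt[, 3]),
      "reaction time (s)", "Reaction time")
  ipd <- aggregate_ip(run$metrics)
  sp <- split(ipd, ipd$condition)
  bar("fig_ip.pdf", list(solo = sp$solo$overall, shared = sp$shared$overall),
      "inter-participant distance (m)", "IP (full reach)")
  bar("fig_ip_phases.pdf",
      list("solo\np1" = sp$solo$phase1, "shared\np1" = sp$shared$phase1,
           "solo\np2" = sp$solo$phase2, "shared\np2" = sp$shared$phase2,
           "solo\np3" = sp$solo$phase3, "shared\np3" = sp$shared$phase3),
      "inter-participant distance (m)", "IP by movement phase")
  if (!is.null(run$ratings)) {
    r <- run$ratings
    bar("fig_agency.pdf",
        list(solo = r$agency[r$condition == "solo"],
             shared = r$agency[r$condition == "shared"]),
        "sense of agency (%)", "Sense of agency")
    bar("fig_ownership.pdf",
        list(solo = r$ownership[r$condition == "solo"],
             shared = r$ownership[r$condition == "shared"]),
        "sense of ownership (-3..3)", "Sense of ownership")
    if (!is.null(run$battery)) {
      rh <- r[r$condition == "shared", ]
      d_av <- agg_a$D[match(rh$dyad_id, agg_a$dyad_id)]
      f <- file.path(dir, "fig_corr_ownership_D.pdf")
      grDevices::pdf(f, width = 4.5, height = 4)
      graphics::plot(d_av, rh$ownership, xlab = "avatar reach deviation (m)",
                     ylab = "ownership (shared)",
                     main = sprintf("rho = %.3f",
                                    run$battery$analyses$corr_ownership_D$result$statistic))
      grDevices::dev.off()
      files["fig_corr_ownership_D.pdf"] <- f
    }
  }
  files
}
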