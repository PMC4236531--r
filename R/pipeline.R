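#' Configuration of a full capability-gap run
#'
#' @param model an [msk_model()] or path to a model YAML file; default the
#'   shipped planar9 model.
#' @param profiles list of [adl_profile()]s, paths, or `NULL` for the five
#'   shipped fixtures.
#' @param levels weakness levels in `[0, 1]` (non-empty).
#' @param threshold gap-detection threshold (Nm/kg), `> 0`.
#' @param seed integer seed for trial generation.
#' @param n_trials synthetic trials per activity; with `noise_sd > 0` their
#'   spread replaces the across-subject variability of an experimental
#'   cohort.
#' @param noise_sd trial-to-trial amplitude noise; `NULL` keeps each
#'   profile's own value.
#' @param reserve_optimal_moment reserves' optimal moment tau0 (Nm).
#' @param out_dir output directory, or `NULL` for no file output.
#' @param format `"csv"` or `"sto"` for the per-frame exports.
#' @param write_series also export per-frame gap series.
#' @return an object of class `run_config`.
#' @export
run_config <- function(model = NULL, profiles = NULL,
                       levels = seq(0, 1, by = 0.1), threshold = 0.01,
                       seed = 1L, n_trials = 1L, noise_sd = NULL,
                       reserve_optimal_moment = 1,
                       out_dir = NULL, format = c("csv", "sto"),
                       write_series = FALSE) {
  if (length(levels) == 0L) stop("levels must be non-empty")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (threshold <= 0) stop("threshold must be > 0")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (is.character(model)) model <- read_msk_model(model)
  if (is.null(model)) model <- default_model()
  if (is.null(profiles)) profiles <- default_profiles()
  profiles <- lapply(profiles, function(p) {
    if (is.character(p)) read_adl_profile(p) else p
  })
  structure(list(model = model, profiles = profiles, levels = sort(levels),
                 threshold = threshold, seed = as.integer(seed),
                 n_trials = as.integer(n_trials), noise_sd = noise_sd,
                 reserve_optimal_moment = reserve_optimal_moment,
                 out_dir = out_dir, format = match.arg(format),
                 write_series = write_series),
            class = "run_config")
}

#' Run the full capability-gap pipeline
#'
#' For every activity profile: generate the synthetic trial(s), sweep the
#' weakness levels through the static optimization, and assemble the
#' tolerance report.  When an output directory is configured, writes the
#' report CSV, a run manifest (configuration echo, package version, seed)
#' and optionally per-frame gap series.  Deterministic: rerunning with the
#' same configuration and seed reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return a [tolerance_report()]; the underlying sweeps are attached as
#'   attribute `"sweeps"` (first trial of each activity).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sweeps <- list(); all_sweeps <- list()
  for (p in config$profiles) {
    for (rep in seq_len(config$n_trials)) {
      trial <- generate_trial(p, config$model,
                              seed = config$seed + 1000L * (rep - 1L),
                              noise_sd = config$noise_sd)
      sw <- weakness_sweep(config$model, trial, config$levels,
                           config$reserve_optimal_moment)
      all_sweeps[[length(all_sweeps) + 1L]] <- sw
      if (rep == 1L) sweeps[[p$activity]] <- sw
    }
  }
  report <- tolerance_report(all_sweeps, config$threshold)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report),
              file.path(config$out_dir, "capability_gap_report.csv"),
              row.names = FALSE)
    write.csv(attr(report, "summary"),
              file.path(config$out_dir, "tolerance_summary.csv"),
              row.names = FALSE)
    manifest <- list(
      package = "capgap",
      version = as.character(utils::packageVersion("capgap")),
      seed = config$seed, levels = config$levels,
      threshold = config$threshold, n_trials = config$n_trials,
      reserve_optimal_moment = config$reserve_optimal_moment,
      model = config$model$name, body_mass = config$model$body_mass,
      activities = vapply(config$profiles, `[[`, character(1), "activity"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    if (config$write_series) {
      for (a in names(sweeps)) {
        sw <- sweeps[[a]]
        for (i in seq_along(sw$levels)) {
          for (d in names(sw$series[[i]])) {
            s <- sw$series[[i]][[d]]
            fn <- sprintf("gap_%s_%s_%s.%s", a, d, format_level(sw$levels[i]),
                          config$format)
            if (config$format == "sto") {
              write_sto(s[c("time", "task_moment", "capability_moment",
                            "gap_moment", "gap_power")],
                        file.path(config$out_dir, fn), name = fn)
            } else {
              write.csv(s, file.path(config$out_dir, fn), row.names = FALSE)
            }
          }
        }
      }
    }
  }
  attr(report, "sweeps") <- sweeps
  report
}
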