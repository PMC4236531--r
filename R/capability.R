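#' Capability-gap time series for one DOF
#'
#' The capability gap is the task's net joint moment minus the
#' muscle-generated moment, i.e. exactly the moment carried by the DOF's
#' ideal moment actuator in the static optimization.  All quantities are
#' mass-normalized; gap power is the gap moment times the joint angular
#' velocity.
#'
#' @param solutions a `trial_solution` from [solve_trial()].
#' @param trial the [trial_data()] the solutions were computed from.
#' @param dof DOF name.
#' @param weakness weakness fraction the solutions were computed at (stored
#'   for reporting).
#' @return an object of class `capgap_series`: data.frame with columns
#'   `time`, `percent_cycle`, `task_moment`, `capability_moment`,
#'   `gap_moment` (Nm/kg), `gap_power` (W/kg) plus attributes `dof` and
#'   `weakness`.
#' @export
capability_gap <- function(solutions, trial, dof, weakness = NA_real_) {
  stopifnot(inherits(solutions, "trial_solution"), inherits(trial, "trial_data"))
  if (!dof %in% colnames(solutions$reserve_moments)) {
    stop(sprintf("no reserve actuator for DOF '%s'", dof))
  }
  if (nrow(solutions$reserve_moments) != length(trial$time)) {
    stop("solutions do not align with trial frames")
  }
  task <- normalize_by_mass(trial$net_moments[, dof], trial$body_mass)
  gap <- normalize_by_mass(solutions$reserve_moments[, dof], trial$body_mass)
  out <- data.frame(time = trial$time,
                    percent_cycle = trial$percent_cycle,
                    task_moment = task,
                    capability_moment = task - gap,
                    gap_moment = gap,
                    gap_power = joint_power(gap, trial$angular_velocities[, dof]))
  structure(out, dof = dof, weakness = weakness,
            activity = trial$activity,
            class = c("capgap_series", "data.frame"))
}

#' Sweep simulated muscle weakness
#'
#' For each weakness level: scale every muscle's maximal isometric force by
#' `1 - w` ([apply_weakness()]), re-solve the static optimization for the
#' whole trial, and extract the capability-gap series of every DOF.
#'
#' @param model an [msk_model()] at full strength.
#' @param trial a [trial_data()].
#' @param levels weakness fractions in `[0, 1]`, default 0 to 1 in steps of
#'   0.1.
#' @param reserve_optimal_moment reserves' optimal moment tau0 (Nm).
#' @return an object of class `capgap_sweep`: list with `activity`, `levels`,
#'   `trial`, and `series[[level]][[dof]]` capability-gap series.
#' @export
weakness_sweep <- function(model, trial, levels = seq(0, 1, by = 0.1),
                           reserve_optimal_moment = 1) {
  if (any(levels < 0 | levels > 1)) stop("weakness levels must lie in [0, 1]")
  levels <- sort(levels)
  series <- vector("list", length(levels))
  names(series) <- format_level(levels)
  for (i in seq_along(levels)) {
    weakened <- apply_weakness(model, levels[i])
    sol <- tryCatch(
      solve_trial(weakened, trial, reserve_optimal_moment),
      error = function(e) stop(sprintf("weakness level %.2f: %s",
                                       levels[i], conditionMessage(e)), call. = FALSE))
    series[[i]] <- setNames(
      lapply(model$dofs$name, function(d) capability_gap(sol, trial, d, levels[i])),
      model$dofs$name)
  }
  structure(list(activity = trial$activity, levels = levels, series = series,
                 trial = trial),
            class = "capgap_sweep")
}

format_level <- function(levels) sprintf("w%03.0f", 100 * levels)

#' @export
print.capgap_sweep <- function(x, ...) {
  cat(sprintf("<capgap_sweep> %s: %d frames, weakness levels %s\n",
              x$activity, length(x$trial$time),
              paste(sprintf("%.0f%%", 100 * x$levels), collapse = " ")))
  for (d in names(x$series[[1]])) {
    pk <- vapply(x$series, function(s) max(abs(s[[d]]$gap_moment)), numeric(1))
    cat(sprintf("  %-6s peak |gap| (Nm/kg): %s\n", d,
                paste(sprintf("%.2f", pk), collapse = " ")))
  }
  invisible(x)
}

#' Detect a capability gap in a series
#'
#' The quadratically costly reserve always carries a tiny moment (the
#' gain-ratio "leak"), so "a gap is present" needs a cutoff.  A gap is
#' detected when any frame's gap moment magnitude exceeds `threshold`
#' (default 0.01 Nm/kg, about 1 Nm for a 100 kg user); the exceeding frames
#' are reported.  `direction` restricts detection to positive or negative
#' gap moments.
#'
#' @param series a `capgap_series` from [capability_gap()].
#' @param threshold detection threshold (Nm/kg), `> 0`.
#' @param direction `"any"`, `"positive"` or `"negative"`.
#' @return list with `detected` (logical), `frames` (indices) and
#'   `percent_cycle` of the exceeding frames.
#' @export
detect_gap <- function(series, threshold = 0.01, direction = "any") {
  stopifnot(inherits(series, "capgap_series"))
  if (threshold <= 0) stop("threshold must be > 0")
  direction <- match.arg(direction, c("any", "positive", "negative"))
  g <- series$gap_moment
  hit <- switch(direction,
                any = abs(g) > threshold,
                positive = g > threshold,
                negative = g < -threshold)
  idx <- which(hit)
  list(detected = length(idx) > 0, frames = idx,
       percent_cycle = series$percent_cycle[idx])
}

#' Weakness-tolerance level
#'
#' The lowest weakness level in a sweep at which a capability gap is detected
#' for a DOF and moment direction -- the level of muscle weakness from which
#' the task demand can no longer be met by active muscle force in that
#' direction.
#'
#' @param sweep a `capgap_sweep`.
#' @param dof DOF name.
#' @param direction `"positive"`, `"negative"` or `"any"`.
#' @param threshold gap-detection threshold (Nm/kg).
#' @return the smallest weakness fraction with a detected gap, or `NA` if no
#'   level in the sweep shows one.
#' @export
tolerance_level <- function(sweep, dof, direction = "any", threshold = 0.01) {
  stopifnot(inherits(sweep, "capgap_sweep"))
  if (length(sweep$levels) < 2L) stop("sweep needs at least 2 levels")
  for (i in seq_along(sweep$levels)) {
    if (detect_gap(sweep$series[[i]][[dof]], threshold, direction)$detected) {
      return(sweep$levels[i])
    }
  }
  NA_real_
}

#' Maximal task requirements of a trial
#'
#' Direction-resolved maxima of the mass-normalized net joint moments and of
#' the joint powers over all frames.
#'
#' @param trial a [trial_data()].
#' @return data.frame with one row per DOF: `max_moment_pos`,
#'   `max_moment_neg` (Nm/kg, both reported as magnitudes), `max_power_pos`
#'   and `max_power_neg` (W/kg, magnitudes).
#' @export
max_requirements <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  dofs <- colnames(trial$net_moments)
  mom <- normalize_by_mass(trial$net_moments, trial$body_mass)
  pow <- joint_power(mom, trial$angular_velocities)
  data.frame(
    dof = dofs,
    max_moment_pos = apply(mom, 2, function(x) max(c(x, 0))),
    max_moment_neg = apply(mom, 2, function(x) max(c(-x, 0))),
    max_power_pos = apply(pow, 2, function(x) max(c(x, 0))),
    max_power_neg = apply(pow, 2, function(x) max(c(-x, 0))),
    row.names = NULL)
}

#' Compare inverse-dynamics sizing with assistance-as-needed sizing
#'
#' Inverse-dynamics (ID) sizing takes the peak task moment as the required
#' assistive moment; assistance-as-needed (AAN) sizing takes the peak
#' capability gap at the given weakness level.  The AAN peak can never
#' exceed the ID peak, and at intermediate weakness the assistance is also
#' targeted in time: the support fraction is the share of the cycle during
#' which the gap exceeds the detection threshold.
#'
#' @param sweep a `capgap_sweep`.
#' @param dof DOF name.
#' @param level weakness level present in the sweep.
#' @param threshold gap-detection threshold (Nm/kg).
#' @return list with `id_peak` (Nm/kg), `aan_peak` (Nm/kg) and
#'   `aan_support_fraction` (% of frames).
#' @export
id_vs_aan <- function(sweep, dof, level, threshold = 0.01) {
  stopifnot(inherits(sweep, "capgap_sweep"))
  i <- match(TRUE, abs(sweep$levels - level) < 1e-9)
  if (is.na(i)) stop("level not present in the sweep")
  s <- sweep$series[[i]][[dof]]
  list(id_peak = max(abs(s$task_moment)),
       aan_peak = max(abs(s$gap_moment)),
       aan_support_fraction = 100 * mean(abs(s$gap_moment) > threshold))
}

#' Tolerance and peak-assistance report over activities
#'
#' Summarizes a set of weakness sweeps (one per activity) the way exoskeleton
#' sizing needs them: per activity, DOF, moment direction and weakness level,
#' the peak gap moment and gap power, whether a gap is detected, and the
#' per-direction weakness tolerance and maximal task requirement.
#'
#' @param sweeps list of `capgap_sweep` objects (one per activity).
#' @param threshold gap-detection threshold (Nm/kg).
#' @return an object of class `tolerance_report`: data.frame with one row per
#'   (activity, dof, direction, weakness level) and a `summary` attribute
#'   with per-(activity, dof, direction) tolerance and maxima.
#' @export
tolerance_report <- function(sweeps, threshold = 0.01) {
  rows <- list(); srows <- list()
  for (sw in sweeps) {
    dofs <- names(sw$series[[1]])
    req <- max_requirements(sw$trial)
    for (d in dofs) {
      for (dir in c("positive", "negative")) {
        sgn <- if (dir == "positive") 1 else -1
        pg <- vapply(sw$series, function(s) {
          max(c(sgn * s[[d]]$gap_moment, 0))
        }, numeric(1))
        pp <- vapply(sw$series, function(s) {
          max(c(sgn * s[[d]]$gap_power, 0))
        }, numeric(1))
        det <- pg > threshold
        rows[[length(rows) + 1L]] <- data.frame(
          activity = sw$activity, dof = d, direction = dir,
          weakness = sw$levels, peak_gap_moment = unname(pg),
          peak_gap_power = unname(pp), gap_detected = unname(det))
        tol <- if (any(det)) sw$levels[which(det)[1]] else NA_real_
        r <- req[req$dof == d, ]
        srows[[length(srows) + 1L]] <- data.frame(
          activity = sw$activity, dof = d, direction = dir,
          tolerance_weakness = tol,
          max_gap_moment = max(pg), max_gap_power = max(pp),
          max_task_moment = if (dir == "positive") r$max_moment_pos else r$max_moment_neg,
          max_task_power = if (dir == "positive") r$max_power_pos else r$max_power_neg)
      }
    }
  }
  structure(do.call(rbind, rows),
            summary = do.call(rbind, srows),
            threshold = threshold,
            class = c("tolerance_report", "data.frame"))
}

#' @export
print.tolerance_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<tolerance_report> %d activities, gap threshold %.3g Nm/kg\n",
              length(unique(x$activity)), attr(x, "threshold")))
  print.data.frame(s, digits = 3)
  invisible(x)
}

#' Plot a weakness sweep for one DOF
#'
#' Task-requirement curve plus the capability-gap curves of every weakness
#' level, over the movement cycle.
#'
#' @param x a `capgap_sweep`.
#' @param dof DOF name (default: first DOF).
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.capgap_sweep <- function(x, dof = NULL, ...) {
  dof <- dof %||% names(x$series[[1]])[1]
  s0 <- x$series[[1]][[dof]]
  ylim <- range(0, s0$task_moment,
                vapply(x$series, function(s) range(s[[dof]]$gap_moment), numeric(2)))
  plot(s0$percent_cycle, s0$task_moment, type = "l", lwd = 2, lty = 2,
       xlab = "% cycle", ylab = "moment (Nm/kg)",
       main = sprintf("%s, %s", x$activity, dof), ylim = ylim, ...)
  greys <- grDevices::grey(seq(0.75, 0, length.out = length(x$levels)))
  for (i in seq_along(x$levels)) {
    lines(x$series[[i]][[dof]]$percent_cycle, x$series[[i]][[dof]]$gap_moment,
          col = greys[i])
  }
  legend("topleft", bty = "n", lwd = c(2, 1, 1), lty = c(2, 1, 1),
         col = c("black", greys[1], greys[length(greys)]),
         legend = c("task requirement", "gap, weakest sweep level", "gap, 100% weakness"))
  invisible(x)
}
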