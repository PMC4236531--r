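#' Parametric profile of a synthetic ADL trial
#'
#' Describes one activity of daily living as closed-form joint-angle
#' trajectories (truncated Fourier series for the cyclic activities, logistic
#' transitions for the chair activities) plus per-DOF net-moment waveforms
#' (sums of Gaussian bumps over the movement cycle, in Nm/kg).  Shipped
#' fixture profiles cover gait, stair ascent/descent, sit-to-stand and
#' stand-to-sit with peak moment magnitudes in the range reported for healthy
#' adults (about 0.1-1.7 Nm/kg).
#'
#' @param x a named list following the profile YAML schema (see the files
#'   under `extdata/profiles`).
#' @return an object of class `adl_profile`.
#' @export
adl_profile <- function(x) {
  stopifnot(is.list(x), !is.null(x$activity))
  x$activity <- match.arg(x$activity, c("gait", "stair_ascent", "stair_descent",
                                        "sit_to_stand", "stand_to_sit"))
  x$cyclic <- x$cyclic %||% (x$activity %in% c("gait", "stair_ascent", "stair_descent"))
  x$sampling_rate <- x$sampling_rate %||% 100
  x$noise_sd <- x$noise_sd %||% 0
  if (is.null(x$duration) || x$duration <= 0) stop("profile needs a positive duration")
  if (x$sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (x$noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(x$angles) || is.null(x$moments)) {
    stop("profile needs 'angles' and 'moments' blocks")
  }
  # peak mass-normalized moment targets implied by the bump definitions
  x$moment_scale <- vapply(names(x$moments), function(d) {
    xx <- seq(0, 1, length.out = 501)
    max(abs(compose_bumps(x$moments[[d]], xx, x$cyclic)))
  }, numeric(1))
  structure(x, class = "adl_profile")
}

#' @export
print.adl_profile <- function(x, ...) {
  cat(sprintf("<adl_profile> %s: %.2f s @ %.0f Hz, %s, noise_sd %.2f\n",
              x$activity, x$duration, x$sampling_rate,
              if (x$cyclic) "cyclic" else "aperiodic", x$noise_sd))
  cat("  peak |moment| targets (Nm/kg): ",
      paste(sprintf("%s %.2f", names(x$moment_scale), x$moment_scale),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an ADL profile from YAML
#' @param path profile file path.
#' @return an [adl_profile()].
#' @export
read_adl_profile <- function(path) adl_profile(yaml::read_yaml(path))

#' The shipped fixture profiles for all five activities
#' @return named list of [adl_profile()] objects.
#' @export
default_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "capgap", mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  profs <- lapply(files, read_adl_profile)
  setNames(profs, vapply(profs, `[[`, character(1), "activity"))
}

compose_bumps <- function(bumps, x, cyclic) {
  out <- 0 * x
  for (b in bumps) {
    centers <- if (cyclic) b$center + c(-1, 0, 1) else b$center
    for (ct in centers) out <- out + b$amp * exp(-((x - ct) / b$width)^2 / 2)
  }
  out
}

# angle trajectory and its first two analytic derivatives for one DOF
angle_series <- function(spec, t, duration, cyclic) {
  if (cyclic) {
    q <- rep(spec$mean %||% 0, length(t)); qd <- qdd <- 0 * t
    for (h in spec$harmonics) {
      wh <- 2 * pi * h$order / duration
      arg <- wh * t - h$phase
      q <- q + h$amp * cos(arg)
      qd <- qd - h$amp * wh * sin(arg)
      qdd <- qdd - h$amp * wh^2 * cos(arg)
    }
  } else {
    z <- (t - spec$center) / spec$width
    sig <- 1 / (1 + exp(-z))
    dA <- spec$end - spec$start
    q <- spec$start + dA * sig
    qd <- dA * sig * (1 - sig) / spec$width
    qdd <- dA * sig * (1 - sig) * (1 - 2 * sig) / spec$width^2
  }
  list(q = q, qd = qd, qdd = qdd)
}

#' Generate a synthetic ADL trial
#'
#' Builds smooth joint-angle trajectories from the profile (velocities and
#' accelerations by exact differentiation of the parametric form), then makes
#' the authored per-DOF net-moment waveforms dynamically consistent: for every
#' frame the unique planar ground-reaction point force (vertical and
#' horizontal component plus moving center of pressure under the foot) that
#' reproduces the target moments on the segment chain is found by a linear
#' solve, and the stored net moments are the inverse-dynamics output under
#' that external load -- re-running [inverse_dynamics_planar()] on the trial
#' reproduces them to machine precision.  With `noise_sd > 0` the harmonic
#' and bump amplitudes are perturbed multiplicatively (sd = `noise_sd`),
#' emulating trial-to-trial variability; generation is reproducible for a
#' given seed.
#'
#' @param profile an [adl_profile()].
#' @param model an [msk_model()] supplying the segment chain and body mass.
#' @param seed integer seed for the noise draws.
#' @param noise_sd overrides the profile's noise level when not `NULL`.
#' @return a [trial_data()] with external load attached.
#' @export
generate_trial <- function(profile, model, seed = 1L, noise_sd = NULL) {
  stopifnot(inherits(profile, "adl_profile"), inherits(model, "msk_model"))
  dofs <- model$dofs$name
  if (!all(dofs %in% names(profile$angles)) || !all(dofs %in% names(profile$moments))) {
    stop("profile does not cover every model DOF")
  }
  noise_sd <- noise_sd %||% profile$noise_sd
  set.seed(as.integer(seed))
  jitter <- function(amp) amp * (1 + noise_sd * rnorm(1))

  fs <- profile$sampling_rate
  t <- seq(0, profile$duration, by = 1 / fs)
  x <- t / profile$duration
  n <- length(t)
  q <- qd <- qdd <- matrix(0, n, length(dofs), dimnames = list(NULL, dofs))
  tau_target <- matrix(0, n, length(dofs), dimnames = list(NULL, dofs))
  for (d in dofs) {
    spec <- profile$angles[[d]]
    if (noise_sd > 0) {
      if (profile$cyclic) {
        spec$harmonics <- lapply(spec$harmonics, function(h) {
          h$amp <- jitter(h$amp); h
        })
      } else {
        spec$end <- spec$start + jitter(spec$end - spec$start)
      }
    }
    a <- angle_series(spec, t, profile$duration, profile$cyclic)
    q[, d] <- a$q; qd[, d] <- a$qd; qdd[, d] <- a$qdd
    bumps <- profile$moments[[d]]
    if (noise_sd > 0) bumps <- lapply(bumps, function(b) { b$amp <- jitter(b$amp); b })
    tau_target[, d] <- compose_bumps(bumps, x, profile$cyclic) * model$body_mass
  }

  # gravity + inertia moments without external load
  tau_gi <- inverse_dynamics_planar(model, q, qd, qdd)

  # per-frame point ground reaction (Fx, Fy, cop_x) realizing the residual
  # moments; linear in (u, v, w) = (Fx, Fy, cop_x * Fy)
  kin <- chain_abs_angles(model, q)
  pos <- chain_positions(model, kin$theta)
  nseg <- nrow(model$segments)
  s <- model$dofs$axis_sign
  y_contact <- pos$P[[nseg + 1L]][, 2]           # distal tip height
  Fext <- Xext <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    A <- t(vapply(seq_along(dofs), function(k) {
      c(-(y_contact[i] - pos$P[[k]][i, 2]), -pos$P[[k]][i, 1], 1)
    }, numeric(3)))
    rhs <- -s * (tau_target[i, ] - tau_gi[i, ])
    sol <- if (nrow(A) == 3L) solve(A, rhs) else qr.solve(A, rhs)
    Fext[i, ] <- sol[1:2]
    Xext[i, ] <- c(if (abs(sol[2]) > 1e-9) sol[3] / sol[2] else pos$P[[nseg]][i, 1],
                   y_contact[i])
    if (abs(sol[2]) <= 1e-9) Fext[i, ] <- c(sol[1], 0)
  }
  tau <- inverse_dynamics_planar(model, q, qd, qdd, Fext, Xext)

  trial_data(activity = profile$activity, time = t,
             angles = q, angular_velocities = qd, net_moments = tau,
             body_mass = model$body_mass,
             percent_cycle = 100 * x,
             angular_accelerations = qdd,
             external_load = list(force = Fext, point = Xext))
}

#' Synthesize a surface-EMG-like signal from simulated activations
#'
#' An amplitude-modulated broadband carrier: zero-mean noise band-limited to
#' 20-400 Hz (unit RMS), multiplied by the muscle's simulated activation
#' upsampled to the EMG rate, plus additive broadband noise of relative
#' standard deviation `noise_sd`.  Feeding the result through
#' [process_emg()] recovers an envelope that ranks with the true activation.
#'
#' @param solutions a `trial_solution` from [solve_trial()].
#' @param trial the corresponding [trial_data()].
#' @param muscle muscle name.
#' @param noise_sd additive noise standard deviation relative to the unit-RMS
#'   carrier.
#' @param fs EMG sampling rate (Hz), default 1000.
#' @param seed integer seed.
#' @return an object of class `synthetic_emg` with elements `muscle`, `fs`,
#'   `time`, `raw` and per-trial-frame `true_activation`.
#' @export
generate_emg <- function(solutions, trial, muscle, noise_sd = 0.1,
                         fs = 1000, seed = 1L) {
  stopifnot(inherits(solutions, "trial_solution"), inherits(trial, "trial_data"))
  if (!muscle %in% colnames(solutions$muscle_activations)) {
    stop(sprintf("unknown muscle '%s'", muscle))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  te <- seq(trial$time[1], trial$time[length(trial$time)], by = 1 / fs)
  act <- approx(trial$time, solutions$muscle_activations[, muscle],
                xout = te, rule = 2)$y
  bf <- signal::butter(4, c(20, 400) * 2 / fs, type = "pass")
  carrier <- signal::filtfilt(bf, rnorm(length(te)))
  carrier <- carrier / sd(carrier)
  raw <- carrier * act + noise_sd * rnorm(length(te))
  structure(list(muscle = muscle, fs = fs, time = te, raw = raw,
                 true_activation = solutions$muscle_activations[, muscle]),
            class = "synthetic_emg")
}
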