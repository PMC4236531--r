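# forward-backward filtering with odd-reflection padding so that filter
# start-up transients decay inside the pad, not in the signal
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1L, pad %||% n)
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Process a raw EMG signal into a linear envelope
#'
#' The standard surface-EMG chain: zero-lag (forward-backward) 4th-order
#' Butterworth band-pass at 20-400 Hz, full-wave rectification, zero-lag
#' 4th-order Butterworth low-pass at 10 Hz, amplitude normalization to the
#' trial maximum, and optional resampling onto the trial's frame times.
#' The envelope is invariant to input amplitude scaling; the rank-based
#' validation in [spearman_validation()] is additionally invariant to the
#' normalization choice.
#'
#' @param raw a [generate_emg()] object, or a numeric signal.
#' @param fs sampling rate (Hz) when `raw` is numeric; must exceed twice the
#'   band-pass upper edge (800 Hz).
#' @param trial_time optional frame times (s) to resample the envelope onto.
#' @param band band-pass edges (Hz).
#' @param lowpass_hz envelope low-pass cutoff (Hz).
#' @return an object of class `emg_envelope`: list with `envelope`
#'   (normalized, `>= 0`), `amplitude` (the pre-normalization envelope peak in
#'   raw signal units; ~0 for an input with no in-band content), `time`, and
#'   `muscle` when known.
#' @export
process_emg <- function(raw, fs = NULL, trial_time = NULL,
                        band = c(20, 400), lowpass_hz = 10) {
  muscle <- NULL
  if (inherits(raw, "synthetic_emg")) {
    fs <- raw$fs; muscle <- raw$muscle
    time <- raw$time; sig <- raw$raw
  } else {
    if (is.null(fs)) stop("fs is required for a plain numeric signal")
    sig <- as.numeric(raw)
    time <- (seq_along(sig) - 1) / fs
  }
  if (fs < 2 * band[2]) {
    stop(sprintf("sampling rate %.0f Hz is below twice the band-pass edge (%.0f Hz)",
                 fs, band[2]))
  }
  if (length(sig) < fs) stop("need at least 1 s of signal")
  stop_if_not_finite(sig, "raw EMG")
  bp <- signal::butter(4, band * 2 / fs, type = "pass")
  filtered <- filtfilt_padded(bp, sig, pad = round(fs / 2))
  rectified <- abs(filtered)
  lp <- signal::butter(4, lowpass_hz * 2 / fs, type = "low")
  env <- pmax(filtfilt_padded(lp, rectified, pad = round(fs / 2)), 0)
  amplitude <- max(env)              # pre-normalization peak, raw units
  if (amplitude > 0) env <- env / amplitude
  if (!is.null(trial_time)) {
    env <- approx(time, env, xout = trial_time, rule = 2)$y
    time <- trial_time
  }
  structure(list(envelope = env, amplitude = amplitude, time = time,
                 muscle = muscle),
            class = "emg_envelope")
}

#' Spearman-correlation validation of simulated activations
#'
#' Rank correlation (average ranks for ties) between a processed EMG envelope
#' and the simulated muscle activation of the same frames, with a seeded
#' permutation p-value.  Constant series make the correlation undefined and
#' are flagged as an error rather than silently reported as 0.
#'
#' @param envelope an `emg_envelope` (or numeric per-frame envelope).
#' @param activation numeric per-frame simulated activation.
#' @param n_perm number of rank permutations for the p-value.
#' @param seed integer seed for the permutations.
#' @return list with `rho` (in `[-1, 1]`), `p_value` and `n`.
#' @export
spearman_validation <- function(envelope, activation, n_perm = 999L, seed = 1L) {
  env <- if (inherits(envelope, "emg_envelope")) envelope$envelope else as.numeric(envelope)
  if (length(env) != length(activation)) stop("series must have equal length")
  if (length(env) < 3L) stop("need at least 3 frames")
  if (sd(env) == 0 || sd(activation) == 0) {
    stop("constant series: Spearman correlation undefined")
  }
  rho <- cor(env, activation, method = "spearman")
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, abs(cor(env, sample(activation), method = "spearman")))
  p <- (1 + sum(perm >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n = length(env))
}

#' Table of envelope-vs-activation correlations for a solved trial
#'
#' Runs [generate_emg()], [process_emg()] and [spearman_validation()] for a
#' set of muscles of one solved trial, producing the per-muscle rho/p table
#' used to judge simulation validity.
#'
#' @param solutions a `trial_solution`.
#' @param trial the matching [trial_data()].
#' @param muscles muscle names (default: all with non-constant activation).
#' @param noise_sd EMG noise level passed to [generate_emg()].
#' @param seed integer seed.
#' @return data.frame with columns `activity`, `muscle`, `rho`, `p_value`.
#' @export
validation_table <- function(solutions, trial, muscles = NULL,
                             noise_sd = 0.1, seed = 1L) {
  act <- solutions$muscle_activations
  if (is.null(muscles)) {
    muscles <- colnames(act)[apply(act, 2, sd) > 1e-9]
  }
  rows <- lapply(seq_along(muscles), function(i) {
    m <- muscles[i]
    emg <- generate_emg(solutions, trial, m, noise_sd = noise_sd, seed = seed + i)
    env <- process_emg(emg, trial_time = trial$time)
    v <- spearman_validation(env, act[, m], seed = seed + i)
    data.frame(activity = trial$activity, muscle = m,
               rho = v$rho, p_value = v$p_value)
  })
  do.call(rbind, rows)
}
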