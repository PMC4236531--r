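#' One recorded or generated activity trial
#'
#' Joint kinematics and net joint moments for a single trial of one activity
#' of daily living, sampled on a uniform time grid.
#'
#' @param activity one of `"gait"`, `"stair_ascent"`, `"stair_descent"`,
#'   `"sit_to_stand"`, `"stand_to_sit"`.
#' @param time strictly increasing, uniformly spaced time stamps (s).
#' @param angles,angular_velocities,net_moments numeric matrices
#'   (frames x DOFs, columns named by DOF) of joint angles (rad), angular
#'   velocities (rad/s) and net joint moments (Nm, not mass-normalized).
#' @param body_mass subject body mass (kg).
#' @param percent_cycle percent of the movement cycle per frame (0-100);
#'   computed from `time` when `NULL`.
#' @param angular_accelerations optional matrix (rad/s^2).
#' @param external_load optional list with per-frame external (ground
#'   reaction) `force` (frames x 2, N) and application `point` (frames x 2, m)
#'   acting on the distal segment.
#' @return an object of class `trial_data`.
#' @export
trial_data <- function(activity, time, angles, angular_velocities, net_moments,
                       body_mass, percent_cycle = NULL,
                       angular_accelerations = NULL, external_load = NULL) {
  activity <- match.arg(activity, c("gait", "stair_ascent", "stair_descent",
                                    "sit_to_stand", "stand_to_sit"))
  angles <- as.matrix(angles)
  angular_velocities <- as.matrix(angular_velocities)
  net_moments <- as.matrix(net_moments)
  n <- length(time)
  if (n < 2L) stop("a trial needs at least 2 frames")
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing")
  if (diff(range(dts)) > 1e-9) stop("time step must be uniform (within 1e-9 s)")
  for (m in list(angles, angular_velocities, net_moments)) {
    if (nrow(m) != n) stop("all series must share the trial's frame count")
  }
  if (body_mass <= 0) stop("body_mass must be > 0")
  if (is.null(percent_cycle)) {
    percent_cycle <- 100 * (time - time[1]) / (time[n] - time[1])
  }
  structure(
    list(activity = activity, time = time, dt = mean(dts),
         angles = angles, angular_velocities = angular_velocities,
         net_moments = net_moments, body_mass = body_mass,
         percent_cycle = percent_cycle,
         angular_accelerations = angular_accelerations,
         external_load = external_load),
    class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %s: %d frames @ %.0f Hz, %.2f s, body mass %.1f kg\n",
              x$activity, length(x$time), 1 / x$dt, diff(range(x$time)), x$body_mass))
  pk <- apply(abs(x$net_moments), 2, max) / x$body_mass
  cat("  peak |moment| (Nm/kg): ",
      paste(sprintf("%s %.2f", colnames(x$net_moments), pk), collapse = ", "), "\n")
  invisible(x)
}

cross2 <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]

# Absolute segment angles / angular rates of the chain, frames x segments.
# DOF-convention angles are mapped through axis_sign and ref_offset; the
# first segment hangs straight down (-pi/2 from the +x axis) at all-zero
# angles.
chain_abs_angles <- function(model, q, qd = NULL, qdd = NULL) {
  s <- model$dofs$axis_sign
  off <- model$dofs$ref_offset
  k <- length(s)
  csum <- upper.tri(matrix(1, k, k), diag = TRUE) * 1  # column i sums joints 1..i
  phi <- sweep(q %*% diag(s, k), 2, off, "+")
  out <- list(theta = -pi / 2 + phi %*% csum)
  if (!is.null(qd)) out$omega <- (qd %*% diag(s, k)) %*% csum
  if (!is.null(qdd)) out$alpha <- (qdd %*% diag(s, k)) %*% csum
  out
}

# Joint and COM positions of the chain (lists of frames x 2 matrices).
chain_positions <- function(model, theta) {
  nseg <- nrow(model$segments)
  P <- vector("list", nseg + 1L)
  C <- vector("list", nseg)
  P[[1]] <- matrix(0, nrow(theta), 2)
  for (i in seq_len(nseg)) {
    u <- cbind(cos(theta[, i]), sin(theta[, i]))
    C[[i]] <- P[[i]] + model$segments$com[i] * u
    P[[i + 1L]] <- P[[i]] + model$segments$length[i] * u
  }
  list(P = P, C = C)
}

#' Planar inverse dynamics of the open chain
#'
#' Recursive Newton-Euler for the model's sagittal segment chain, solved from
#' the distal segment to the base.  Includes gravity, the segments' inertial
#' forces, and an optional external point force (ground reaction) on the
#' distal segment.  In the static, unloaded limit it reduces to the
#' closed-form gravitational joint moments.
#'
#' @param model an [msk_model()] providing the segment chain and sign
#'   conventions.
#' @param angles,angular_velocities,angular_accelerations frames x DOFs
#'   matrices of joint kinematics in the DOF sign convention.
#' @param external_force optional frames x 2 matrix (N) applied to the distal
#'   segment.
#' @param external_point optional frames x 2 matrix (m), application point of
#'   `external_force` in the base frame.
#' @return frames x DOFs matrix of net joint moments (Nm) in the DOF sign
#'   convention (the moment the proximal side exerts on the distal side).
#' @export
inverse_dynamics_planar <- function(model, angles, angular_velocities,
                                    angular_accelerations,
                                    external_force = NULL,
                                    external_point = NULL) {
  stopifnot(inherits(model, "msk_model"))
  q <- as.matrix(angles); qd <- as.matrix(angular_velocities)
  qdd <- as.matrix(angular_accelerations)
  nseg <- nrow(model$segments)
  if (ncol(q) != nseg || ncol(qd) != nseg || ncol(qdd) != nseg) {
    stop("kinematics must have one column per joint of the chain")
  }
  stop_if_not_finite(cbind(q, qd, qdd), "chain kinematics")
  n <- nrow(q)
  kin <- chain_abs_angles(model, q, qd, qdd)
  pos <- chain_positions(model, kin$theta)
  g <- c(0, -model$gravity)
  if (is.null(external_force)) external_force <- matrix(0, n, 2)
  if (is.null(external_point)) external_point <- matrix(0, n, 2)

  # forward pass: linear accelerations of joints and centers of mass
  AP <- vector("list", nseg + 1L); AC <- vector("list", nseg)
  AP[[1]] <- matrix(0, n, 2)
  for (i in seq_len(nseg)) {
    u <- cbind(cos(kin$theta[, i]), sin(kin$theta[, i]))
    perp <- cbind(-u[, 2], u[, 1])
    ci <- model$segments$com[i]; Li <- model$segments$length[i]
    AC[[i]] <- AP[[i]] + kin$alpha[, i] * ci * perp - kin$omega[, i]^2 * ci * u
    AP[[i + 1L]] <- AP[[i]] + kin$alpha[, i] * Li * perp - kin$omega[, i]^2 * Li * u
  }

  # backward pass: joint force f_i and torque tau_i from parent on segment i
  tau <- matrix(0, n, nseg)
  f_child <- matrix(0, n, 2); tau_child <- rep(0, n)
  for (i in rev(seq_len(nseg))) {
    m_i <- model$segments$mass[i]
    Fe <- if (i == nseg) external_force else matrix(0, n, 2)
    Xe <- external_point
    f_i <- m_i * AC[[i]] - matrix(g, n, 2, byrow = TRUE) * m_i - Fe + f_child
    t_i <- model$segments$inertia[i] * kin$alpha[, i] + tau_child -
      cross2(pos$P[[i]] - pos$C[[i]], f_i) -
      cross2(pos$P[[i + 1L]] - pos$C[[i]], -f_child)
    if (i == nseg) t_i <- t_i - cross2(Xe - pos$C[[i]], Fe)
    tau[, i] <- t_i
    f_child <- f_i; tau_child <- t_i
  }
  out <- tau %*% diag(model$dofs$axis_sign, nseg)
  colnames(out) <- model$dofs$name
  out
}

#' Numerical differentiation of a sampled series
#'
#' Central differences in the interior, one-sided at the ends, with optional
#' zero-lag Butterworth low-pass smoothing before differencing.
#'
#' @param series numeric vector or frames x k matrix.
#' @param dt sampling interval (s).
#' @param smooth_hz optional low-pass cutoff (Hz) applied (4th-order
#'   Butterworth, forward-backward) before differencing.
#' @return derivative with the same shape as `series`.
#' @export
differentiate <- function(series, dt, smooth_hz = NULL) {
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) stop("differentiate needs at least 3 frames")
  if (!is.null(smooth_hz)) {
    bf <- signal::butter(4, smooth_hz * 2 * dt, type = "low")
    x <- apply(x, 2, function(col) filtfilt_padded(bf, col))
  }
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  if (vec) drop(d) else d
}

#' Joint power
#'
#' Elementwise product of net joint moment and joint angular velocity;
#' positive is generation, negative absorption.
#'
#' @param net_moment moments (Nm or Nm/kg), vector or matrix.
#' @param angular_velocity matching angular velocities (rad/s).
#' @return power (W or W/kg) with the shape of the inputs.
#' @export
joint_power <- function(net_moment, angular_velocity) {
  if (length(net_moment) != length(angular_velocity)) {
    stop("moment and angular velocity must have equal length")
  }
  net_moment * angular_velocity
}

#' Normalize moments or powers by body mass
#'
#' @param values Nm or W values.
#' @param body_mass body mass (kg), `> 0`.
#' @return Nm/kg or W/kg.
#' @export
normalize_by_mass <- function(values, body_mass) {
  if (length(body_mass) != 1L || !is.finite(body_mass) || body_mass <= 0) {
    stop("body_mass must be a single positive number")
  }
  values / body_mass
}

#' Resample a per-frame series to 0-100% cycle
#'
#' Linear interpolation onto `n` evenly spaced points of the movement cycle,
#' for reporting; computations run at native sampling.
#'
#' @param values vector or frames x k matrix.
#' @param percent_cycle per-frame percent cycle (0-100).
#' @param n number of output points (default 101).
#' @return resampled values with `n` rows.
#' @export
resample_cycle <- function(values, percent_cycle, n = 101L) {
  grid <- seq(0, 100, length.out = n)
  x <- as.matrix(values)
  out <- apply(x, 2, function(col) approx(percent_cycle, col, xout = grid)$y)
  if (is.null(dim(values))) drop(out) else out
}
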