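#' One time frame's muscle-redundancy problem
#'
#' The static optimization at a single instant: distribute the required net
#' joint moment of every DOF over the muscles and one ideal moment actuator
#' (reserve) per DOF, minimizing the summed squared activations
#' `J = sum(a_t^2) + sum(a_m^2)` under the exact moment constraint
#' `tau_k = tau0_k * a_t_k + sum_m gain_mk * a_m` for every DOF `k`.
#' Each muscle's gain is its fully activated Hill force times its signed
#' moment arm at the frame's posture (Nm per unit activation).  Reserve
#' activations are unbounded, muscle activations are bounded to `[0, 1]`, and
#' a small optimal moment `tau0` (default 1 Nm) makes reserves costly: muscle
#' action is preferred and the reserve moment equals the capability gap.
#'
#' @param required_moments named numeric, net moment demand per DOF (Nm).
#' @param muscle_gains muscles x DOFs numeric matrix of moments per unit
#'   activation (Nm); may be negative (antagonists).
#' @param reserve_optimal_moments named numeric, the reserves' optimal moment
#'   tau0 per DOF (Nm), `> 0`; recycled scalar allowed (default 1).
#' @param lower,upper muscle activation bounds (default 0 and 1).
#' @return an object of class `frame_problem`.
#' @export
frame_problem <- function(required_moments, muscle_gains,
                          reserve_optimal_moments = 1,
                          lower = 0, upper = 1) {
  muscle_gains <- as.matrix(muscle_gains)
  K <- length(required_moments)
  if (ncol(muscle_gains) != K) stop("muscle_gains needs one column per DOF")
  stop_if_not_finite(required_moments, "required moments")
  stop_if_not_finite(muscle_gains, "muscle gains")
  tau0 <- rep_len(reserve_optimal_moments, K)
  if (any(tau0 <= 0)) stop("reserve optimal moments must be > 0")
  if (is.null(names(required_moments)) && !is.null(colnames(muscle_gains))) {
    names(required_moments) <- colnames(muscle_gains)
  }
  n <- nrow(muscle_gains)
  structure(
    list(required_moments = required_moments,
         muscle_gains = muscle_gains,
         reserve_optimal_moments = setNames(tau0, names(required_moments)),
         lower = rep_len(lower, n), upper = rep_len(upper, n)),
    class = "frame_problem")
}

#' Solve one frame of the static optimization
#'
#' Global minimizer of the strictly convex quadratic program described in
#' [frame_problem()].  The unbounded reserve activations are eliminated
#' exactly through the equality constraints
#' (`a_t_k = (tau_k - sum_m gain_mk a_m) / tau0_k`), leaving a
#' bound-constrained QP in the muscle activations that is solved by an exact
#' active-set method.  The moment constraint therefore holds to machine
#' precision and the reserves make every problem feasible.
#'
#' @param problem a [frame_problem()].
#' @return an object of class `frame_solution` with elements
#'   `muscle_activations` (in `[0, 1]`), `reserve_activations` (unbounded),
#'   `reserve_moments` (`tau0 * a_t`, Nm), `objective_value`,
#'   `moment_residual` (Nm per DOF) and `solver_status`.
#' @export
solve_frame <- function(problem) {
  stopifnot(inherits(problem, "frame_problem"))
  G <- problem$muscle_gains                      # N x K
  tau <- problem$required_moments
  tau0 <- problem$reserve_optimal_moments
  N <- nrow(G)
  Dw <- 1 / tau0^2
  # J(a) = sum_k (tau_k - (G'a)_k)^2 / tau0_k^2 + a'a
  H <- 2 * (diag(N) + G %*% (Dw * t(G)))
  d <- -2 * drop(G %*% (Dw * tau))
  qp <- solve_box_qp(H, d, problem$lower, problem$upper)
  a_m <- qp$x
  a_t <- (tau - drop(crossprod(G, a_m))) / tau0
  achieved <- tau0 * a_t + drop(crossprod(G, a_m))
  structure(
    list(muscle_activations = setNames(a_m, rownames(G)),
         reserve_activations = setNames(a_t, names(tau)),
         reserve_moments = setNames(tau0 * a_t, names(tau)),
         objective_value = sum(a_t^2) + sum(a_m^2),
         moment_residual = achieved - tau,
         solver_status = if (qp$status == "optimal") "optimal" else "max_iter"),
    class = "frame_solution")
}

#' @export
print.frame_solution <- function(x, ...) {
  cat(sprintf("<frame_solution> status %s, J = %.6g\n", x$solver_status,
              x$objective_value))
  cat("  muscle activations:", paste(sprintf("%.4f", x$muscle_activations),
                                     collapse = " "), "\n")
  cat("  reserve moments (Nm):", paste(sprintf("%s %.4f", names(x$reserve_moments),
                                               x$reserve_moments), collapse = ", "), "\n")
  invisible(x)
}

# Per-frame muscle gains for a whole trial: fully activated Hill force times
# signed moment arm, for each muscle and spanned DOF.  Returns a frames x
# muscles x DOFs array plus fiber states (used by EMG synthesis/testing).
trial_muscle_gains <- function(model, trial) {
  dofs <- model$dofs$name
  q <- trial$angles[, dofs, drop = FALSE]
  qd <- trial$angular_velocities[, dofs, drop = FALSE]
  n <- nrow(q); N <- length(model$muscles)
  gains <- array(0, dim = c(n, N, length(dofs)),
                 dimnames = list(NULL, names(model$muscles), dofs))
  lnorm <- vnorm <- matrix(0, n, N, dimnames = list(NULL, names(model$muscles)))
  for (j in seq_len(N)) {
    m <- model$muscles[[j]]
    len <- rep(m$reference_fiber_length, n); vel <- rep(0, n)
    for (k in m$spanned_dofs) {
      len <- len - poly_integral_eval(m$moment_arms[[k]], q[, k])
      vel <- vel - poly_eval(m$moment_arms[[k]], q[, k]) * qd[, k]
    }
    if (any(len <= 0)) {
      stop(sprintf("non-positive fiber length for muscle '%s' during trial", m$name))
    }
    lnorm[, j] <- len / m$optimal_fiber_length
    vnorm[, j] <- vel / (m$optimal_fiber_length * m$max_contraction_velocity)
    fmax <- m$max_isometric_force * force_length(lnorm[, j]) *
      force_velocity(vnorm[, j])
    for (k in m$spanned_dofs) {
      gains[, j, k] <- fmax * poly_eval(m$moment_arms[[k]], q[, k])
    }
  }
  list(gains = gains, lnorm = lnorm, vnorm = vnorm)
}

#' Solve the static optimization for every frame of a trial
#'
#' Builds each frame's [frame_problem()] from the muscle kinematics, moment
#' arms and Hill force scales at that frame's posture, and solves the frames
#' independently (the optimization is instantaneous; there is no
#' activation-rate coupling).  Deterministic given its inputs.
#'
#' @param model an [msk_model()] (apply weakness first via
#'   [apply_weakness()]).
#' @param trial a [trial_data()] whose DOFs match the model's.
#' @param reserve_optimal_moment reserves' optimal moment tau0 (Nm), scalar
#'   or per DOF.
#' @return an object of class `trial_solution` with matrices
#'   `muscle_activations` (frames x muscles), `reserve_activations` and
#'   `reserve_moments` (frames x DOFs), vectors `objective_value` and
#'   `solver_status`, and the gain array used.
#' @export
solve_trial <- function(model, trial, reserve_optimal_moment = 1) {
  stopifnot(inherits(model, "msk_model"), inherits(trial, "trial_data"))
  dofs <- model$dofs$name
  if (!all(dofs %in% colnames(trial$net_moments))) {
    stop("trial does not provide net moments for every model DOF")
  }
  tg <- trial_muscle_gains(model, trial)
  n <- dim(tg$gains)[1]; N <- dim(tg$gains)[2]; K <- dim(tg$gains)[3]
  tau0 <- rep_len(reserve_optimal_moment, K)
  act <- matrix(0, n, N, dimnames = list(NULL, dimnames(tg$gains)[[2]]))
  res_act <- res_mom <- matrix(0, n, K, dimnames = list(NULL, dofs))
  obj <- numeric(n); status <- character(n)
  for (i in seq_len(n)) {
    Gi <- matrix(tg$gains[i, , ], N, K,
                 dimnames = dimnames(tg$gains)[2:3])
    pb <- frame_problem(required_moments = setNames(trial$net_moments[i, dofs], dofs),
                        muscle_gains = Gi, reserve_optimal_moments = tau0)
    sol <- solve_frame(pb)
    if (sol$solver_status != "optimal") {
      stop(sprintf("static optimization failed at frame %d (%s)", i, sol$solver_status))
    }
    act[i, ] <- sol$muscle_activations
    res_act[i, ] <- sol$reserve_activations
    res_mom[i, ] <- sol$reserve_moments
    obj[i] <- sol$objective_value
    status[i] <- sol$solver_status
  }
  structure(
    list(muscle_activations = act, reserve_activations = res_act,
         reserve_moments = res_mom, objective_value = obj,
         solver_status = status, reserve_optimal_moments = setNames(tau0, dofs),
         gains = tg$gains, fiber_lnorm = tg$lnorm, fiber_vnorm = tg$vnorm),
    class = "trial_solution")
}

#' Extract one frame of a trial solution
#'
#' @param solution a `trial_solution` from [solve_trial()].
#' @param frame frame index.
#' @return a `frame_solution` equivalent to solving that frame alone.
#' @export
frame_solution_at <- function(solution, frame) {
  stopifnot(inherits(solution, "trial_solution"))
  structure(
    list(muscle_activations = solution$muscle_activations[frame, ],
         reserve_activations = solution$reserve_activations[frame, ],
         reserve_moments = solution$reserve_moments[frame, ],
         objective_value = solution$objective_value[frame],
         moment_residual = setNames(rep(0, ncol(solution$reserve_moments)),
                                    colnames(solution$reserve_moments)),
         solver_status = solution$solver_status[frame]),
    class = "frame_solution")
}

#' Brute-force grid oracle for the frame optimization
#'
#' Independent check of [solve_frame()]: enumerate muscle activations on a
#' regular grid, compute the reserve activations exactly from the equality
#' constraints at every grid point, and return the best point.  The grid
#' objective is an upper bound on the QP optimum and converges to it as the
#' step shrinks.  Full enumeration is used when the grid is small enough;
#' above `max_points` a coarse full grid is refined locally down to
#' `grid_step` (valid here because the eliminated objective is convex).
#' Refuses instances with more than 3 muscles or 2 DOFs.
#'
#' @param problem a [frame_problem()] with at most 3 muscles and 2 DOFs.
#' @param grid_step grid resolution on the activation axis.
#' @param max_points largest number of grid points enumerated at once.
#' @return a `frame_solution` (status `"optimal"` denotes grid optimum).
#' @export
brute_force_oracle <- function(problem, grid_step = 1e-3, max_points = 2e6) {
  stopifnot(inherits(problem, "frame_problem"))
  G <- problem$muscle_gains
  N <- nrow(G); K <- ncol(G)
  if (N > 3L || K > 2L) stop("oracle restricted to <= 3 muscles and <= 2 DOFs")
  tau <- problem$required_moments
  tau0 <- problem$reserve_optimal_moments
  lower <- problem$lower; upper <- problem$upper

  eval_grid <- function(axes) {
    A <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    Res <- sweep(-A %*% G, 2, tau, "+")        # tau - G'a per row
    Res <- sweep(Res, 2, tau0, "/")
    J <- rowSums(A^2) + rowSums(Res^2)
    i <- which.min(J)
    list(a = A[i, ], J = J[i])
  }
  axis_for <- function(step) {
    lapply(seq_len(N), function(j) seq(lower[j], upper[j], by = step))
  }
  step <- grid_step
  npts <- prod(vapply(axis_for(step), length, integer(1)))
  if (npts <= max_points) {
    best <- eval_grid(axis_for(step))
  } else {
    # coarse pass, then zoom onto the incumbent (convex objective)
    coarse <- grid_step
    repeat {
      coarse <- coarse * 10
      if (prod(vapply(axis_for(coarse), length, integer(1))) <= max_points) break
    }
    best <- eval_grid(axis_for(coarse))
    while (coarse > grid_step * 1.0001) {
      fine <- max(coarse / 10, grid_step)
      axes <- lapply(seq_len(N), function(j) {
        lo <- max(lower[j], best$a[j] - coarse)
        hi <- min(upper[j], best$a[j] + coarse)
        unique(c(seq(lo, hi, by = fine), hi))
      })
      best <- eval_grid(axes)
      coarse <- fine
    }
  }
  a_m <- best$a
  a_t <- (tau - drop(crossprod(G, a_m))) / tau0
  structure(
    list(muscle_activations = setNames(a_m, rownames(G)),
         reserve_activations = setNames(a_t, names(tau)),
         reserve_moments = setNames(tau0 * a_t, names(tau)),
         objective_value = best$J,
         moment_residual = setNames(rep(0, K), names(tau)),
         solver_status = "optimal"),
    class = "frame_solution")
}

#' KKT stationarity residual of a frame solution
#'
#' Certifies optimality of the convex program: recovers the equality
#' multipliers by least squares from the free variables' stationarity
#' conditions and returns the largest violation of `2x - A' lambda = mu`,
#' with the bound multipliers `mu` projected to their admissible sign at
#' active bounds.  A small residual certifies the global optimum.
#'
#' @param problem a [frame_problem()].
#' @param solution a `frame_solution` for it.
#' @param bound_tol distance from a bound below which a muscle activation is
#'   treated as active.
#' @return maximal stationarity violation (dimensionless).
#' @export
kkt_residual <- function(problem, solution, bound_tol = 1e-7) {
  stopifnot(inherits(problem, "frame_problem"), inherits(solution, "frame_solution"))
  G <- problem$muscle_gains
  N <- nrow(G); K <- ncol(G)
  x <- c(solution$reserve_activations, solution$muscle_activations)
  A <- cbind(diag(problem$reserve_optimal_moments, K), t(G))  # K x (K+N)
  at_lo <- c(rep(FALSE, K), solution$muscle_activations <= problem$lower + bound_tol)
  at_hi <- c(rep(FALSE, K), solution$muscle_activations >= problem$upper - bound_tol)
  free <- !(at_lo | at_hi)
  # free variables: 2 x_i = (A' lambda)_i
  lam <- qr.solve(t(A[, free, drop = FALSE]), 2 * x[free])
  g <- 2 * x - drop(crossprod(A, lam))
  viol <- abs(g) * free
  viol[at_lo] <- pmax(0, -g[at_lo])   # need multiplier >= 0 at lower bound
  viol[at_hi] <- pmax(0, g[at_hi])    # need multiplier <= 0 at upper bound
  max(viol)
}
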