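# Small models and trials built in code for the tests.

# one-DOF, one-muscle model with a constant moment arm; at the zero posture
# the fiber is at optimal length, so max_feasible_moment = F0 * arm
tiny_model <- function(F0 = 3000, arm = 0.04, lopt = 0.1, body_mass = 70) {
  msk_model(
    dofs = data.frame(name = "ankle", positive_direction = "plantarflexion",
                      axis_sign = 1, ref_offset = 0),
    muscles = list(muscle_params("pf", F0, lopt, 10,
                                 moment_arms = list(ankle = arm))),
    segments = data.frame(name = "foot", mass = 1, length = 0.2,
                          com = 0.1, inertia = 0.004),
    body_mass = body_mass, name = "tiny")
}

# two-DOF model with a bi-articular muscle, for coupling/oracle tests
two_dof_model <- function() {
  msk_model(
    dofs = data.frame(name = c("hip", "knee"),
                      positive_direction = c("extension", "extension"),
                      axis_sign = c(-1, 1), ref_offset = c(0, 0)),
    muscles = list(
      muscle_params("mono_hip", 2000, 0.12, 10, moment_arms = list(hip = 0.05)),
      muscle_params("biart", 1500, 0.12, 10,
                    moment_arms = list(hip = 0.05, knee = c(-0.03, 0.008))),
      muscle_params("mono_knee", 2500, 0.1, 10,
                    moment_arms = list(knee = c(0.045, 0.01)))),
    segments = data.frame(name = c("thigh", "shank"),
                          mass = c(6, 3), length = c(0.42, 0.42),
                          com = c(0.18, 0.18), inertia = c(0.1, 0.05)),
    body_mass = 61, name = "two_dof")
}

# quasi-static trial whose peak |moment| equals `ratio` times the isometric
# single-direction capability of `model` at the zero posture (velocities are
# zero throughout, so the capability is exactly (1-w) * ratio^-1 * peak)
planted_trial <- function(model, ratio, dof = model$dofs$name[1], n = 41) {
  cap <- max_feasible_moment(model, dof,
                             setNames(rep(0, nrow(model$dofs)), model$dofs$name),
                             sign = 1)
  time <- seq(0, 2, length.out = n)
  k <- length(model$dofs$name)
  zero <- matrix(0, n, k, dimnames = list(NULL, model$dofs$name))
  mom <- zero
  mom[, dof] <- ratio * cap * sin(pi * time / max(time))
  trial_data(activity = "sit_to_stand", time = time, angles = zero,
             angular_velocities = zero, net_moments = mom,
             body_mass = model$body_mass)
}

# random small (desk-scale) frame problem for oracle-equivalence checks;
# gains are kept modest so the first-order grid bound holds with margin
random_frame_problem <- function(n_muscles, n_dofs) {
  G <- matrix(runif(n_muscles * n_dofs, -25, 25), n_muscles, n_dofs)
  tau <- sample(c(-1, 1), n_dofs, replace = TRUE) * runif(n_dofs, 8, 40)
  frame_problem(required_moments = setNames(tau, paste0("d", seq_len(n_dofs))),
                muscle_gains = G)
}

shipped_model <- function() default_model()
shipped_profiles <- function() default_profiles()

# closed-form static gravitational joint moments: each joint supports the
# weight of all distal segments acting at their horizontal COM offsets
statics_oracle <- function(model, q) {
  kin <- capgap:::chain_abs_angles(model, matrix(q, 1))
  pos <- capgap:::chain_positions(model, kin$theta)
  nseg <- nrow(model$segments)
  vapply(seq_len(nseg), function(k) {
    model$dofs$axis_sign[k] * sum(vapply(k:nseg, function(j) {
      model$segments$mass[j] * model$gravity *
        (pos$C[[j]][1, 1] - pos$P[[k]][1, 1])
    }, numeric(1)))
  }, numeric(1))
}
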