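#' Hill-type muscle group parameters
#'
#' Defines one (grouped) musculotendon actuator of the planar model: maximal
#' isometric force, optimal fiber length, maximal contraction velocity, and a
#' signed polynomial moment arm for every spanned degree of freedom.  A rigid
#' tendon is assumed, so fiber length changes equal musculotendon path length
#' changes obtained by integrating the moment arms over joint angle.
#'
#' @param name muscle name.
#' @param max_isometric_force maximal isometric force F0 (N), `>= 0`.
#' @param optimal_fiber_length optimal fiber length (m), `> 0`.
#' @param max_contraction_velocity maximal shortening velocity in optimal
#'   fiber lengths per second, `> 0`.
#' @param moment_arms named list (one entry per spanned DOF) of polynomial
#'   coefficients of the moment arm versus joint angle, ascending powers
#'   (m, m/rad, ...).  The sign follows the DOF's positive-moment convention:
#'   a positive moment arm means the muscle produces a positive moment.
#' @param optimal_angles named numeric, the joint angles (rad) at which the
#'   fiber sits at optimal length; defaults to 0 for every spanned DOF.  Used
#'   to place the operating point of the force-length curve.
#' @param reference_fiber_length fiber length (m) at all-zero joint angles;
#'   computed from `optimal_angles` when `NULL`.
#' @return an object of class `muscle_params`.
#' @export
muscle_params <- function(name, max_isometric_force, optimal_fiber_length,
                          max_contraction_velocity = 10,
                          moment_arms = list(),
                          optimal_angles = NULL,
                          reference_fiber_length = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (max_isometric_force < 0) stop("max_isometric_force must be >= 0")
  if (optimal_fiber_length <= 0) stop("optimal_fiber_length must be > 0")
  if (max_contraction_velocity <= 0) stop("max_contraction_velocity must be > 0")
  if (length(moment_arms) == 0L || is.null(names(moment_arms))) {
    stop("moment_arms must be a named list with one entry per spanned DOF")
  }
  spanned <- names(moment_arms)
  if (is.null(optimal_angles)) optimal_angles <- setNames(rep(0, length(spanned)), spanned)
  if (!all(spanned %in% names(optimal_angles))) {
    optimal_angles <- setNames(optimal_angles[spanned] %||% 0, spanned)
    optimal_angles[is.na(optimal_angles)] <- 0
  }
  if (is.null(reference_fiber_length)) {
    # l(q) = reference - sum_k int_0^q r_k ; choose reference so that
    # l(optimal_angles) = optimal_fiber_length
    excursion <- sum(vapply(spanned, function(k) {
      poly_integral_eval(moment_arms[[k]], optimal_angles[[k]])
    }, numeric(1)))
    reference_fiber_length <- optimal_fiber_length + excursion
  }
  structure(
    list(name = name,
         max_isometric_force = max_isometric_force,
         optimal_fiber_length = optimal_fiber_length,
         max_contraction_velocity = max_contraction_velocity,
         spanned_dofs = spanned,
         moment_arms = moment_arms,
         optimal_angles = optimal_angles,
         reference_fiber_length = reference_fiber_length),
    class = "muscle_params")
}

#' Instantaneous muscle fiber state
#'
#' @param fiber_length fiber length (m), `> 0`.
#' @param fiber_velocity fiber velocity (m/s), shortening negative.
#' @return an object of class `muscle_state`.
#' @export
muscle_state <- function(fiber_length, fiber_velocity = 0) {
  stop_if_not_finite(c(fiber_length, fiber_velocity), "muscle state")
  if (any(fiber_length <= 0)) stop("fiber_length must be > 0")
  structure(list(fiber_length = fiber_length, fiber_velocity = fiber_velocity),
            class = "muscle_state")
}

#' Planar musculoskeletal model
#'
#' A sagittal-plane open-chain model: ordered degrees of freedom (DOFs), body
#' segments hanging from a fixed proximal joint, and a set of Hill-type muscle
#' groups.  The shipped default (`planar9`) has hip, knee and ankle
#' flexion/extension and nine muscle groups including the bi-articular
#' hamstrings, rectus femoris and gastrocnemius.
#'
#' Sign conventions: extension moments are positive at hip and knee,
#' plantarflexion is positive at the ankle; angles are radians and follow the
#' same sign convention as the moments, with zero at quiet standing.
#'
#' @param dofs data.frame with columns `name`, `positive_direction`
#'   (documentation of the sign convention), `axis_sign` (+1/-1 mapping the
#'   DOF convention to counter-clockwise rotation of the planar chain) and
#'   `ref_offset` (rad, relative segment rotation at all-zero angles).
#' @param muscles list of [muscle_params()] objects.
#' @param segments data.frame with columns `name`, `mass` (kg), `length` (m),
#'   `com` (m, distance of the center of mass from the proximal joint along
#'   the segment axis) and `inertia` (kg m^2, about the center of mass).  One
#'   segment per DOF, ordered proximal to distal.
#' @param body_mass body mass (kg), used for normalization.
#' @param gravity gravitational acceleration magnitude (m/s^2).
#' @param name model name.
#' @return an object of class `msk_model`.
#' @export
msk_model <- function(dofs, muscles, segments, body_mass,
                      gravity = 9.81, name = "model") {
  stopifnot(is.data.frame(dofs), all(c("name", "axis_sign", "ref_offset") %in% names(dofs)))
  if (anyDuplicated(dofs$name)) stop("DOF names must be unique")
  if (body_mass <= 0) stop("body_mass must be > 0")
  if (length(muscles) < 1L) stop("model needs at least one muscle")
  for (m in muscles) {
    if (!inherits(m, "muscle_params")) stop("muscles must be muscle_params objects")
    missing <- setdiff(m$spanned_dofs, dofs$name)
    if (length(missing)) {
      stop(sprintf("muscle '%s' spans unknown DOF(s): %s",
                   m$name, paste(missing, collapse = ", ")))
    }
  }
  stopifnot(is.data.frame(segments),
            all(c("name", "mass", "length", "com", "inertia") %in% names(segments)))
  if (any(segments$mass <= 0) || any(segments$length <= 0)) {
    stop("segment masses and lengths must be > 0")
  }
  if (nrow(segments) != nrow(dofs)) stop("need one segment per DOF")
  names(muscles) <- vapply(muscles, `[[`, character(1), "name")
  structure(
    list(name = name, dofs = dofs, muscles = muscles, segments = segments,
         body_mass = body_mass, gravity = gravity),
    class = "msk_model")
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model '%s'>  %d DOFs, %d muscles, body mass %.1f kg\n",
              x$name, nrow(x$dofs), length(x$muscles), x$body_mass))
  cat("  DOFs: ", paste(x$dofs$name, sprintf("(%s+)", x$dofs$positive_direction),
                        collapse = ", "), "\n", sep = "")
  for (m in x$muscles) {
    cat(sprintf("  %-14s F0 = %6.0f N, lopt = %.3f m, spans %s\n",
                m$name, m$max_isometric_force, m$optimal_fiber_length,
                paste(m$spanned_dofs, collapse = "+")))
  }
  invisible(x)
}

#' Read a planar musculoskeletal model from YAML
#'
#' @param path path to a model definition file (see the shipped
#'   `planar9.yaml` under `extdata` for the schema).
#' @return an [msk_model()] object.
#' @export
read_msk_model <- function(path) {
  y <- yaml::read_yaml(path)
  dofs <- do.call(rbind, lapply(y$dofs, function(d) {
    data.frame(name = d$name,
               positive_direction = d$positive_direction %||% "",
               axis_sign = d$axis_sign, ref_offset = d$ref_offset %||% 0)
  }))
  body_mass <- y$body_mass
  segments <- do.call(rbind, lapply(y$segments, function(s) {
    mass <- s$mass %||% (s$mass_fraction * body_mass)
    data.frame(name = s$name, mass = mass, length = s$length,
               com = s$com_fraction * s$length,
               inertia = mass * (s$gyration_fraction * s$length)^2)
  }))
  muscles <- lapply(y$muscles, function(m) {
    arms <- lapply(m$dofs, function(d) unlist(d$moment_arm))
    names(arms) <- vapply(m$dofs, `[[`, character(1), "name")
    opt <- setNames(vapply(m$dofs, function(d) d$optimal_angle %||% 0, numeric(1)),
                    names(arms))
    muscle_params(name = m$name,
                  max_isometric_force = m$max_isometric_force,
                  optimal_fiber_length = m$optimal_fiber_length,
                  max_contraction_velocity = m$max_contraction_velocity %||% 10,
                  moment_arms = arms, optimal_angles = opt)
  })
  msk_model(dofs = dofs, muscles = muscles, segments = segments,
            body_mass = body_mass, gravity = y$gravity %||% 9.81,
            name = y$name %||% "model")
}

#' The shipped default planar lower-limb model
#'
#' Three sagittal DOFs (hip, knee, ankle) and nine muscle groups; grouped
#' maximal isometric forces follow a standard generic lower-limb
#' musculoskeletal model.
#'
#' @param body_mass optional body mass (kg) overriding the file value.
#' @return an [msk_model()] object.
#' @export
default_model <- function(body_mass = NULL) {
  m <- read_msk_model(system.file("extdata", "planar9.yaml", package = "capgap",
                                  mustWork = TRUE))
  if (!is.null(body_mass)) {
    scale <- body_mass / m$body_mass
    m$segments$mass <- m$segments$mass * scale
    m$segments$inertia <- m$segments$inertia * scale
    m$body_mass <- body_mass
  }
  m
}

#' Active Hill-type muscle force
#'
#' `activation * F0 * f_L(lnorm) * f_V(vnorm)` with the force-length and
#' force-velocity curves of [force_length()] and [force_velocity()]; both
#' curves equal 1 at optimal length and isometric velocity, so the force is
#' linear in activation and in maximal isometric force.
#'
#' @param params a [muscle_params()] object.
#' @param state a [muscle_state()] object.
#' @param activation muscle activation in `[0, 1]`.
#' @return active fiber force (N), `>= 0`.
#' @export
active_force <- function(params, state, activation) {
  stopifnot(inherits(params, "muscle_params"), inherits(state, "muscle_state"))
  stop_if_not_finite(c(state$fiber_length, state$fiber_velocity), "muscle state")
  if (any(activation < 0 | activation > 1)) stop("activation must be in [0, 1]")
  lnorm <- state$fiber_length / params$optimal_fiber_length
  vnorm <- state$fiber_velocity /
    (params$optimal_fiber_length * params$max_contraction_velocity)
  activation * params$max_isometric_force * force_length(lnorm) * force_velocity(vnorm)
}

#' Apply uniform muscle weakness
#'
#' Multiplies every muscle's maximal isometric force by `1 - weakness`; all
#' other parameters are unchanged and the input model is not modified.
#' Because active force is linear in maximal isometric force, this scales the
#' whole force-length and force-velocity surface of each muscle.
#'
#' @param model an [msk_model()].
#' @param weakness fraction in `[0, 1]`; 0 is full strength, 1 is complete
#'   paralysis.
#' @return a new, weakened [msk_model()].
#' @export
apply_weakness <- function(model, weakness) {
  stopifnot(inherits(model, "msk_model"))
  if (length(weakness) != 1L || !is.finite(weakness) || weakness < 0 || weakness > 1) {
    stop("weakness must be a single value in [0, 1]")
  }
  model$muscles <- lapply(model$muscles, function(m) {
    m$max_isometric_force <- m$max_isometric_force * (1 - weakness)
    m
  })
  model
}

#' Signed moment arm of a muscle about a DOF
#'
#' Polynomial in the spanned joint angle; the sign encodes the action
#' direction in the DOF's positive-moment convention.  Querying a DOF the
#' muscle does not span is an error (distinct from a zero moment arm).
#'
#' @param params a [muscle_params()] object.
#' @param dof DOF name.
#' @param angle joint angle (rad); vectorized.
#' @return moment arm (m), signed.
#' @export
moment_arm <- function(params, dof, angle) {
  stopifnot(inherits(params, "muscle_params"))
  if (!dof %in% params$spanned_dofs) {
    stop(sprintf("muscle '%s' does not span DOF '%s'", params$name, dof))
  }
  poly_eval(params$moment_arms[[dof]], angle)
}

#' Muscle fiber kinematics from joint kinematics
#'
#' With a rigid tendon the fiber length is the reference length minus the
#' integral of the moment arm over each spanned joint angle (exact polynomial
#' antiderivative), and the fiber velocity is `-sum_k r_k(q_k) * qdot_k`:
#' a positive moment arm with an increasing angle shortens the muscle.
#'
#' @param params a [muscle_params()] object.
#' @param angles named numeric of joint angles (rad) covering all spanned DOFs.
#' @param angular_velocities named numeric of joint angular velocities (rad/s);
#'   defaults to zero.
#' @return a [muscle_state()].
#' @export
muscle_kinematics <- function(params, angles, angular_velocities = NULL) {
  stopifnot(inherits(params, "muscle_params"))
  if (is.null(angular_velocities)) {
    angular_velocities <- setNames(rep(0, length(angles)), names(angles))
  }
  missing <- setdiff(params$spanned_dofs, names(angles))
  if (length(missing)) {
    stop(sprintf("angles missing for spanned DOF(s): %s", paste(missing, collapse = ", ")))
  }
  stop_if_not_finite(c(angles, angular_velocities), "joint kinematics")
  len <- params$reference_fiber_length
  vel <- 0
  for (k in params$spanned_dofs) {
    len <- len - poly_integral_eval(params$moment_arms[[k]], angles[[k]])
    vel <- vel - poly_eval(params$moment_arms[[k]], angles[[k]]) * angular_velocities[[k]]
  }
  if (len <= 0) {
    stop(sprintf("non-positive fiber length for muscle '%s': inconsistent model geometry",
                 params$name))
  }
  muscle_state(fiber_length = len, fiber_velocity = vel)
}

#' Maximal muscle-generated moment about one DOF
#'
#' Upper bound on the moment the muscles can produce in one direction at a
#' given posture: the sum, over muscles whose moment arm sign matches the
#' requested direction, of their fully activated Hill force times the moment
#' arm magnitude.  Demands at other DOFs are ignored, so this is an
#' optimistic single-DOF capability (used as an analytic oracle for
#' weakness-tolerance checks).
#'
#' @param model an [msk_model()].
#' @param dof DOF name.
#' @param angles,angular_velocities named numeric joint kinematics (rad,
#'   rad/s); velocities default to zero (isometric capability).
#' @param sign +1 for the DOF's positive direction, -1 for negative.
#' @return moment (Nm), `>= 0`.
#' @export
max_feasible_moment <- function(model, dof, angles, angular_velocities = NULL,
                                sign = 1) {
  stopifnot(inherits(model, "msk_model"), sign %in% c(-1, 1))
  if (is.null(angular_velocities)) {
    angular_velocities <- setNames(rep(0, length(angles)), names(angles))
  }
  total <- 0
  for (m in model$muscles) {
    if (!dof %in% m$spanned_dofs) next
    r <- moment_arm(m, dof, angles[[dof]])
    if (sign * r <= 0) next
    st <- muscle_kinematics(m, angles, angular_velocities)
    total <- total + active_force(m, st, 1) * abs(r)
  }
  total
}
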