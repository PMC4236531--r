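#' Active force-length curve
#'
#' Gaussian active force-length relation of a Hill-type fiber, equal to 1 at
#' optimal fiber length and decaying symmetrically on either side.
#'
#' @param lnorm fiber length normalized by optimal fiber length.
#' @param width Gaussian half-width on the normalized length axis; the force
#'   falls to `exp(-1)` of maximum at `lnorm = 1 +/- width`.
#' @return dimensionless force scale factor in (0, 1].
#' @seealso [force_velocity()], [active_force()]
#' @export
force_length <- function(lnorm, width = 0.45) {
  stop_if_not_finite(lnorm, "normalized fiber length")
  exp(-((lnorm - 1) / width)^2)
}

#' Force-velocity curve
#'
#' Classic Hill hyperbola on the shortening side (force 0 at maximal
#' shortening velocity, 1 at isometric) with a smooth eccentric branch that
#' saturates at `ecc_plateau`; the two branches meet at isometric with equal
#' value and slope.
#'
#' @param vnorm fiber velocity normalized by maximal contraction velocity
#'   (optimal fiber lengths per second times optimal fiber length); shortening
#'   is negative.
#' @param curvature Hill curvature constant `a/F0` of the shortening branch.
#' @param ecc_plateau asymptotic force scale during lengthening.
#' @return dimensionless force scale factor in `[0, ecc_plateau)`.
#' @export
force_velocity <- function(vnorm, curvature = 0.25, ecc_plateau = 1.4) {
  stop_if_not_finite(vnorm, "normalized fiber velocity")
  # slope of the shortening branch at vnorm = 0 is (1 + 1/curvature); the
  # eccentric exponential decay constant is chosen to match it (C1 continuity)
  s <- (ecc_plateau - 1) * curvature / (1 + curvature)
  conc <- (1 + vnorm) / (1 - vnorm / curvature)
  conc[vnorm <= -1] <- 0
  ecc <- ecc_plateau - (ecc_plateau - 1) * exp(-vnorm / s)
  out <- ifelse(vnorm >= 0, ecc, conc)
  pmax(out, 0)
}
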