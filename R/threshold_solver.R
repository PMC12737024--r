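#' Critical vertical GRF at a given shin angle
#'
#' Solves the abduction = adduction torque balance about the lateral condyle
#' for the vertical ground reaction force. Writing C for the
#' angle-independent adduction sum (ligaments, quadriceps, semitendinosus,
#' bodyweight at the half-biacetabular lever), the closed form is
#'
#' \deqn{F_y^* = \frac{C + m g\, T \sin\alpha}{L(\sin\alpha - \mu\cos\alpha)}}
#'
#' with T the thigh length and L the ground-to-lateral-condyle distance.
#' A landing with Fy above this value is past the injury threshold.
#'
#' The balance has no solution when the effective abduction lever
#' `sin(alpha) - mu * cos(alpha)` is non-positive (at mu = 0 this is the
#' alpha = 0 singularity; with traction, any alpha <= atan(mu)): the GRF
#' then cannot load the abduction side and the threshold is infinite.
#'
#' @param shin_angle Shin angle(s) in degrees, (0, 90\]; vectorised.
#' @param profile An `anthro_profile`.
#' @param tissue A `tissue_parameters`.
#' @param activation An `activation_state`.
#' @param surface A `surface_state`.
#' @param gravity Gravitational constant, m/s^2.
#' @param no_solution How to report an unreachable balance: `"error"`
#'   (default) or `"inf"` (return `Inf`, used by curve generation).
#' @return Critical Fy in N (vector matching `shin_angle`).
#' @examples
#' critical_grf(90)  # about 1561.3 N for the reference parameters
#' @export
critical_grf <- function(shin_angle, profile = average_profile(),
                         tissue = tissue_parameters(),
                         activation = activation_state(),
                         surface = surface_state(), gravity = 10,
                         no_solution = c("error", "inf")) {
  no_solution <- match.arg(no_solution)
  stopifnot(inherits(profile, "anthro_profile"),
            inherits(tissue, "tissue_parameters"),
            inherits(activation, "activation_state"),
            inherits(surface, "surface_state"))
  .check_angle(shin_angle)
  bw <- profile$body_mass * gravity
  const <- .adduction_constant(profile, tissue, activation, bw)
  lever <- profile$ground_to_lateral_condyle *
    (.sin_deg(shin_angle) - surface$mu * .cos_deg(shin_angle))
  adduction <- const + bw * profile$thigh_length * .sin_deg(shin_angle)
  out <- ifelse(lever > 0, adduction / lever, Inf)
  if (no_solution == "error" && any(!is.finite(out)))
    stop("no finite threshold: effective abduction lever ",
         "sin(alpha) - mu*cos(alpha) is non-positive", call. = FALSE)
  out
}

#' Angle of damage for a given vertical GRF
#'
#' Inverts the threshold relation: the smallest shin angle in (0, 90\]
#' degrees at which the given Fy reaches the critical value (abduction and
#' adduction torques balance). Beyond this angle the scenario is at risk.
#' Returns `NA` when even a fully horizontal lever (alpha = 90 degrees)
#' would need more force than supplied.
#'
#' With mu = 0 the inversion is closed-form: the balance
#' `Fy L sin(a) = C + m g T sin(a)` gives
#' `a = asin(C / (Fy L - m g T))`. With traction the root of the torque
#' residual is bracketed and bisected (via [stats::uniroot]) to a residual
#' tolerance of 1e-9 N m.
#'
#' @param grf_vertical Vertical GRF in N (> 0).
#' @inheritParams critical_grf
#' @return Angle in degrees, or `NA_real_` if no angle in (0, 90\] reaches
#'   the threshold.
#' @examples
#' angle_of_damage(2500)  # about 30 degrees
#' @export
angle_of_damage <- function(grf_vertical, profile = average_profile(),
                            tissue = tissue_parameters(),
                            activation = activation_state(),
                            surface = surface_state(), gravity = 10) {
  if (!is.numeric(grf_vertical) || length(grf_vertical) != 1L ||
      is.na(grf_vertical) || grf_vertical <= 0)
    stop("'grf_vertical' must be a single positive number", call. = FALSE)
  stopifnot(inherits(profile, "anthro_profile"))
  bw <- profile$body_mass * gravity
  const <- .adduction_constant(profile, tissue, activation, bw)
  L <- profile$ground_to_lateral_condyle
  mgT <- bw * profile$thigh_length
  if (surface$mu == 0) {
    denom <- grf_vertical * L - mgT
    # Fy within rounding of the alpha = 90 threshold balances exactly there
    if (denom <= const) {
      if (denom >= const * (1 - 1e-9)) return(90)
      return(NA_real_)  # below the alpha = 90 minimum threshold
    }
    ratio <- const / denom
    # asin is ill-conditioned at 1: within rounding of the endpoint, snap
    if (ratio >= 1 - 1e-14) return(90)
    return(asin(ratio) * 180 / pi)
  }
  residual <- function(a_deg) {
    grf_vertical * L * (.sin_deg(a_deg) - surface$mu * .cos_deg(a_deg)) -
      (const + mgT * .sin_deg(a_deg))
  }
  if (residual(90) < 0) return(NA_real_)
  # threshold diverges as alpha approaches atan(mu): bracket just above it
  lo <- max(atan(surface$mu) * 180 / pi, 0) + 1e-9
  if (residual(lo) >= 0) return(lo)
  stats::uniroot(residual, c(lo, 90), tol = 1e-12)$root
}

#' Generate the angle-of-damage threshold curve
#'
#' Samples the critical GRF on a closed regular grid of shin angles,
#' reproducing the published curve-generation procedure (0.01 degree steps
#' by default, from 0.01 to 90 degrees; the grid starts above zero because
#' the zero-traction threshold diverges at alpha = 0). Grid cells whose
#' effective abduction lever is non-positive (possible when mu > 0) carry
#' `Inf` and are flagged `unreachable`.
#'
#' @param angle_min,angle_max Grid limits in degrees, 0 <= min < max <= 90.
#' @param step Grid step in degrees (> 0).
#' @inheritParams critical_grf
#' @return A data.frame of class `threshold_curve` with columns
#'   `angle_deg`, `critical_grf_N`, `critical_grf_BW` (Fy divided by
#'   body_mass x gravity), `mu` and `unreachable`; model parameters are
#'   attached as the `"parameters"` attribute.
#' @examples
#' curve <- generate_curve(step = 1)
#' head(curve)
#' @export
generate_curve <- function(angle_min = 0.01, angle_max = 90, step = 0.01,
                           profile = average_profile(),
                           tissue = tissue_parameters(),
                           activation = activation_state(),
                           surface = surface_state(), gravity = 10) {
  if (!is.numeric(angle_min) || !is.numeric(angle_max) ||
      !is.numeric(step) || length(step) != 1L || step <= 0 ||
      angle_min < 0 || angle_max > 90 || angle_min >= angle_max)
    stop("need 0 <= angle_min < angle_max <= 90 and step > 0",
         call. = FALSE)
  angles <- pmin(seq(angle_min, angle_max, by = step), angle_max)
  crit <- critical_grf(angles, profile, tissue, activation, surface,
                       gravity, no_solution = "inf")
  bw <- profile$body_mass * gravity
  out <- data.frame(angle_deg = angles, critical_grf_N = crit,
                    critical_grf_BW = crit / bw, mu = surface$mu,
                    unreachable = !is.finite(crit))
  structure(out, class = c("threshold_curve", "data.frame"),
            parameters = list(profile = unclass(profile),
                              tissue = unclass(tissue),
                              activation = unclass(activation),
                              surface = unclass(surface),
                              gravity = gravity,
                              grid = list(angle_min = angle_min,
                                          angle_max = angle_max,
                                          step = step)))
}

#' Classify a landing scenario against the injury threshold
#'
#' A scenario is at risk when its GRF abduction torque strictly exceeds the
#' total adduction torque (a GRF exactly at the threshold balances and is
#' classified safe). The margin is the net abduction torque in N m.
#'
#' @param scenario A `landing_scenario`.
#' @param tissue A `tissue_parameters`.
#' @return A list with elements `at_risk` (logical) and `margin_Nm`.
#' @export
classify_risk <- function(scenario, tissue = tissue_parameters()) {
  margin <- net_abduction_torque(scenario, tissue)
  list(at_risk = margin > 0, margin_Nm = margin)
}
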