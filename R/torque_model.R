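#' Tissue force parameters
#'
#' Maximal forces the passive and active adduction-side structures can
#' develop, taken at their literature maxima (the model's conservative
#' convention): ACL ultimate tensile strength 2300 N, MCL 799 N, quadriceps
#' maximal force 8000 N, gastrocnemius medialis 931 N, and the
#' semitendinosus-semimembranosus group at 2 bodyweights.
#'
#' @param acl_max_force,mcl_max_force,quad_max_force,gastroc_max_force
#'   Maximal forces in N.
#' @param semit_force_bw_multiple Semitendinosus group force as a multiple
#'   of bodyweight (body_mass x gravity).
#' @return An object of class `tissue_parameters`.
#' @export
tissue_parameters <- function(acl_max_force = 2300, mcl_max_force = 799,
                              quad_max_force = 8000,
                              gastroc_max_force = 931,
                              semit_force_bw_multiple = 2) {
  p <- list(acl_max_force = acl_max_force, mcl_max_force = mcl_max_force,
            quad_max_force = quad_max_force,
            gastroc_max_force = gastroc_max_force,
            semit_force_bw_multiple = semit_force_bw_multiple)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  structure(p, class = "tissue_parameters")
}

#' Muscle and ligament activation fractions
#'
#' Scales each adduction-side contribution between 0 (silent / unloaded)
#' and 1 (full activation / ultimate strength). The default of 1 everywhere
#' is the conservative full-activation assumption used to locate the injury
#' threshold; lowering a fraction models delayed or disturbed activation.
#'
#' @param quad_fraction,semit_fraction,gastroc_fraction,ligament_fraction
#'   Fractions in \[0, 1\].
#' @return An object of class `activation_state`.
#' @export
activation_state <- function(quad_fraction = 1, semit_fraction = 1,
                             gastroc_fraction = 1, ligament_fraction = 1) {
  p <- list(quad_fraction = quad_fraction, semit_fraction = semit_fraction,
            gastroc_fraction = gastroc_fraction,
            ligament_fraction = ligament_fraction)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(p, class = "activation_state")
}

#' Shoe-surface traction state
#'
#' Coulomb friction coefficient between shoe and surface. The model's
#' boundary condition is the perfectly slippery surface mu = 0, where the
#' horizontal ground-reaction component vanishes and the abduction torque is
#' maximal; mu > 0 lets a horizontal component mu * Fy oppose the lateral
#' slide of the foot and unload the ACL.
#'
#' @param mu Friction coefficient >= 0.
#' @return An object of class `surface_state`.
#' @export
surface_state <- function(mu = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single non-negative number", call. = FALSE)
  structure(list(mu = mu), class = "surface_state")
}

#' A single-leg landing scenario
#'
#' @param shin_angle Angle of the shank from the vertical, degrees in
#'   \[0, 90\] (frontal plane).
#' @param grf_vertical Vertical ground reaction force Fy, N (>= 0).
#' @param profile An `anthro_profile`.
#' @param activation An `activation_state`.
#' @param surface A `surface_state`.
#' @param gravity Gravitational constant in m/s^2 (default 10, so the
#'   80.2 kg reference subject weighs 802 N).
#' @return An object of class `landing_scenario`.
#' @export
landing_scenario <- function(shin_angle, grf_vertical,
                             profile = average_profile(),
                             activation = activation_state(),
                             surface = surface_state(),
                             gravity = 10) {
  .check_angle(shin_angle)
  if (!is.numeric(grf_vertical) || length(grf_vertical) != 1L ||
      is.na(grf_vertical) || grf_vertical < 0)
    stop("'grf_vertical' must be a single non-negative number",
         call. = FALSE)
  stopifnot(inherits(profile, "anthro_profile"),
            inherits(activation, "activation_state"),
            inherits(surface, "surface_state"))
  if (!is.numeric(gravity) || length(gravity) != 1L || gravity <= 0)
    stop("'gravity' must be a single positive number", call. = FALSE)
  structure(list(shin_angle = shin_angle, grf_vertical = grf_vertical,
                 profile = profile, activation = activation,
                 surface = surface, gravity = gravity),
            class = "landing_scenario")
}

.check_angle <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0) ||
      any(alpha > 90))
    stop("shin angle must lie in [0, 90] degrees", call. = FALSE)
  invisible(alpha)
}

# sinpi/cospi keep the grid endpoints exact: sin(90 deg) = 1, cos(90 deg) = 0
.sin_deg <- function(deg) sinpi(deg / 180)
.cos_deg <- function(deg) cospi(deg / 180)

#' Moment arm of the vertical GRF about the lateral condyle
#'
#' The vertical GRF acts at the foot contact point; its lever about the
#' lateral condyle is the ground-to-lateral-condyle distance projected onto
#' the horizontal, `ground_to_lateral_condyle * sin(alpha)`.
#'
#' @param profile An `anthro_profile`.
#' @param shin_angle Shin angle in degrees, \[0, 90\]; vectorised.
#' @return Moment arm(s) in m.
#' @examples
#' grf_abduction_moment_arm(average_profile(), 90)  # 0.59486
#' @export
grf_abduction_moment_arm <- function(profile, shin_angle) {
  stopifnot(inherits(profile, "anthro_profile"))
  .check_angle(shin_angle)
  profile$ground_to_lateral_condyle * .sin_deg(shin_angle)
}

#' Moment arm of bodyweight (COG) about the lateral condyle
#'
#' With the trunk vertical, the centre of gravity sits over the hip, so its
#' lever about the lateral condyle is the bi-acetabular half-distance plus
#' the thigh length projected onto the horizontal:
#' `half_biacetabular + thigh_length * sin(alpha)`.
#'
#' @inheritParams grf_abduction_moment_arm
#' @return Moment arm(s) in m.
#' @examples
#' cog_adduction_moment_arm(average_profile(), 0)  # 0.12378
#' @export
cog_adduction_moment_arm <- function(profile, shin_angle) {
  stopifnot(inherits(profile, "anthro_profile"))
  .check_angle(shin_angle)
  profile$half_biacetabular + profile$thigh_length * .sin_deg(shin_angle)
}

#' Abduction torque from the ground reaction force
#'
#' The vertical component Fy drives abduction with lever
#' `L * sin(alpha)` (L = ground-to-lateral-condyle distance). With traction,
#' the Coulomb slip limit `Fx = mu * Fy` opposes the lateral slide with
#' lever `L * cos(alpha)`, so the net GRF abduction torque is
#' `max(0, Fy * L * (sin(alpha) - mu * cos(alpha)))`; the clamp encodes that
#' friction can cancel, but never reverse, the GRF's abduction action. With
#' mu = 0 this reduces to the slippery-surface expression `Fy * L * sin(alpha)`.
#'
#' @param scenario A `landing_scenario`.
#' @return Torque in N m (abduction positive).
#' @export
abduction_torque <- function(scenario) {
  stopifnot(inherits(scenario, "landing_scenario"))
  a <- scenario$shin_angle
  L <- scenario$profile$ground_to_lateral_condyle
  lever <- L * (.sin_deg(a) - scenario$surface$mu * .cos_deg(a))
  max(0, scenario$grf_vertical * lever)
}

#' Total adduction torque about the lateral condyle
#'
#' Sums the restraining torques: ligaments (ACL and MCL at their maximal
#' stresses scaled by `ligament_fraction`), the quadriceps through the
#' patellar tendon acting at half the intercondylar distance, the
#' semitendinosus group (a bodyweight multiple acting at the MCL arm), and
#' bodyweight at the COG lever. The gastrocnemius medialis is excluded
#' unless a moment arm is supplied (`gastroc_arm`), as the reference balance
#' omits it.
#'
#' @param scenario A `landing_scenario`.
#' @param tissue A `tissue_parameters`.
#' @param gastroc_arm Optional gastrocnemius medialis moment arm in m;
#'   `NULL` (default) excludes the term.
#' @return Torque in N m (adduction positive).
#' @export
adduction_torque <- function(scenario, tissue = tissue_parameters(),
                             gastroc_arm = NULL) {
  stopifnot(inherits(scenario, "landing_scenario"),
            inherits(tissue, "tissue_parameters"))
  p <- scenario$profile
  act <- scenario$activation
  bw <- p$body_mass * scenario$gravity
  const <- .adduction_constant(p, tissue, act, bw, gastroc_arm)
  const + bw * p$thigh_length * .sin_deg(scenario$shin_angle)
}

# angle-independent part of the adduction torque (N m); bw = m*g in N
.adduction_constant <- function(profile, tissue, activation, bw,
                                gastroc_arm = NULL) {
  out <- activation$ligament_fraction *
    (tissue$acl_max_force * profile$acl_moment_arm +
       tissue$mcl_max_force * profile$mcl_moment_arm) +
    activation$quad_fraction * tissue$quad_max_force *
      profile$intercondylar_distance / 2 +
    activation$semit_fraction * tissue$semit_force_bw_multiple * bw *
      profile$mcl_moment_arm +
    bw * profile$half_biacetabular
  if (!is.null(gastroc_arm))
    out <- out + activation$gastroc_fraction * tissue$gastroc_max_force *
      gastroc_arm
  out
}

#' Net abduction torque
#'
#' `abduction_torque - adduction_torque`; positive values mean the GRF
#' overwhelms the restraints and the scenario is past the injury threshold.
#'
#' @inheritParams adduction_torque
#' @return Torque in N m (may be negative).
#' @export
net_abduction_torque <- function(scenario, tissue = tissue_parameters(),
                                 gastroc_arm = NULL) {
  abduction_torque(scenario) -
    adduction_torque(scenario, tissue, gastroc_arm)
}
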