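#' Monte Carlo threshold propagation over a cohort
#'
#' Evaluates the critical GRF at each queried shin angle for every subject
#' of a cohort and summarises the spread with percentile bands. Percentiles
#' use linear interpolation between order statistics
#' ([stats::quantile] type 7); band values depend on this definition, so it
#' is fixed and documented rather than configurable.
#'
#' @param cohort Cohort data.frame in the mm/kg file schema (one subject
#'   per row), e.g. from [synthesize_cohort] or [read_cohort].
#' @param angles Shin angles in degrees, each in (0, 90].
#' @param tissue A `tissue_parameters`.
#' @param activation An `activation_state`.
#' @param surface A `surface_state`.
#' @param gravity Gravitational constant, m/s^2.
#' @param probs Percentile levels for the bands (fractions in \[0, 1\]).
#' @return An object of class `cohort_result`: a list with
#'   \describe{
#'     \item{thresholds}{long data.frame `subject`, `angle_deg`,
#'       `critical_grf_N`, `critical_grf_BW` (per-subject bodyweight
#'       units).}
#'     \item{bands}{long data.frame `angle_deg`, `percentile`,
#'       `critical_grf_N`.}
#'     \item{parameters}{model parameter snapshot.}
#'   }
#' @export
cohort_thresholds <- function(cohort, angles,
                              tissue = tissue_parameters(),
                              activation = activation_state(),
                              surface = surface_state(), gravity = 10,
                              probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("'cohort' must be a non-empty data.frame", call. = FALSE)
  if (length(angles) == 0L)
    stop("'angles' must be non-empty", call. = FALSE)
  .check_angle(angles)
  if (any(angles == 0))
    stop("shin angle 0 has no finite zero-traction threshold",
         call. = FALSE)
  n <- nrow(cohort)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- suppressWarnings(profile_from_row(cohort[i, ]))
    crit <- critical_grf(angles, prof, tissue, activation, surface,
                         gravity, no_solution = "inf")
    per[[i]] <- data.frame(subject = i, angle_deg = angles,
                           critical_grf_N = crit,
                           critical_grf_BW = crit / (prof$body_mass * gravity))
  }
  thresholds <- do.call(rbind, per)
  bands <- do.call(rbind, lapply(angles, function(a) {
    x <- thresholds$critical_grf_N[thresholds$angle_deg == a]
    data.frame(angle_deg = a, percentile = probs,
               critical_grf_N = unname(stats::quantile(x, probs, type = 7)))
  }))
  structure(list(thresholds = thresholds, bands = bands,
                 parameters = list(tissue = unclass(tissue),
                                   activation = unclass(activation),
                                   surface = unclass(surface),
                                   gravity = gravity, probs = probs,
                                   n_subjects = n)),
            class = "cohort_result")
}

#' Fraction of a cohort at risk for a given landing
#'
#' @param result A `cohort_result`.
#' @param angle_deg Shin angle queried (must be one of the result's
#'   angles).
#' @param grf_vertical Vertical GRF in N.
#' @return Fraction in \[0, 1\] of subjects whose critical GRF is strictly
#'   below `grf_vertical` (strict, matching [classify_risk]).
#' @export
at_risk_fraction <- function(result, angle_deg, grf_vertical) {
  stopifnot(inherits(result, "cohort_result"))
  x <- result$thresholds$critical_grf_N[
    result$thresholds$angle_deg == angle_deg]
  if (length(x) == 0L)
    stop("angle ", angle_deg, " not present in the cohort result",
         call. = FALSE)
  mean(grf_vertical > x)
}

.sweep_parameters <- c("mu", "quad_fraction", "semit_fraction",
                       "ligament_fraction")

#' One-at-a-time parameter sweep of the threshold curve
#'
#' Recomputes the critical GRF across shin angles for each value of one
#' swept parameter (surface friction or an activation fraction), holding
#' everything else at the supplied baseline. Sweeps are one-at-a-time by
#' design; a full factorial is out of scope.
#'
#' @param parameter One of `"mu"`, `"quad_fraction"`, `"semit_fraction"`,
#'   `"ligament_fraction"`.
#' @param values Numeric values to sweep (mu >= 0; fractions in \[0, 1\]).
#' @param angles Shin angles in degrees, each in (0, 90].
#' @param profile An `anthro_profile`.
#' @param tissue A `tissue_parameters`.
#' @param activation Baseline `activation_state`.
#' @param surface Baseline `surface_state`.
#' @param gravity Gravitational constant, m/s^2.
#' @return A long data.frame with columns `parameter`, `value`,
#'   `angle_deg`, `critical_grf_N` (infinite thresholds appear as `Inf`).
#' @examples
#' sweep_parameter("mu", c(0, 0.2, 0.4), angles = 45)
#' @export
sweep_parameter <- function(parameter, values, angles,
                            profile = average_profile(),
                            tissue = tissue_parameters(),
                            activation = activation_state(),
                            surface = surface_state(), gravity = 10) {
  parameter <- match.arg(parameter, .sweep_parameters)
  if (length(values) == 0L || anyNA(values))
    stop("'values' must be non-empty and free of NA", call. = FALSE)
  if (parameter == "mu") {
    if (any(values < 0)) stop("mu values must be >= 0", call. = FALSE)
  } else if (any(values < 0 | values > 1)) {
    stop("activation fractions must lie in [0, 1]", call. = FALSE)
  }
  .check_angle(angles)
  rows <- lapply(values, function(v) {
    act <- activation
    surf <- surface
    if (parameter == "mu") surf <- surface_state(v) else act[[parameter]] <- v
    crit <- critical_grf(angles, profile, tissue, act, surf, gravity,
                         no_solution = "inf")
    data.frame(parameter = parameter, value = v, angle_deg = angles,
               critical_grf_N = crit)
  })
  do.call(rbind, rows)
}
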