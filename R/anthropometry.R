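#' Population parameters for the anthropometric model
#'
#' Bundles the per-variable mean and standard deviation (in mm, mass in kg)
#' that describe the reference cohort of young adult male handball players,
#' together with the gravitational constant used throughout the model.
#'
#' Defaults are the published reference values: five MRI/anthropometric
#' distances (lateral condyle to ACL, lateral condyle to MCL, intercondylar,
#' ground to lateral condyle, lateral condyle to greater trochanter), the
#' bi-acetabular half-distance taken from the literature (fixed, SD 0 unless
#' a spread is supplied), and body mass 80.2 +/- 6.8 kg. The gravitational
#' constant defaults to 10 m/s^2 so that the reference 80.2 kg body weighs
#' exactly 802 N, matching the coefficients of the reference torque balance.
#'
#' @param acl_mm,mcl_mm,intercondylar_mm,ground_lc_mm,thigh_mm,half_biacetabular_mm,mass_kg
#'   Two-element numeric vectors `c(mean, sd)`. Distances in mm, mass in kg.
#' @param gravity Gravitational constant in m/s^2.
#' @return An object of class `population_parameters`: a list with one
#'   `c(mean, sd)` pair per variable plus `gravity`.
#' @examples
#' pop <- population_parameters()
#' average_profile(pop)
#' @export
population_parameters <- function(acl_mm = c(26.06, 1.7),
                                  mcl_mm = c(68.8, 3.27),
                                  intercondylar_mm = c(58.46, 2.82),
                                  ground_lc_mm = c(594.86, 13.89),
                                  thigh_mm = c(461.8, 9.33),
                                  half_biacetabular_mm = c(123.78, 0),
                                  mass_kg = c(80.2, 6.8),
                                  gravity = 10) {
  vars <- list(acl_mm = acl_mm, mcl_mm = mcl_mm,
               intercondylar_mm = intercondylar_mm,
               ground_lc_mm = ground_lc_mm, thigh_mm = thigh_mm,
               half_biacetabular_mm = half_biacetabular_mm,
               mass_kg = mass_kg)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v))
      stop("'", nm, "' must be a numeric c(mean, sd) pair", call. = FALSE)
    if (v[1] <= 0)
      stop("mean of '", nm, "' must be strictly positive", call. = FALSE)
    if (v[2] < 0)
      stop("sd of '", nm, "' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(gravity) || length(gravity) != 1L || gravity <= 0)
    stop("'gravity' must be a single positive number", call. = FALSE)
  structure(c(lapply(vars, function(v) c(mean = v[1], sd = v[2])),
              list(gravity = gravity)),
            class = "population_parameters")
}

# mm-file column order shared by cohort I/O and the profile constructor
.cohort_columns <- c("acl_mm", "mcl_mm", "intercondylar_mm", "ground_lc_mm",
                     "thigh_mm", "half_biacetabular_mm", "mass_kg")

#' Construct a single-subject anthropometric profile
#'
#' A profile holds the six frontal-plane distances (in metres) and the body
#' mass (kg) that fix one subject's moment-arm geometry about the lateral
#' femoral condyle. All internal computation uses SI units; file interfaces
#' carry mm and kg.
#'
#' The lateral condyle to MCL distance doubles as the semitendinosus moment
#' arm; the patellar tendon acts at half the intercondylar distance.
#'
#' @param acl_moment_arm Lateral condyle to ACL distance, m.
#' @param mcl_moment_arm Lateral condyle to MCL distance, m (also the
#'   semitendinosus moment arm).
#' @param intercondylar_distance Lateral to medial condyle distance, m.
#' @param ground_to_lateral_condyle Ground to lateral condyle distance, m.
#' @param thigh_length Lateral condyle to greater trochanter distance, m.
#' @param half_biacetabular Bi-acetabular half-distance, m.
#' @param body_mass Body mass, kg.
#' @return An object of class `anthro_profile`.
#' @export
anthropometric_profile <- function(acl_moment_arm, mcl_moment_arm,
                                   intercondylar_distance,
                                   ground_to_lateral_condyle,
                                   thigh_length, half_biacetabular,
                                   body_mass) {
  p <- list(acl_moment_arm = acl_moment_arm,
            mcl_moment_arm = mcl_moment_arm,
            intercondylar_distance = intercondylar_distance,
            ground_to_lateral_condyle = ground_to_lateral_condyle,
            thigh_length = thigh_length,
            half_biacetabular = half_biacetabular,
            body_mass = body_mass)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("'", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  # holds for the population averages; violations flag implausible input
  if (!(p$acl_moment_arm < p$mcl_moment_arm &&
        p$mcl_moment_arm < p$ground_to_lateral_condyle))
    warning("expected acl_moment_arm < mcl_moment_arm < ",
            "ground_to_lateral_condyle; check units (metres expected)",
            call. = FALSE)
  structure(p, class = "anthro_profile")
}

#' @export
print.anthro_profile <- function(x, ...) {
  cat("Anthropometric profile (m, kg):\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Average-subject profile from population means
#'
#' Builds the profile of the average subject by converting the population
#' mean distances from mm to m. With the default reference parameters this
#' profile reproduces every coefficient of the reference torque-balance
#' equation (e.g. ground-to-lateral-condyle 0.59486 m, ACL arm 0.02606 m).
#'
#' @param pop A `population_parameters` object.
#' @return An `anthro_profile`.
#' @export
average_profile <- function(pop = population_parameters()) {
  stopifnot(inherits(pop, "population_parameters"))
  m <- vapply(pop[.cohort_columns], `[[`, numeric(1), "mean")
  anthropometric_profile(
    acl_moment_arm = m[["acl_mm"]] / 1000,
    mcl_moment_arm = m[["mcl_mm"]] / 1000,
    intercondylar_distance = m[["intercondylar_mm"]] / 1000,
    ground_to_lateral_condyle = m[["ground_lc_mm"]] / 1000,
    thigh_length = m[["thigh_mm"]] / 1000,
    half_biacetabular = m[["half_biacetabular_mm"]] / 1000,
    body_mass = m[["mass_kg"]])
}

# Rejection-sampled Gaussian truncated below at `floor`; deterministic given
# the RNG state. SDs are small relative to means so redraws are rare.
.rtruncnorm_floor <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Synthesize a cohort of anthropometric profiles
#'
#' Draws `n` subjects with each variable sampled independently from a
#' Gaussian with the population mean and SD, truncated below at a positive
#' floor (the larger of mean - 4 sd and `floor_mm`) so lengths and masses
#' stay physical. An optional correlation matrix over the seven variables
#' induces correlated draws via a Cholesky transform; the published cohort
#' reports no covariances, so the default is independence.
#'
#' @param pop A `population_parameters` object.
#' @param n Number of subjects (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param floor_mm Absolute lower floor in mm (kg for mass), default 1.
#' @param correlation Optional 7x7 correlation matrix ordered as the cohort
#'   columns; `NULL` (default) samples independently.
#' @return A data.frame with columns `acl_mm`, `mcl_mm`, `intercondylar_mm`,
#'   `ground_lc_mm`, `thigh_mm`, `half_biacetabular_mm`, `mass_kg`, one row
#'   per subject (units mm and kg, matching the cohort file schema).
#' @examples
#' coh <- synthesize_cohort(population_parameters(), n = 15, seed = 1)
#' colMeans(coh)
#' @export
synthesize_cohort <- function(pop, n, seed, floor_mm = 1,
                              correlation = NULL) {
  stopifnot(inherits(pop, "population_parameters"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != floor(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  n <- as.integer(n)
  means <- vapply(pop[.cohort_columns], `[[`, numeric(1), "mean")
  sds <- vapply(pop[.cohort_columns], `[[`, numeric(1), "sd")
  floors <- pmax(means - 4 * sds, floor_mm)
  out <- matrix(numeric(0), nrow = n, ncol = length(.cohort_columns),
                dimnames = list(NULL, .cohort_columns))
  if (n > 0L) {
    set.seed(as.integer(seed))
    if (is.null(correlation)) {
      for (j in seq_along(.cohort_columns))
        out[, j] <- .rtruncnorm_floor(n, means[j], sds[j], floors[j])
    } else {
      if (!is.matrix(correlation) || !all(dim(correlation) == 7L))
        stop("'correlation' must be a 7x7 matrix", call. = FALSE)
      z <- matrix(stats::rnorm(n * 7L), nrow = n) %*% chol(correlation)
      out <- sweep(sweep(z, 2L, sds, `*`), 2L, means, `+`)
      colnames(out) <- .cohort_columns
      out <- pmax(out, matrix(floors, n, 7L, byrow = TRUE))
    }
  }
  as.data.frame(out)
}

#' Convert one cohort row to an anthropometric profile
#'
#' @param row A one-row data.frame (or named list/vector) using the cohort
#'   column schema in mm and kg.
#' @return An `anthro_profile` in metres and kg.
#' @export
profile_from_row <- function(row) {
  row <- as.list(row)
  missing <- setdiff(.cohort_columns, names(row))
  if (length(missing) > 0L)
    stop("cohort row missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  anthropometric_profile(
    acl_moment_arm = row$acl_mm / 1000,
    mcl_moment_arm = row$mcl_mm / 1000,
    intercondylar_distance = row$intercondylar_mm / 1000,
    ground_to_lateral_condyle = row$ground_lc_mm / 1000,
    thigh_length = row$thigh_mm / 1000,
    half_biacetabular = row$half_biacetabular_mm / 1000,
    body_mass = row$mass_kg)
}

#' Convert a profile back to the mm/kg cohort row representation
#'
#' @param profile An `anthro_profile`.
#' @return A one-row data.frame in the cohort file schema.
#' @export
profile_to_row <- function(profile) {
  stopifnot(inherits(profile, "anthro_profile"))
  data.frame(acl_mm = profile$acl_moment_arm * 1000,
             mcl_mm = profile$mcl_moment_arm * 1000,
             intercondylar_mm = profile$intercondylar_distance * 1000,
             ground_lc_mm = profile$ground_to_lateral_condyle * 1000,
             thigh_mm = profile$thigh_length * 1000,
             half_biacetabular_mm = profile$half_biacetabular * 1000,
             mass_kg = profile$body_mass)
}

#' Read / write a cohort CSV (mm and kg)
#'
#' The cohort file is comma-delimited UTF-8 with a fixed header:
#' `acl_mm, mcl_mm, intercondylar_mm, ground_lc_mm, thigh_mm,
#' half_biacetabular_mm, mass_kg`, one subject per row.
#'
#' @param path File path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  missing <- setdiff(.cohort_columns, names(df))
  if (length(missing) > 0L)
    stop("cohort file ", path, " missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[.cohort_columns]
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame in the fixed schema.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(.cohort_columns, names(cohort))
  if (length(missing) > 0L)
    stop("cohort missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(format(cohort[.cohort_columns], digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
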