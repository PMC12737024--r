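#' Default run configuration
#'
#' A run configuration bundles everything needed to reproduce an analysis:
#' population parameters (mm/kg means and SDs), tissue forces, activation
#' fractions, surface friction, the angle grid, cohort size and RNG seed.
#' It is fully serialisable: the JSON sidecar written next to every output
#' re-runs to identical results.
#'
#' @return A nested list of class `run_config` holding all model defaults.
#' @examples
#' cfg <- default_config()
#' cfg$surface$mu <- 0.3
#' @export
default_config <- function() {
  pop <- population_parameters()
  structure(list(
    population = lapply(unclass(pop)[.cohort_columns], as.list),
    gravity = pop$gravity,
    tissue = unclass(tissue_parameters()),
    activation = unclass(activation_state()),
    surface = unclass(surface_state()),
    grid = list(angle_min = 0.01, angle_max = 90, step = 0.01),
    cohort = list(n = 15, seed = 1),
    percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields absent from the file keep their defaults, so a config file may
#' override only what it changes. Format is chosen by file extension
#' (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Path to a YAML or JSON config file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, raw)
  class(cfg) <- "run_config"
  .validate_config(cfg)
  cfg
}

#' Write a run configuration
#'
#' @param config A `run_config`.
#' @param path Destination path (`.yml`/`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

.validate_config <- function(config) {
  # constructors enforce the invariants; building the objects validates
  invisible(.config_objects(config))
}

# materialise the model objects a config describes
.config_objects <- function(config) {
  pop <- do.call(population_parameters,
                 c(lapply(config$population, function(v)
                     c(v$mean, v$sd)),
                   list(gravity = config$gravity)))
  list(pop = pop,
       profile = average_profile(pop),
       tissue = do.call(tissue_parameters, config$tissue),
       activation = do.call(activation_state, config$activation),
       surface = do.call(surface_state, config$surface),
       gravity = config$gravity)
}

#' Print the fully resolved configuration
#'
#' Dumps the effective parameter set (defaults merged with any overrides)
#' as YAML, so the provenance of every coefficient is auditable.
#'
#' @param config A `run_config`.
#' @return `config`, invisibly.
#' @export
show_config <- function(config = default_config()) {
  cat(yaml::as.yaml(unclass(config)))
  invisible(config)
}

# every artifact gets a machine-readable sidecar sufficient to re-run it
.write_sidecar <- function(config, path, extra = list()) {
  jsonlite::write_json(c(list(config = unclass(config)), extra), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the average-profile threshold curve analysis
#'
#' Generates the angle-of-damage curve for the config's average profile and
#' writes `curve.csv` (columns `angle_deg`, `critical_grf_N`,
#' `critical_grf_BW`, `mu`), a `curve_config.json` sidecar and, optionally,
#' a `curve.png` figure.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if absent).
#' @param plot Whether to also write the figure (default `FALSE`).
#' @return The `threshold_curve`, invisibly.
#' @export
run_curve <- function(config = default_config(), out_dir, plot = FALSE) {
  obj <- .config_objects(config)
  .ensure_dir(out_dir)
  curve <- generate_curve(config$grid$angle_min, config$grid$angle_max,
                          config$grid$step, obj$profile, obj$tissue,
                          obj$activation, obj$surface, obj$gravity)
  utils::write.csv(
    format(as.data.frame(curve)[c("angle_deg", "critical_grf_N",
                                  "critical_grf_BW", "mu")],
           digits = 15, scientific = FALSE, trim = TRUE),
    file.path(out_dir, "curve.csv"), row.names = FALSE, quote = FALSE,
    eol = "\n")
  .write_sidecar(config, file.path(out_dir, "curve_config.json"))
  if (plot)
    ggplot2::ggsave(file.path(out_dir, "curve.png"), plot_curve(curve),
                    width = 7, height = 5, dpi = 150)
  invisible(curve)
}

#' Run the cohort synthesis and Monte Carlo threshold analysis
#'
#' Synthesizes a cohort from the config's population parameters, writes it
#' as `cohort.csv` (mm/kg schema), propagates it through the threshold
#' model on the queried angles, and writes `cohort_thresholds.csv` and
#' `cohort_bands.csv` (tidy long format) with a `cohort_config.json`
#' sidecar recording the seed.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if absent).
#' @param angles Shin angles (degrees) at which to evaluate thresholds.
#' @return The `cohort_result`, invisibly.
#' @export
run_cohort <- function(config = default_config(), out_dir,
                       angles = c(15, 30, 45, 60, 75, 90)) {
  obj <- .config_objects(config)
  .ensure_dir(out_dir)
  cohort <- synthesize_cohort(obj$pop, config$cohort$n, config$cohort$seed)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  result <- cohort_thresholds(cohort, angles, obj$tissue, obj$activation,
                              obj$surface, obj$gravity,
                              probs = config$percentiles)
  utils::write.csv(result$thresholds,
                   file.path(out_dir, "cohort_thresholds.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(result$bands, file.path(out_dir, "cohort_bands.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  .write_sidecar(config, file.path(out_dir, "cohort_config.json"),
                 extra = list(angles = angles))
  invisible(result)
}

#' Run a one-at-a-time parameter sweep and export it
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if absent).
#' @param parameter,values Passed to [sweep_parameter].
#' @param angles Shin angles (degrees).
#' @return The sweep data.frame, invisibly.
#' @export
run_sweep <- function(config = default_config(), out_dir, parameter,
                      values, angles = c(15, 30, 45, 60, 75, 90)) {
  obj <- .config_objects(config)
  .ensure_dir(out_dir)
  sw <- sweep_parameter(parameter, values, angles, obj$profile,
                        obj$tissue, obj$activation, obj$surface,
                        obj$gravity)
  utils::write.csv(sw, file.path(out_dir, paste0("sweep_", parameter,
                                                 ".csv")),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  .write_sidecar(config, file.path(out_dir,
                                   paste0("sweep_", parameter,
                                          "_config.json")),
                 extra = list(parameter = parameter, values = values,
                              angles = angles))
  invisible(sw)
}

.ensure_dir <- function(path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path, call. = FALSE)
  if (file.access(path, mode = 2) != 0L)
    stop("output directory not writable: ", path, call. = FALSE)
  invisible(path)
}

#' Plot a threshold curve in bodyweight units
#'
#' Reproduces the standard presentation of the angle-of-damage relation:
#' shin angle on the x axis, critical GRF in bodyweight multiples on the y
#' axis; landings above the curve are at risk.
#'
#' @param curve A `threshold_curve` (or a list of them, overlaid and
#'   coloured by `mu`).
#' @return A ggplot object.
#' @export
plot_curve <- function(curve) {
  if (inherits(curve, "threshold_curve")) curve <- list(curve)
  df <- do.call(rbind, lapply(curve, function(cv)
    as.data.frame(cv)[!cv$unreachable, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg,
                                   y = .data$critical_grf_BW,
                                   colour = factor(.data$mu))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "shin angle from vertical (degrees)",
                  y = "critical GRF (bodyweights)",
                  colour = expression(mu)) +
    ggplot2::coord_cartesian(ylim = c(0, min(20, max(df$critical_grf_BW)))) +
    ggplot2::theme_minimal()
}
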