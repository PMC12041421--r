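#' Read a simulation configuration from a flat key/value file
#'
#' Accepts YAML or JSON files whose keys use the standard parameter-table
#' names: `growth_rate`, `production_cost` and `resistance_cost` (in
#' percent), `toxin_coefficient`, `metabolite_diff`, `toxin_diff`,
#' `biomass_diff`, `space_width`, `spatial_seed`, `initial_biomass`,
#' `grid_size` (e.g. `"50 x 50"` or a two-element list),
#' `add_signal_parameter` (only `bounded_linear` is built in),
#' `conc_where_effect_ends`, `max_cycles` (hours), `dt` (hours),
#' `prod_ratio`, `density`. Unknown keys are rejected so typos do not pass
#' silently.
#'
#' @param path file path (`.yml`, `.yaml` or `.json`).
#' @param base base [simulation_config()] supplying defaults for keys the
#'   file omits.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path, base = simulation_config()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("growth_rate", "production_cost", "resistance_cost",
             "toxin_coefficient", "metabolite_diff", "toxin_diff",
             "biomass_diff", "space_width", "spatial_seed", "initial_biomass",
             "grid_size", "add_signal_parameter", "conc_where_effect_ends",
             "max_cycles", "dt", "prod_ratio", "density")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  cfg <- base
  g <- function(key, default) raw[[key]] %||% default
  if (!is.null(raw$add_signal_parameter) &&
      !identical(raw$add_signal_parameter, "bounded_linear")) {
    abort("only the bounded_linear signal form is built in")
  }
  cfg$growth_rate <- g("growth_rate", cfg$growth_rate)
  cfg$production_cost <- g("production_cost", cfg$production_cost * 100) / 100
  cfg$resistance_cost <- g("resistance_cost", cfg$resistance_cost * 100) / 100
  cfg$toxin_coefficient <- g("toxin_coefficient", cfg$toxin_coefficient)
  cfg$conc_where_effect_ends <- g("conc_where_effect_ends",
                                  cfg$conc_where_effect_ends)
  cfg$spatial_seed <- as.integer(g("spatial_seed", cfg$spatial_seed))
  cfg$initial_biomass <- g("initial_biomass", cfg$initial_biomass)
  cfg$max_time <- g("max_cycles", cfg$max_time)
  cfg$dt <- g("dt", cfg$dt)
  grid <- raw$grid_size
  if (!is.null(grid)) {
    if (is.character(grid)) {
      grid <- as.integer(strsplit(grid, "[^0-9]+")[[1]])
    }
    grid <- as.integer(grid)
    if (length(grid) == 1L) grid <- c(grid, grid)
  } else {
    grid <- c(cfg$lattice$nx, cfg$lattice$ny)
  }
  cfg$lattice <- lattice_config(
    nx = grid[1], ny = grid[2],
    dx = g("space_width", cfg$lattice$dx),
    metabolite_diff = g("metabolite_diff", cfg$lattice$metabolite_diff),
    toxin_diff = g("toxin_diff", cfg$lattice$toxin_diff),
    biomass_diff = g("biomass_diff", cfg$lattice$biomass_diff)
  )
  if (!is.null(raw$density) || !is.null(raw$prod_ratio)) {
    density <- g("density", sum(cfg$counts))
    prod_ratio <- g("prod_ratio",
                    unname(cfg$counts["producer"] / sum(cfg$counts)))
    cfg$counts <- colony_counts(density, prod_ratio)
  }
  cfg$hard_cap <- max(6 * cfg$max_time, 300)
  cfg
}

#' Write a simulation result to CSV tables
#'
#' Writes the per-colony biomass trajectory (`trajectory.csv`, long format),
#' the colony registry (`colonies.csv`), and the per-run metrics
#' (`metrics.csv`: relative fitness, toxin CV, proximity slope where
#' defined) into `dir`.
#'
#' @param result a `toxsim_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(result), file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(result$registry, file.path(dir, "colonies.csv"),
                   row.names = FALSE)
  fit <- fitness_summary(result)
  prox <- tryCatch(proximity_effect(result), error = function(e) NA_real_)
  metrics <- dplyr::bind_cols(
    fit,
    tibble::tibble(toxin_cv_max = suppressWarnings(toxin_cv_max(result)),
                   proximity_slope = prox,
                   converged = result$converged,
                   time_final = max(result$time))
  )
  long <- tidyr::pivot_longer(metrics, dplyr::everything(),
                              names_to = "metric", values_to = "value",
                              values_transform = as.character)
  utils::write.csv(long, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(dir)
}
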