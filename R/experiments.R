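#' Colony counts from total density and producer ratio
#'
#' Splits `density` founder colonies among the roles: producers and
#' resistant cheaters each get `round(prod_ratio * density)` colonies (they
#' are always seeded 1:1) and susceptibles absorb the remainder.
#'
#' @param density total number of founder colonies (default 50).
#' @param prod_ratio starting fraction of producer colonies (and equally of
#'   resistant colonies) in the total (default 0.1, i.e. the 80:10:10 ratio).
#' @return named integer vector with susceptible, resistant and producer
#'   counts.
#' @export
#' @examples
#' colony_counts(50, 0.1)  # 40 / 5 / 5
#' colony_counts(10, 0.1)  # 8 / 1 / 1
colony_counts <- function(density = 50, prod_ratio = 0.1) {
  n_p <- as.integer(round(prod_ratio * density))
  n_s <- as.integer(density) - 2L * n_p
  if (n_s < 0) abort("prod_ratio too large: susceptible count would be negative")
  c(susceptible = n_s, resistant = n_p, producer = n_p)
}

#' Preset: growth-rate series at default parameters
#'
#' The reference experiment: growth rates 0.125 to 1 hr^-1, fifteen seeded
#' spatial layouts per rate plus one well-mixed (liquid) run per rate, all
#' other parameters at their defaults (1% production cost, toxin coefficient
#' 15, 40/5/5 colonies).
#'
#' @param growth_rates growth-rate axis (hr^-1).
#' @param seeds layout seeds for the spatial replicates (default 1:15).
#' @param base base [simulation_config()] to modify.
#' @param liquid include one well-mixed run per growth rate (default TRUE).
#' @return a `sweep_spec`: run grid plus base configuration.
#' @export
preset_growth_rate_series <- function(growth_rates = c(0.125, 0.25, 0.5, 0.75, 1),
                                      seeds = 1:15,
                                      base = simulation_config(),
                                      liquid = TRUE) {
  grid <- tidyr::expand_grid(environment = "spatial",
                             growth_rate = growth_rates, seed = seeds)
  if (liquid) {
    grid <- dplyr::bind_rows(
      grid,
      tibble::tibble(environment = "liquid", growth_rate = growth_rates,
                     seed = NA_integer_)
    )
  }
  new_sweep_spec(grid, base)
}

#' Preset: one-axis parameter sweep crossed with growth rate
#'
#' Sweeps a single parameter axis against the growth-rate axis with three
#' seeded spatial layouts per cell. Axes and their default values:
#' `toxin_coefficient` (1, 15, 30, 50, 75 mmol/gDW), `toxin_diff` (5e-8 to
#' 5e-5 cm^2/s), `density` (10 to 90 total colonies at the fixed 80:10:10
#' role ratio) and `prod_ratio` (0.02 to 0.4 producer and resistant colony
#' fraction each, susceptibles taking the rest).
#'
#' @param axis which parameter to sweep.
#' @param values axis values; defaults to the standard set for the axis.
#' @param growth_rates growth-rate axis (hr^-1).
#' @param seeds layout seeds (default `c(1, 2, 5)`).
#' @param base base [simulation_config()].
#' @return a `sweep_spec`.
#' @export
#' @examples
#' spec <- preset_parameter_sweep("toxin_coefficient",
#'                                growth_rates = c(0.5, 1), seeds = 1:2)
#' nrow(spec$grid)
preset_parameter_sweep <- function(axis = c("toxin_coefficient", "toxin_diff",
                                            "density", "prod_ratio"),
                                   values = NULL,
                                   growth_rates = c(0.125, 0.25, 0.5, 0.75, 1),
                                   seeds = c(1, 2, 5),
                                   base = simulation_config()) {
  axis <- match.arg(axis)
  values <- values %||% switch(axis,
    toxin_coefficient = c(1, 15, 30, 50, 75),
    toxin_diff = c(5e-8, 5e-7, 5e-6, 2.5e-5, 5e-5),
    density = c(10, 30, 50, 70, 90),
    prod_ratio = c(0.02, 0.06, 0.1, 0.2, 0.3, 0.4)
  )
  if (length(values) == 0) abort("axis values must be non-empty")
  if (anyDuplicated(seeds)) abort("replicate seeds must be distinct")
  grid <- tidyr::expand_grid(environment = "spatial",
                             !!axis := values,
                             growth_rate = growth_rates, seed = seeds)
  new_sweep_spec(grid, base, axis = axis)
}

new_sweep_spec <- function(grid, base, axis = NULL) {
  structure(list(grid = grid, base = base, axis = axis), class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec> %d runs%s\n", nrow(x$grid),
              if (!is.null(x$axis)) paste0(" over axis `", x$axis, "`") else ""))
  invisible(x)
}

# Build the concrete simulation_config for one grid row.
config_for_run <- function(base, row) {
  cfg <- base
  if (!is.null(row$growth_rate)) cfg$growth_rate <- row$growth_rate
  if (!is.null(row$toxin_coefficient)) cfg$toxin_coefficient <- row$toxin_coefficient
  if (!is.null(row$toxin_diff)) cfg$lattice$toxin_diff <- row$toxin_diff
  density <- if (!is.null(row$density)) row$density else sum(base$counts)
  prod_ratio <- if (!is.null(row$prod_ratio)) row$prod_ratio else {
    unname(base$counts["producer"] / sum(base$counts))
  }
  if (!is.null(row$density) || !is.null(row$prod_ratio)) {
    cfg$counts <- colony_counts(density, prod_ratio)
  }
  if (!is.null(row$seed) && !is.na(row$seed)) cfg$spatial_seed <- row$seed
  cfg
}

#' Run every simulation in a sweep and aggregate the metrics
#'
#' Executes each row of the sweep grid (spatial rows via [run_batch()],
#' liquid rows via [run_well_mixed()]) and returns one tidy row per run with
#' the parameters, the relative-fitness summary, the maximum spatial toxin
#' CV and, where defined, the proximity-effect slope. Results are
#' deterministic given the seeds and independent of `workers`.
#'
#' @param spec a `sweep_spec` from [preset_growth_rate_series()] or
#'   [preset_parameter_sweep()].
#' @param workers number of parallel worker processes (forked; default 1).
#' @return a tibble, one row per run.
#' @export
run_sweep <- function(spec, workers = 1L) {
  if (!inherits(spec, "sweep_spec")) abort("`spec` must be a sweep_spec")
  rows <- seq_len(nrow(spec$grid))
  run_one <- function(i) {
    row <- as.list(spec$grid[i, ])
    cfg <- config_for_run(spec$base, row)
    res <- tryCatch({
      if (identical(row$environment, "liquid")) run_well_mixed(cfg)
      else run_batch(cfg)
    }, error = function(e) {
      abort(sprintf("run %d (%s) failed: %s", i,
                    paste(names(row), unlist(row), sep = "=", collapse = ", "),
                    conditionMessage(e)))
    })
    init_freq <- unname(cfg$counts["producer"] / sum(cfg$counts))
    fit <- fitness_summary(res, initial_frequency = init_freq)
    prox <- if (identical(row$environment, "spatial") &&
                sum(res$registry$role == "susceptible") >= 2 &&
                sum(res$registry$role == "producer") >= 1) {
      tryCatch(proximity_effect(res), error = function(e) NA_real_)
    } else NA_real_
    dplyr::bind_cols(
      tibble::as_tibble(row),
      fit,
      tibble::tibble(
        toxin_cv_max = suppressWarnings(toxin_cv_max(res)),
        proximity_slope = prox,
        converged = res$converged,
        time_final = max(res$time)
      )
    )
  }
  out <- if (workers > 1L) {
    parallel::mclapply(rows, run_one, mc.cores = workers)
  } else {
    purrr::map(rows, run_one)
  }
  dplyr::bind_rows(out)
}
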