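#' Lattice geometry and transport coefficients
#'
#' @param nx,ny box counts (default 50 x 50).
#' @param dx side length of a box (cm, default 0.01).
#' @param metabolite_diff resource diffusion constant (cm^2 s^-1, default 5e-6).
#' @param toxin_diff toxin diffusion constant (cm^2 s^-1, default 5e-7).
#' @param biomass_diff biomass diffusion constant (cm^2 s^-1, default 5e-9;
#'   slow colony spreading relative to solutes).
#' @return an object of class `lattice_config`. Boundaries are no-flux.
#' @export
lattice_config <- function(nx = 50, ny = 50, dx = 0.01,
                           metabolite_diff = 5e-6, toxin_diff = 5e-7,
                           biomass_diff = 5e-9) {
  if (nx < 1 || ny < 1) abort("nx and ny must be >= 1")
  if (dx <= 0) abort("dx must be positive")
  if (min(metabolite_diff, toxin_diff, biomass_diff) < 0) {
    abort("diffusion constants must be non-negative")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 metabolite_diff = metabolite_diff, toxin_diff = toxin_diff,
                 biomass_diff = biomass_diff, boundary = "no_flux"),
            class = "lattice_config")
}

#' Configure a batch-culture community simulation
#'
#' Collects the environment, inoculum and strain parameters for one run.
#' Defaults reproduce the reference spatial experiment: a 50 x 50 lattice of
#' 0.01 cm boxes, each seeded once with 4e-7 mmol carbon; 50 founder
#' colonies (40 susceptible, 5 resistant, 5 producer) of 2e-10 gDW each at
#' random distinct boxes; toxin produced at 15 mmol/gDW with a 1% growth
#' cost; a bounded-linear susceptible response that reaches zero growth at a
#' toxin level of 15.
#'
#' The signal level seen by susceptibles is, by default, the local toxin
#' concentration in mmol cm^-3 (per-box amount divided by the box volume
#' `dx^3`); set `signal_on = "amount"` to use the raw per-box amount in mmol
#' instead.
#'
#' @param growth_rate target maximal growth rate mu (hr^-1) shared by all
#'   strains; the carbon uptake bound is derived so the realized maximum
#'   equals mu.
#' @param production_cost,resistance_cost fractional growth costs
#'   (defaults 0.01 and 0).
#' @param toxin_coefficient mmol toxin per gDW producer biomass (default 15).
#' @param conc_where_effect_ends signal level K at which susceptible growth
#'   reaches zero (default 15).
#' @param counts named integer vector of founder colonies per role
#'   (default `c(susceptible = 40, resistant = 5, producer = 5)`); see
#'   [colony_counts()] for the density/ratio helper.
#' @param initial_biomass per-colony inoculum (gDW, default 2e-10).
#' @param carbon_per_box initial carbon per box (mmol, default 4e-7).
#' @param lattice a [lattice_config()].
#' @param spatial_seed integer seed for colony placement.
#' @param dt macro time step (hr, default 0.1); diffusion is sub-stepped
#'   automatically to stay stable at any coefficient.
#' @param max_time nominal simulated duration (hr, default 75); runs extend
#'   past it until stationary phase.
#' @param hard_cap absolute time cap (hr); default `max(6 * max_time, 300)`.
#'   A run still changing at the cap is returned flagged, not silently.
#' @param stationary_tol relative total-biomass change per macro step below
#'   which the culture is considered stationary (default 1e-6).
#' @param yield gDW biomass per mmol carbon (default 1).
#' @param death_rate first-order death rate (hr^-1, default 0).
#' @param signal_on `"concentration"` (default) or `"amount"`.
#' @param record_every store toxin/carbon field snapshots every this many
#'   macro steps (default 5); summary statistics are recorded every step.
#' @return an object of class `sim_config`.
#' @seealso [run_batch()], [run_well_mixed()], [read_sim_config()]
#' @export
simulation_config <- function(growth_rate = 1,
                              production_cost = 0.01,
                              resistance_cost = 0,
                              toxin_coefficient = 15,
                              conc_where_effect_ends = 15,
                              counts = c(susceptible = 40, resistant = 5,
                                         producer = 5),
                              initial_biomass = 2e-10,
                              carbon_per_box = 4e-7,
                              lattice = lattice_config(),
                              spatial_seed = 1,
                              dt = 0.1,
                              max_time = 75,
                              hard_cap = NULL,
                              stationary_tol = 1e-6,
                              yield = 1,
                              death_rate = 0,
                              signal_on = c("concentration", "amount"),
                              record_every = 5L) {
  signal_on <- match.arg(signal_on)
  roles <- c("susceptible", "resistant", "producer")
  if (!all(names(counts) %in% roles)) abort("counts must be named by role")
  counts <- counts[intersect(roles, names(counts))]
  if (any(counts < 0)) abort("counts must be non-negative")
  if (carbon_per_box < 0) abort("carbon_per_box must be non-negative")
  if (dt <= 0) abort("dt must be positive")
  structure(list(
    growth_rate = growth_rate,
    production_cost = production_cost,
    resistance_cost = resistance_cost,
    toxin_coefficient = toxin_coefficient,
    conc_where_effect_ends = conc_where_effect_ends,
    counts = counts,
    initial_biomass = initial_biomass,
    carbon_per_box = carbon_per_box,
    lattice = lattice,
    spatial_seed = as.integer(spatial_seed),
    dt = dt,
    max_time = max_time,
    hard_cap = hard_cap %||% max(6 * max_time, 300),
    stationary_tol = stationary_tol,
    yield = yield,
    death_rate = death_rate,
    signal_on = signal_on,
    record_every = as.integer(record_every)
  ), class = "sim_config")
}

#' Place founder colonies at random distinct lattice boxes
#'
#' Samples `sum(counts)` distinct boxes uniformly without replacement using
#' a private RNG stream, so identical seeds give identical layouts and the
#' caller's RNG state is untouched. Coordinates are 0-based (row, col).
#'
#' @param seed integer seed.
#' @param counts named colony counts per role.
#' @param nx,ny lattice dimensions.
#' @return a tibble with columns `colony`, `role`, `row`, `col`.
#' @export
#' @examples
#' place_colonies(1, c(susceptible = 40, resistant = 5, producer = 5), 50, 50)
place_colonies <- function(seed, counts, nx, ny) {
  total <- sum(counts)
  if (total > nx * ny) abort("too many colonies for the grid")
  boxes <- with_private_seed(seed, sample.int(nx * ny, total))
  tibble::tibble(
    colony = seq_len(total),
    role = rep(names(counts), counts),
    row = (boxes - 1L) %% nx,
    col = (boxes - 1L) %/% nx
  )
}

#' One diffusion step on a lattice field
#'
#' Explicit 5-point stencil with no-flux boundaries, internally sub-stepped
#' so every sub-step satisfies `D * dt_sub / dx^2 <= 0.25` (stability), which
#' makes the update mass-conserving and non-negativity-preserving for any
#' `D` and `dt`. `D = 0` is the identity.
#'
#' @param field numeric matrix, non-negative.
#' @param D diffusion constant (cm^2 s^-1).
#' @param dt step length (hr).
#' @param dx box side (cm).
#' @return the diffused field (a new matrix).
#' @export
diffusion_step <- function(field, D, dt, dx) {
  if (D < 0) abort("D must be non-negative")
  if (dt <= 0 || dx <= 0) abort("dt and dx must be positive")
  f <- field + 0 # force a copy; the kernel works in place
  lambda <- D * 3600 * dt / dx^2 # cm^2/s -> cm^2/hr
  cpp_diffuse_inplace(f, lambda, n_substeps(lambda))
  f
}

n_substeps <- function(lambda) {
  if (lambda <= 0) 0L else as.integer(ceiling(lambda / 0.25))
}

# Per-colony parameter vectors used by the growth kernel. All strains share
# the same carbon uptake bound v_max = growth_rate / yield, so a strain with
# fractional cost c realizes at most growth_rate / (1 + c): the cost lowers
# both the growth rate and the biomass yield per carbon.
colony_params <- function(config, registry) {
  role <- registry$role
  cost <- ifelse(role == "producer", config$production_cost,
                 ifelse(role == "resistant", config$resistance_cost, 0))
  list(
    v_max = rep(config$growth_rate / config$yield, length(role)),
    cost = cost,
    yield = rep(config$yield, length(role)),
    tau = ifelse(role == "producer", config$toxin_coefficient, 0),
    delta = rep(config$death_rate, length(role)),
    susceptible = role == "susceptible"
  )
}

#' Advance every colony's biomass by one growth step
#'
#' Applies the per-box dFBA update for a single macro step `dt`: each
#' colony's growth rate comes from the closed-form flux solution under its
#' local carbon-limited uptake bound and its signal bound from the local
#' toxin level; when the summed carbon demand in a box exceeds the carbon
#' present, all colonies' uptake there is scaled by the same factor
#' (proportional allocation). Carbon is decremented and toxin incremented by
#' the corresponding stoichiometric amounts; no field can go negative.
#'
#' This is the engine of [run_batch()] exposed as a pure function on a world
#' state, mainly for testing and custom stepping schemes.
#'
#' @param state a `world_state`: list with `carbon` and `toxin` matrices, a
#'   biomass array `bio` (nx x ny x n_colonies), `registry`, `config`, `time`.
#' @param dt step length (hr).
#' @return the updated state (new copies of all fields, `time` advanced).
#' @export
growth_step <- function(state, dt) {
  if (dt <= 0) abort("dt must be positive")
  carbon <- state$carbon + 0
  toxin <- state$toxin + 0
  bio <- state$bio + 0
  p <- colony_params(state$config, state$registry)
  cpp_growth_inplace(carbon, toxin, bio,
                     p$v_max, p$cost, p$yield, p$tau, p$delta, p$susceptible,
                     state$config$conc_where_effect_ends,
                     state$vol_box,
                     state$config$signal_on == "concentration",
                     dt)
  state$carbon <- carbon; state$toxin <- toxin; state$bio <- bio
  state$time <- state$time + dt
  state
}

#' Initialise a world state from a configuration
#'
#' @param config a [simulation_config()].
#' @param registry optional colony registry (defaults to
#'   [place_colonies()] with the config's seed and counts).
#' @param vol_box signal reference volume per box (cm^3); defaults to `dx^3`.
#' @return a `world_state` list.
#' @export
init_world <- function(config, registry = NULL, vol_box = NULL) {
  lat <- config$lattice
  registry <- registry %||%
    place_colonies(config$spatial_seed, config$counts, lat$nx, lat$ny)
  nc <- nrow(registry)
  bio <- array(0, dim = c(lat$nx, lat$ny, nc))
  for (i in seq_len(nc)) {
    bio[registry$row[i] + 1L, registry$col[i] + 1L, i] <- config$initial_biomass
  }
  structure(list(
    time = 0,
    carbon = matrix(config$carbon_per_box, lat$nx, lat$ny),
    toxin = matrix(0, lat$nx, lat$ny),
    bio = bio,
    registry = registry,
    config = config,
    vol_box = vol_box %||% lat$dx^3
  ), class = "world_state")
}

#' Run a spatially structured batch-culture simulation
#'
#' Alternates [growth_step()] with diffusion of carbon, toxin and each
#' colony's biomass layer (operator splitting) until the total biomass
#' changes by less than `stationary_tol` (relative) over a macro step —
#' stationary phase — extending past `max_time` when needed. A run still
#' changing at `hard_cap` is returned with `converged = FALSE`.
#'
#' @param config a [simulation_config()].
#' @param registry optional pre-built colony registry (e.g. to share one
#'   layout across parameter values).
#' @return an object of class `toxsim_result`: per-colony biomass
#'   trajectories, per-step toxin field summaries (mean, sd, CV), periodic
#'   field snapshots, the final state, and the configuration echo. Use
#'   [tidy()] for a long trajectory tibble and [fitness_summary()],
#'   [toxin_cv_max()], [proximity_effect()] for the derived metrics.
#' @export
#' @examples
#' cfg <- simulation_config(lattice = lattice_config(nx = 10, ny = 10),
#'                          counts = c(susceptible = 4, resistant = 1,
#'                                     producer = 1),
#'                          carbon_per_box = 4e-7, max_time = 30)
#' res <- run_batch(cfg)
#' glance(res)
run_batch <- function(config, registry = NULL) {
  state <- init_world(config, registry)
  run_engine(state, diffuse = TRUE)
}

#' Run the well-mixed (liquid) control simulation
#'
#' A single-box batch culture holding the same totals as the spatial run:
#' carbon `nx * ny * carbon_per_box`, all founder inocula pooled into the one
#' box, and a signal reference volume equal to the whole environment. There
#' is no diffusion and no placement randomness, so repeated runs are
#' bit-identical.
#'
#' @inheritParams run_batch
#' @return a `toxsim_result`.
#' @export
run_well_mixed <- function(config) {
  lat <- config$lattice
  n_boxes <- lat$nx * lat$ny
  cfg <- config
  cfg$lattice <- lattice_config(nx = 1, ny = 1, dx = lat$dx,
                                metabolite_diff = 0, toxin_diff = 0,
                                biomass_diff = 0)
  cfg$carbon_per_box <- config$carbon_per_box * n_boxes
  total <- sum(config$counts)
  registry <- tibble::tibble(
    colony = seq_len(total),
    role = rep(names(config$counts), config$counts),
    row = 0L, col = 0L
  )
  state <- init_world(cfg, registry, vol_box = n_boxes * lat$dx^3)
  run_engine(state, diffuse = FALSE)
}

run_engine <- function(state, diffuse = TRUE) {
  config <- state$config
  lat <- config$lattice
  dt <- config$dt
  dx <- lat$dx
  nc <- nrow(state$registry)
  nbox <- lat$nx * lat$ny

  lam_c <- lat$metabolite_diff * 3600 * dt / dx^2
  lam_t <- lat$toxin_diff * 3600 * dt / dx^2
  lam_b <- lat$biomass_diff * 3600 * dt / dx^2
  ns_c <- n_substeps(lam_c); ns_t <- n_substeps(lam_t); ns_b <- n_substeps(lam_b)
  do_diffuse <- diffuse && nbox > 1

  carbon <- state$carbon + 0
  toxin <- state$toxin + 0
  bio <- state$bio + 0
  p <- colony_params(config, state$registry)
  conc_signal <- config$signal_on == "concentration"
  K <- config$conc_where_effect_ends

  max_steps <- as.integer(ceiling(config$hard_cap / dt))
  colony_tot <- matrix(NA_real_, max_steps + 1L, nc)
  times <- numeric(max_steps + 1L)
  tox_mean <- tox_sd <- carb_tot <- numeric(max_steps + 1L)

  record <- function(i) {
    colony_tot[i, ] <<- colSums(matrix(bio, nbox, nc))
    times[i] <<- (i - 1) * dt
    tox_mean[i] <<- mean(toxin)
    tox_sd[i] <<- sqrt(mean((toxin - tox_mean[i])^2)) # population sd
    carb_tot[i] <<- sum(carbon)
  }
  record(1L)

  snapshots <- list()
  snap_times <- numeric(0)
  take_snapshot <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<- list(toxin = toxin + 0,
                                                 carbon = carbon + 0)
    snap_times[length(snap_times) + 1L] <<- t
  }
  take_snapshot(0)

  converged <- FALSE
  step <- 0L
  total_prev <- sum(colony_tot[1L, ])
  while (step < max_steps) {
    step <- step + 1L
    cpp_growth_inplace(carbon, toxin, bio, p$v_max, p$cost, p$yield,
                       p$tau, p$delta, p$susceptible, K, state$vol_box,
                       conc_signal, dt)
    if (do_diffuse) {
      cpp_diffuse_inplace(carbon, lam_c, ns_c)
      cpp_diffuse_inplace(toxin, lam_t, ns_t)
      if (lam_b > 0) cpp_diffuse_layers(bio, lat$nx, lat$ny, nc, lam_b, ns_b)
    }
    record(step + 1L)
    if (step %% config$record_every == 0L) take_snapshot(step * dt)
    total_now <- sum(colony_tot[step + 1L, ])
    rel <- abs(total_now - total_prev) / max(total_prev, .Machine$double.xmin)
    total_prev <- total_now
    if (rel < config$stationary_tol) { converged <- TRUE; break }
  }
  keep <- seq_len(step + 1L)
  if (snap_times[length(snap_times)] < step * dt) take_snapshot(step * dt)

  state$carbon <- carbon; state$toxin <- toxin; state$bio <- bio
  state$time <- step * dt

  structure(list(
    time = times[keep],
    colony_biomass = colony_tot[keep, , drop = FALSE],
    registry = state$registry,
    toxin_stats = tibble::tibble(
      time = times[keep], mean = tox_mean[keep], sd = tox_sd[keep],
      cv = ifelse(tox_mean[keep] > 0, tox_sd[keep] / tox_mean[keep], NA_real_)
    ),
    carbon_total = carb_tot[keep],
    snapshots = snapshots,
    snapshot_times = snap_times,
    final = state,
    config = config,
    converged = converged
  ), class = "toxsim_result")
}

#' @export
print.toxsim_result <- function(x, ...) {
  fin <- final_role_biomass(x)
  cat(sprintf("<toxsim_result> %d colonies, t = %.1f hr%s\n",
              nrow(x$registry), max(x$time),
              if (x$converged) " (stationary)" else " (NOT converged)"))
  cat("final biomass by role (gDW):\n")
  print(fin)
  invisible(x)
}

final_role_biomass <- function(result) {
  fin <- result$colony_biomass[nrow(result$colony_biomass), ]
  vapply(split(fin, result$registry$role), sum, numeric(1))
}

#' Tidy a simulation result into a long trajectory tibble
#'
#' @param x a `toxsim_result` from [run_batch()] or [run_well_mixed()].
#' @param ... unused.
#' @return a tibble with columns `time`, `colony`, `role`, `biomass`.
#' @exportS3Method generics::tidy
tidy.toxsim_result <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, times = nrow(x$registry)),
    colony = rep(x$registry$colony, each = length(x$time)),
    role = rep(x$registry$role, each = length(x$time)),
    biomass = as.vector(x$colony_biomass)
  )
}

#' One-row summary of a simulation run
#'
#' Duration, convergence flag, final biomass per role, remaining carbon and
#' total toxin.
#'
#' @inheritParams tidy.toxsim_result
#' @exportS3Method generics::glance
glance.toxsim_result <- function(x, ...) {
  fin <- final_role_biomass(x)
  pick <- function(r) if (r %in% names(fin)) fin[[r]] else 0
  tibble::tibble(
    time_final = max(x$time),
    converged = x$converged,
    biomass_producer = pick("producer"),
    biomass_susceptible = pick("susceptible"),
    biomass_resistant = pick("resistant"),
    carbon_remaining = sum(x$final$carbon),
    toxin_total = sum(x$final$toxin)
  )
}
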