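#' Carbon-limited effective uptake bound
#'
#' Caps the maximum carbon uptake flux so that one forward-Euler step of
#' length `dt` cannot drive the local carbon pool negative:
#' `min(v_max, carbon_available / (biomass * dt))`.
#'
#' @param v_max intrinsic maximum uptake rate (mmol gDW^-1 hr^-1).
#' @param carbon_available local carbon (mmol), non-negative.
#' @param biomass local biomass (gDW), positive.
#' @param dt step length (hr), positive.
#' @return effective uptake bound (mmol gDW^-1 hr^-1).
#' @export
#' @examples
#' effective_uptake_bound(1, 1e-12, 2e-10, 0.1) # 0.05
effective_uptake_bound <- function(v_max, carbon_available, biomass, dt) {
  if (any(biomass <= 0)) abort("biomass must be positive")
  if (any(dt <= 0)) abort("dt must be positive")
  if (any(v_max < 0) || any(carbon_available < 0)) {
    abort("v_max and carbon_available must be non-negative")
  }
  pmin(v_max, carbon_available / (biomass * dt))
}

#' Solve the per-step growth linear program
#'
#' Maximizes flux through the biomass reaction subject to steady-state
#' stoichiometry (`S v = 0`), non-negative fluxes, the carbon-exchange upper
#' bound `uptake_bound`, and a signal-modified upper bound `signal_bound` on
#' the biomass reaction itself. For the generic strain models the optimum has
#' the closed form
#' `mu = min(uptake_bound * Y / (1 + cost), signal_bound)`,
#' which the default fast path uses; `method = "lp"` solves the LP on the
#' full stoichiometric matrix (any reaction count) and agrees with the
#' closed form for these models.
#'
#' @param model a `stoich_model` from [build_strain()].
#' @param uptake_bound upper bound on carbon exchange flux
#'   (mmol gDW^-1 hr^-1); see [effective_uptake_bound()].
#' @param signal_bound upper bound on biomass flux (hr^-1), e.g. from
#'   [bounded_linear()]; `Inf` for no signal.
#' @param method `"closed_form"` (default) or `"lp"` (generic simplex).
#' @return a one-row tibble: `growth_flux` (hr^-1), `carbon_uptake_flux`,
#'   `toxin_secretion_flux` (mmol gDW^-1 hr^-1) and `status`
#'   (`"optimal"` or `"zero_growth"`).
#' @export
#' @examples
#' m <- build_strain("producer", growth_rate = 1)
#' solve_growth(m, uptake_bound = 1)            # mu = 1/1.01
#' solve_growth(m, uptake_bound = 1, method = "lp")
solve_growth <- function(model, uptake_bound, signal_bound = Inf,
                         method = c("closed_form", "lp")) {
  method <- match.arg(method)
  if (!inherits(model, "stoich_model")) abort("`model` must be a stoich_model")
  if (uptake_bound < 0 || signal_bound < 0) abort("bounds must be non-negative")

  if (method == "closed_form") {
    mu <- min(uptake_bound * model$yield / (1 + model$cost), signal_bound)
  } else {
    mu <- solve_growth_lp(model, uptake_bound, signal_bound)
  }
  flux_solution(model, mu)
}

flux_solution <- function(model, mu) {
  tibble::tibble(
    growth_flux = mu,
    carbon_uptake_flux = (1 + model$cost) / model$yield * mu,
    toxin_secretion_flux = model$toxin_coefficient * (1 + model$cost) * mu,
    status = if (mu > 0) "optimal" else "zero_growth"
  )
}

# Generic LP path via the two-phase simplex in `boot`. Variables are the
# reaction fluxes (all irreversible, >= 0); equality rows are S v = 0;
# finite upper bounds become <= rows. An infeasible/unbounded outcome is
# treated as zero growth (it cannot occur for valid strain models).
solve_growth_lp <- function(model, uptake_bound, signal_bound) {
  S <- model$S
  nrxn <- ncol(S)
  ub <- model$reactions$ub
  names(ub) <- model$reactions$id
  ub[["carbon_exchange"]] <- uptake_bound
  if (is.finite(signal_bound)) {
    ub[[model$objective]] <- min(ub[[model$objective]], signal_bound)
  }
  # cap structurally unbounded fluxes: no flux can exceed what the carbon
  # uptake bound supports through the stoichiometry
  big <- max(1, uptake_bound) * max(1, max(abs(S))) * nrxn * 10
  ub[!is.finite(ub)] <- big

  # eliminate fluxes pinned to zero (structural reactions) and any
  # metabolite row left without entries; redundant equalities break the
  # simplex phase-1 step
  free <- ub > 0
  S <- S[, free, drop = FALSE]
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  ub <- ub[free]
  if (!model$objective %in% colnames(S)) return(0)

  obj <- as.numeric(colnames(S) == model$objective)
  out <- tryCatch(
    boot::simplex(a = obj, A1 = diag(ncol(S)), b1 = unname(ub),
                  A3 = unclass(S), b3 = rep(0, nrow(S)), maxi = TRUE),
    error = function(e) NULL
  )
  if (is.null(out) || out$solved != 1) return(0)
  max(0, out$value)
}
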