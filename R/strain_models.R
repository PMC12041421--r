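#' Describe a strain's role and rate/cost parameters
#'
#' A strain specification collects everything needed to build one of the three
#' generic competitors: a toxin **producer** (pays a fractional growth cost
#' `production_cost` and secretes `toxin_coefficient` mmol of toxin per gDW of
#' new biomass), a **susceptible** competitor (its growth bound falls with the
#' local extracellular toxin level via its signal response), and a
#' **resistant** cheater (neither produces nor responds, optionally paying a
#' `resistance_cost`).
#'
#' The maximum carbon uptake rate `v_max_uptake` sets the realized maximum
#' growth rate: with yield `Y` (gDW biomass per mmol carbon) and fractional
#' cost `c`, the fastest possible growth is `v_max * Y / (1 + c)`. When
#' `v_max_uptake` is `NULL` it is derived from `growth_rate` as
#' `growth_rate / Y` — the uptake bound every strain shares — so a costly
#' strain realizes at most `growth_rate / (1 + c)`: the cost is a true
#' growth-rate cost (a 1% production cost means producers grow 1% slower
#' and reach 99% of the biomass on the same carbon).
#'
#' @param role one of `"producer"`, `"susceptible"`, `"resistant"`.
#' @param name identifier; defaults to the role.
#' @param growth_rate target maximal growth rate (hr^-1); used to derive
#'   `v_max_uptake` when that is not given.
#' @param v_max_uptake maximum carbon uptake rate (mmol carbon gDW^-1 hr^-1),
#'   or `NULL` to derive from `growth_rate`.
#' @param yield gDW biomass produced per mmol carbon (default 1).
#' @param production_cost dimensionless fraction >= 0; carbon overhead of
#'   toxin production (producers only, default 0.01 i.e. 1%).
#' @param resistance_cost dimensionless fraction >= 0; carbon overhead of
#'   resistance (resistant strains only, default 0).
#' @param toxin_coefficient mmol toxin produced per gDW of new producer
#'   biomass (default 15; forced to 0 for non-producers).
#' @param death_rate first-order death rate (hr^-1, default 0).
#' @param signal_responses list of [signal_response()] objects; defaults to
#'   the bounded-linear toxin response for susceptible strains and empty
#'   otherwise.
#' @param conc_where_effect_ends toxin level at which the default susceptible
#'   response reaches zero growth (default 15, in the units used by the
#'   simulation's signal; see [simulation_config()]).
#' @return an object of class `strain_spec`.
#' @seealso [build_strain()], [signal_response()]
#' @export
#' @examples
#' strain_spec("producer", growth_rate = 1)
#' strain_spec("susceptible", growth_rate = 0.5)
strain_spec <- function(role = c("producer", "susceptible", "resistant"),
                        name = NULL,
                        growth_rate = 1,
                        v_max_uptake = NULL,
                        yield = 1,
                        production_cost = 0.01,
                        resistance_cost = 0,
                        toxin_coefficient = 15,
                        death_rate = 0,
                        signal_responses = NULL,
                        conc_where_effect_ends = 15) {
  role <- match.arg(role)
  name <- name %||% role
  if (role != "producer") {
    toxin_coefficient <- 0
    production_cost <- 0
  }
  if (role != "resistant") resistance_cost <- 0
  if (is.null(signal_responses)) {
    signal_responses <- if (role == "susceptible") {
      list(signal_response(K = conc_where_effect_ends))
    } else {
      list()
    }
  }
  spec <- structure(
    list(
      name = name, role = role,
      growth_rate = growth_rate,
      v_max_uptake = v_max_uptake %||% (growth_rate / yield),
      yield = yield,
      production_cost = production_cost,
      resistance_cost = resistance_cost,
      toxin_coefficient = toxin_coefficient,
      death_rate = death_rate,
      signal_responses = signal_responses
    ),
    class = "strain_spec"
  )
  validate_strain_spec(spec)
  spec
}

validate_strain_spec <- function(spec) {
  num <- c("v_max_uptake", "yield", "production_cost", "resistance_cost",
           "toxin_coefficient", "death_rate")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("strain_spec field `%s` must be a single non-negative number", f))
    }
  }
  if (!spec$role %in% c("producer", "susceptible", "resistant")) {
    abort("invalid strain role")
  }
  if (spec$role == "resistant" &&
      (spec$toxin_coefficient != 0 || length(spec$signal_responses) > 0)) {
    abort("resistant strains neither produce toxin nor respond to it")
  }
  if (spec$role == "susceptible" && spec$toxin_coefficient != 0) {
    abort("susceptible strains do not produce toxin")
  }
  invisible(spec)
}

#' Map an extracellular signal level onto a modified growth bound
#'
#' Defines how a compound in the environment alters a strain: the built-in
#' form is `bounded_linear`, in which a growth upper bound falls linearly
#' with the signal level and is clamped at zero beyond `K` (so growth can
#' never become negative because of toxin). Other functional forms can be
#' supplied as `form = "custom"` with `fn`, a function `(level, base_bound)`.
#'
#' @param signal metabolite identifier (default `"toxin_e"`).
#' @param target what the signal modifies: the biomass-flux upper bound, the
#'   death rate, or a named reaction bound.
#' @param form `"bounded_linear"` or `"custom"`.
#' @param K signal level at which the bounded-linear effect reaches zero
#'   growth; must be positive.
#' @param reaction reaction id, required when `target = "reaction_bound"`.
#' @param fn custom response function, required when `form = "custom"`.
#' @return an object of class `signal_response`.
#' @export
signal_response <- function(signal = "toxin_e",
                            target = c("biomass_upper_bound", "death_rate",
                                       "reaction_bound"),
                            form = c("bounded_linear", "custom"),
                            K = 15,
                            reaction = NULL,
                            fn = NULL) {
  target <- match.arg(target)
  form <- match.arg(form)
  if (form == "bounded_linear" && (!is.numeric(K) || length(K) != 1L || K <= 0)) {
    abort("bounded_linear responses need K > 0")
  }
  if (target == "reaction_bound" && is.null(reaction)) {
    abort("target = \"reaction_bound\" needs a reaction id")
  }
  if (form == "custom" && !is.function(fn)) {
    abort("form = \"custom\" needs a response function `fn`")
  }
  structure(list(signal = signal, target = target, form = form, K = K,
                 reaction = reaction, fn = fn),
            class = "signal_response")
}

#' Bounded-linear signal response
#'
#' Returns `base_bound * max(0, 1 - conc / K)`: the unmodified bound at zero
#' signal, a linear decline, and exactly zero at and beyond `conc = K`.
#'
#' @param conc signal level(s), non-negative.
#' @param K level at which the bound reaches zero; must be positive.
#' @param base_bound the unmodified upper bound (hr^-1).
#' @return modified bound, same length as `conc`, never negative.
#' @export
#' @examples
#' bounded_linear(c(0, 7.5, 15, 20), K = 15, base_bound = 1)
bounded_linear <- function(conc, K, base_bound = 1) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0) {
    abort("K must be a single positive number")
  }
  if (any(conc < 0, na.rm = TRUE)) abort("conc must be non-negative")
  if (any(base_bound < 0, na.rm = TRUE)) abort("base_bound must be non-negative")
  base_bound * pmax(0, 1 - conc / K)
}

#' Build the stoichiometric model for a strain
#'
#' Constructs the strain's small reaction network. All three roles share the
#' three core reactions: carbon exchange (environment to cell surface),
#' carbon transport (into the cell), and biomass generation. Producers add
#' toxin transport and toxin exchange, so every mmol of toxin made by the
#' biomass reaction ends up extracellular; susceptibles add a structural
#' (zero-flux) toxin uptake reaction and carry the signal-response
#' annotation. Resistant cheaters have no toxin reactions at all.
#'
#' The biomass reaction of a strain with fractional cost `c` (production cost
#' for producers, resistance cost for resistant cheaters) and yield `Y`
#' consumes `(1 + c) / Y` mmol intracellular carbon per unit biomass flux;
#' a producer additionally makes `tau * (1 + c)` mmol toxin per unit biomass
#' flux, where `tau` is the toxin coefficient.
#'
#' @param spec a [strain_spec()], or a role name (a default spec is built).
#' @param ... passed to [strain_spec()] when `spec` is a role name.
#' @return an object of class `stoich_model`: metabolite ids, a reaction
#'   table (tibble with id, bounds), the stoichiometric matrix `S`
#'   (metabolites x reactions), and the objective reaction id.
#' @export
#' @examples
#' m <- build_strain("producer", growth_rate = 1)
#' m$S[, "biomass"]
build_strain <- function(spec, ...) {
  if (is.character(spec)) spec <- strain_spec(spec, ...)
  if (!inherits(spec, "strain_spec")) abort("`spec` must be a strain_spec")
  validate_strain_spec(spec)

  role <- spec$role
  cost <- switch(role,
                 producer = spec$production_cost,
                 resistant = spec$resistance_cost,
                 susceptible = 0)
  Y <- spec$yield
  tau <- spec$toxin_coefficient

  mets <- c("carbon_e", "carbon_c")
  rxn <- list(
    carbon_exchange  = c(carbon_e = 1),
    carbon_transport = c(carbon_e = -1, carbon_c = 1),
    biomass          = c(carbon_c = -(1 + cost) / Y)
  )
  if (role == "producer") {
    mets <- c(mets, "toxin_c", "toxin_e")
    rxn$biomass <- c(rxn$biomass, toxin_c = tau * (1 + cost))
    rxn$toxin_transport <- c(toxin_c = -1, toxin_e = 1)
    rxn$toxin_exchange  <- c(toxin_e = -1)
  } else if (role == "susceptible") {
    mets <- c(mets, "toxin_e", "toxin_c")
    # structural only: bounds pin its flux to zero (toxin is never consumed)
    rxn$toxin_uptake <- c(toxin_e = -1, toxin_c = 1)
  }

  S <- matrix(0, nrow = length(mets), ncol = length(rxn),
              dimnames = list(mets, names(rxn)))
  for (r in names(rxn)) S[names(rxn[[r]]), r] <- rxn[[r]]

  ub <- setNames(rep(Inf, length(rxn)), names(rxn))
  lb <- setNames(rep(0, length(rxn)), names(rxn))
  ub[["carbon_exchange"]] <- spec$v_max_uptake
  if (role == "susceptible") ub[["toxin_uptake"]] <- 0

  structure(
    list(
      name = spec$name, role = role,
      metabolites = mets,
      reactions = tibble::tibble(id = names(rxn), lb = unname(lb), ub = unname(ub)),
      S = S,
      objective = "biomass",
      cost = cost, yield = Y, toxin_coefficient = tau,
      spec = spec
    ),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s (%s): %d metabolites, %d reactions, objective `%s`\n",
              x$name, x$role, length(x$metabolites), ncol(x$S), x$objective))
  invisible(x)
}

#' Save or load a stoichiometric model as JSON
#'
#' Plain-JSON serialization of a [build_strain()] model (ids, coefficients,
#' bounds, objective and the originating strain parameters). `load_model()`
#' validates the document and reproduces a field-equal model.
#'
#' @param model a `stoich_model`.
#' @param path file path.
#' @return `load_model()` returns a `stoich_model`; `save_model()` its path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "stoich_model")) abort("`model` must be a stoich_model")
  doc <- list(
    name = model$name, role = model$role,
    metabolites = model$metabolites,
    reactions = lapply(seq_len(ncol(model$S)), function(j) {
      v <- model$S[, j]
      list(id = colnames(model$S)[j],
           stoichiometry = as.list(v[v != 0]),
           lb = model$reactions$lb[j], ub = model$reactions$ub[j])
    }),
    objective = model$objective,
    parameters = model$spec[c("growth_rate", "v_max_uptake", "yield",
                              "production_cost", "resistance_cost",
                              "toxin_coefficient", "death_rate")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort(paste("malformed model file:", conditionMessage(e))))
  need <- c("role", "metabolites", "reactions", "objective", "parameters")
  if (!all(need %in% names(doc))) {
    abort(sprintf("malformed model file: missing %s",
                  paste(setdiff(need, names(doc)), collapse = ", ")))
  }
  p <- doc$parameters
  spec <- strain_spec(doc$role, name = doc$name,
                      growth_rate = p$growth_rate,
                      v_max_uptake = p$v_max_uptake,
                      yield = p$yield,
                      production_cost = p$production_cost,
                      resistance_cost = p$resistance_cost,
                      toxin_coefficient = p$toxin_coefficient,
                      death_rate = p$death_rate)
  model <- build_strain(spec)
  # cross-check the stored stoichiometry against the rebuilt model
  ids <- vapply(doc$reactions, function(r) r$id, character(1))
  if (!setequal(ids, colnames(model$S))) abort("malformed model file: reaction ids do not match role")
  for (r in doc$reactions) {
    sto <- unlist(r$stoichiometry)
    if (is.null(names(sto)) || !all(names(sto) %in% rownames(model$S))) {
      abort("malformed model file: unnamed or unknown stoichiometry entries")
    }
    if (max(abs(model$S[names(sto), r$id] - sto)) > 1e-12) {
      abort("malformed model file: stoichiometry inconsistent with stored parameters")
    }
  }
  model
}
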