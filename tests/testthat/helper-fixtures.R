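# Small lattice configuration used by fast engine tests: 12 x 12 boxes,
# 6 colonies, default physics otherwise.
tiny_config <- function(...) {
  simulation_config(
    lattice = lattice_config(nx = 12, ny = 12),
    counts = c(susceptible = 4, resistant = 1, producer = 1),
    max_time = 40,
    ...
  )
}

# Minimal hand-built result object for metric unit tests: final biomasses and
# founder coordinates are chosen directly.
fake_result <- function(biomass, roles, rows = NULL, cols = NULL,
                        counts = NULL, dx = 0.01,
                        toxin_stats = NULL) {
  n <- length(biomass)
  counts <- counts %||% table(factor(roles, c("susceptible", "resistant",
                                              "producer")))
  structure(list(
    time = c(0, 1),
    colony_biomass = rbind(rep(1e-10, n), biomass),
    registry = tibble::tibble(colony = seq_len(n), role = roles,
                              row = rows %||% rep(0L, n),
                              col = cols %||% seq_len(n) - 1L),
    toxin_stats = toxin_stats %||%
      tibble::tibble(time = c(0, 1), mean = c(0, 0), sd = c(0, 0),
                     cv = c(NA_real_, NA_real_)),
    config = list(counts = setNames(as.integer(counts), names(counts)),
                  lattice = lattice_config(dx = dx)),
    converged = TRUE
  ), class = "toxsim_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent iteratively-reweighted least-squares oracle for one-predictor
# GLMs, written directly from the IRLS recursion (no glm machinery).
irls_fit <- function(x, y, family = c("logistic", "poisson"), iters = 100) {
  family <- match.arg(family)
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(iters)) {
    eta <- drop(X %*% b)
    mu <- if (family == "logistic") plogis(eta) else exp(eta)
    w <- if (family == "logistic") mu * (1 - mu) else mu
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(b_new - b)) < 1e-12) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  b
}
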