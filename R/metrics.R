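#' Producer relative-fitness summary for one run
#'
#' Computes the two relative-fitness readouts from the final per-strain
#' biomass totals: the producer fraction of the whole community
#' (`producer / (producer + susceptible + resistant)`), compared against the
#' producer's initial frequency (invasion), and the producer fraction of the
#' non-susceptible community (`producer / (producer + resistant)`), compared
#' against 0.5, the 1:1 seeding ratio of producers and cheaters. Both
#' thresholds are strict inequalities.
#'
#' @param result a `toxsim_result`.
#' @param initial_frequency producer's initial biomass frequency; defaults to
#'   its share of founder colonies in the run's configuration.
#' @return a one-row tibble: `producer_fraction_total`,
#'   `producer_fraction_vs_resistant`, `invaded`, `beats_resistant`,
#'   `initial_producer_frequency`.
#' @export
fitness_summary <- function(result, initial_frequency = NULL) {
  fin <- final_role_biomass(result)
  pick <- function(r) if (r %in% names(fin)) fin[[r]] else 0
  P <- pick("producer"); S <- pick("susceptible"); R <- pick("resistant")
  total <- P + S + R
  if (total <= 0) abort("all-zero community: no surviving biomass")
  initial_frequency <- initial_frequency %||% {
    counts <- result$config$counts
    unname(counts["producer"] / sum(counts))
  }
  frac_total <- P / total
  frac_vs_res <- if (P + R > 0) P / (P + R) else 0
  tibble::tibble(
    producer_fraction_total = frac_total,
    producer_fraction_vs_resistant = frac_vs_res,
    invaded = frac_total > initial_frequency,
    beats_resistant = frac_vs_res > 0.5,
    initial_producer_frequency = initial_frequency
  )
}

#' Maximum spatial coefficient of variation of toxin
#'
#' For every recorded macro step up to the cessation of growth, the CV of
#' the toxin field over all lattice boxes (population standard deviation,
#' `n` denominator, divided by the mean); steps with zero mean toxin are
#' skipped. Returns the maximum over steps — the run's peak spatial
#' heterogeneity in toxin exposure. If no step has positive toxin the value
#' is 0, with a warning.
#'
#' @param result a `toxsim_result`.
#' @return a single non-negative number.
#' @export
toxin_cv_max <- function(result) {
  cv <- result$toxin_stats$cv
  cv <- cv[!is.na(cv)]
  if (length(cv) == 0) {
    warn("no step with positive toxin; returning CV 0")
    return(0)
  }
  max(cv)
}

#' Proximity effect: biomass versus distance from producers
#'
#' For each susceptible founder colony, computes the mean Euclidean distance
#' (cm) to all producer founder colonies and regresses the colony's final
#' (scaled) biomass on it by ordinary least squares. A positive slope means
#' susceptibles farther from producers grew larger — localized interference
#' competition; a slope near zero means location did not matter.
#'
#' @param result a `toxsim_result` with at least two susceptible and one
#'   producer founder colony.
#' @param scale how to scale final colony biomass before the regression:
#'   `"max"` (default; divide by the largest susceptible colony biomass in
#'   the run, giving a scale-free slope), `"mean"`, or `"raw"` (gDW).
#' @return the OLS slope (scaled biomass per cm).
#' @export
proximity_effect <- function(result, scale = c("max", "mean", "raw")) {
  scale <- match.arg(scale)
  reg <- result$registry
  sus <- which(reg$role == "susceptible")
  pro <- which(reg$role == "producer")
  if (length(sus) < 2) abort("need at least two susceptible colonies")
  if (length(pro) < 1) abort("need at least one producer colony")
  dx <- result$config$lattice$dx
  dist_cm <- vapply(sus, function(i) {
    mean(sqrt((reg$row[i] - reg$row[pro])^2 +
              (reg$col[i] - reg$col[pro])^2)) * dx
  }, numeric(1))
  if (sd(dist_cm) == 0) abort("zero variance in producer distances")
  fin <- result$colony_biomass[nrow(result$colony_biomass), sus]
  denom <- switch(scale, max = max(fin), mean = mean(fin), raw = 1)
  if (denom == 0) denom <- 1
  y <- fin / denom
  unname(coef(lm(y ~ dist_cm))[2])
}

#' Classify a relative-fitness ratio against a threshold
#'
#' @param ratio non-negative fitness ratio(s).
#' @param threshold comparison threshold (e.g. the initial producer
#'   frequency, or 0.5 for the producer-vs-resistant comparison).
#' @return factor with levels `low`, `intermediate`, `high`: strictly above
#'   the threshold is `high`, exactly at it `intermediate`, below it `low`.
#' @export
#' @examples
#' classify_fitness(c(0.05, 0.5, 0.55), threshold = 0.5)
classify_fitness <- function(ratio, threshold) {
  if (any(ratio < 0, na.rm = TRUE)) abort("ratio must be non-negative")
  out <- ifelse(ratio > threshold, "high",
                ifelse(ratio == threshold, "intermediate", "low"))
  factor(out, levels = c("low", "intermediate", "high"))
}
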