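#' Maximal growth rate from doubling time
#'
#' `ln(2) / doubling_time`, with doubling time in hours and the rate in
#' hr^-1.
#'
#' @param d_hr doubling time(s) in hours, positive.
#' @return growth rate(s) in hr^-1.
#' @export
#' @examples
#' growth_rate_from_doubling(c(1, 2))
growth_rate_from_doubling <- function(d_hr) {
  if (any(is.na(d_hr)) || any(d_hr <= 0)) abort("doubling times must be positive")
  log(2) / d_hr
}

#' Generate a synthetic genome feature table
#'
#' Builds a reproducible per-genome table with known ground truth for
#' exercising the regression machinery: lognormal doubling times, derived
#' growth rates, binary presence of each gene-cluster class drawn from a
#' logistic model `P(present) = plogis(intercept + beta * growth_rate)`,
#' multiplicative 95% CI bounds around each doubling time, and optional
#' Poisson count columns with log-linear rate effects.
#'
#' @param n number of genomes.
#' @param betas named numeric vector: per-class logistic slope on growth
#'   rate (hr).
#' @param intercepts named or scalar logistic intercept(s) (default -1).
#' @param meanlog,sdlog lognormal parameters of the doubling-time
#'   distribution (defaults `log(1.5)` and 0.6: median 1.5 hr, most mass
#'   0.5-5 hr, a realistic copiotroph range).
#' @param ci_halfwidth multiplicative half-width of the 95% CI around each
#'   doubling time: bounds are `d * exp(-+ ci_halfwidth)` (default 0.2).
#' @param count_effects optional named numeric vector of Poisson log-slope
#'   effects; adds one count column per name.
#' @param count_intercepts log-scale intercept(s) for the count columns
#'   (default 0).
#' @param seed integer seed (private RNG stream).
#' @return a tibble with columns `genome_id`, `doubling_time_hr`,
#'   `ci_lower_hr`, `ci_upper_hr`, `growth_rate_hr`, one 0/1 column per
#'   class in `betas`, and one integer column per name in `count_effects`.
#' @export
#' @examples
#' synth_genome_table(5, betas = c(bgcA = 2), seed = 1)
synth_genome_table <- function(n, betas, intercepts = -1,
                               meanlog = log(1.5), sdlog = 0.6,
                               ci_halfwidth = 0.2,
                               count_effects = NULL, count_intercepts = 0,
                               seed = 1) {
  if (n < 1) abort("n must be >= 1")
  if (is.null(names(betas)) || any(names(betas) == "")) {
    abort("betas must be a named vector of class effects")
  }
  if (ci_halfwidth < 0) abort("ci_halfwidth must be non-negative")
  intercepts <- rep_len(intercepts, length(betas))
  with_private_seed(seed, {
    d <- rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    rate <- growth_rate_from_doubling(d)
    tab <- tibble::tibble(
      genome_id = sprintf("g%05d", seq_len(n)),
      doubling_time_hr = d,
      ci_lower_hr = d * exp(-ci_halfwidth),
      ci_upper_hr = d * exp(ci_halfwidth),
      growth_rate_hr = rate
    )
    for (i in seq_along(betas)) {
      tab[[names(betas)[i]]] <-
        rbinom(n, 1, plogis(intercepts[i] + betas[i] * rate))
    }
    if (!is.null(count_effects)) {
      ci <- rep_len(count_intercepts, length(count_effects))
      for (i in seq_along(count_effects)) {
        tab[[names(count_effects)[i]]] <-
          rpois(n, exp(ci[i] + count_effects[i] * rate))
      }
    }
    tab
  })
}

check_genome_table <- function(table, need_ci = FALSE) {
  if (!"growth_rate_hr" %in% names(table)) {
    if (!"doubling_time_hr" %in% names(table)) {
      abort("table needs a growth_rate_hr or doubling_time_hr column")
    }
    table$growth_rate_hr <- growth_rate_from_doubling(table$doubling_time_hr)
  }
  if (need_ci) {
    if (!all(c("ci_lower_hr", "ci_upper_hr") %in% names(table))) {
      abort("resampling needs ci_lower_hr and ci_upper_hr columns")
    }
    bad <- is.na(table$ci_lower_hr) | is.na(table$ci_upper_hr) |
      table$ci_lower_hr <= 0 |
      table$ci_lower_hr > table$doubling_time_hr |
      table$ci_upper_hr < table$doubling_time_hr
    if (any(bad)) {
      warn(sprintf("dropping %d genome(s) with missing or inconsistent CIs",
                   sum(bad)))
      table <- table[!bad, , drop = FALSE]
    }
  }
  table
}

#' Logistic regression of gene-cluster presence on growth rate
#'
#' Fits `presence ~ growth_rate_hr` by maximum-likelihood logistic
#' regression (binomial family, logit link) for one presence/absence class
#' column. A positive `beta` means the class is more probable in
#' faster-growing genomes. The 95% CI for `beta` uses profile likelihood,
#' falling back to a Wald interval (flagged in `ci_method`) if profiling
#' fails. Constant columns and complete separation are flagged degenerate
#' and carry `NA` statistics.
#'
#' @param table a genome feature table (see [synth_genome_table()] for the
#'   column dictionary).
#' @param class name of the 0/1 presence column.
#' @param conf_level CI level (default 0.95).
#' @return a one-row tibble: `class`, `beta`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`, `degenerate`, `ci_method`.
#' @export
fit_bgc_logistic <- function(table, class, conf_level = 0.95) {
  table <- check_genome_table(table)
  y <- table[[class]]
  if (is.null(y)) abort(sprintf("no column `%s`", class))
  if (!all(y %in% c(0, 1))) abort("presence columns must be 0/1")
  degenerate_row <- function() {
    tibble::tibble(class = class, beta = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, p_value = NA_real_,
                   n = length(y), degenerate = TRUE, ci_method = NA_character_)
  }
  if (length(unique(y)) < 2) return(degenerate_row())
  fit <- suppressWarnings(glm(y ~ growth_rate_hr, data = table,
                              family = binomial(link = "logit")))
  beta <- unname(coef(fit)[2])
  # complete (or quasi-) separation: fitted probabilities collapse to 0/1
  # and the slope estimate diverges
  if (!fit$converged || abs(beta) > 50) return(degenerate_row())
  sm <- summary(fit)$coefficients
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, parm = "growth_rate_hr", level = conf_level)
    )),
    error = function(e) NULL
  )
  ci_method <- "profile"
  if (is.null(ci) || any(!is.finite(ci))) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- beta + c(-1, 1) * z * sm["growth_rate_hr", "Std. Error"]
    ci_method <- "wald"
  }
  tibble::tibble(
    class = class, beta = beta,
    ci_lower = ci[1], ci_upper = ci[2],
    p_value = sm["growth_rate_hr", "Pr(>|z|)"],
    n = length(y), degenerate = FALSE, ci_method = ci_method
  )
}

#' Poisson regression of a toxin-gene count on growth rate
#'
#' Fits `count ~ growth_rate_hr` with a log link (Poisson family,
#' appropriate for counts such as toxin genes, unique toxin gene types or
#' toxin islands per genome).
#'
#' @inheritParams fit_bgc_logistic
#' @param count_col name of the non-negative integer count column.
#' @return a one-row tibble in the same shape as [fit_bgc_logistic()].
#' @export
fit_count_poisson <- function(table, count_col, conf_level = 0.95) {
  table <- check_genome_table(table)
  y <- table[[count_col]]
  if (is.null(y)) abort(sprintf("no column `%s`", count_col))
  if (any(y < 0) || any(y != round(y))) {
    abort("counts must be non-negative integers")
  }
  if (all(y == 0)) {
    abort("all-zero count column")
  }
  fit <- suppressWarnings(glm(y ~ growth_rate_hr, data = table,
                              family = poisson(link = "log")))
  beta <- unname(coef(fit)[2])
  sm <- summary(fit)$coefficients
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit, parm = "growth_rate_hr", level = conf_level)
    )),
    error = function(e) NULL
  )
  ci_method <- "profile"
  if (is.null(ci) || any(!is.finite(ci))) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- beta + c(-1, 1) * z * sm["growth_rate_hr", "Std. Error"]
    ci_method <- "wald"
  }
  tibble::tibble(
    class = count_col, beta = beta, ci_lower = ci[1], ci_upper = ci[2],
    p_value = sm["growth_rate_hr", "Pr(>|z|)"],
    n = length(y), degenerate = FALSE, ci_method = ci_method
  )
}

#' Fit every presence class and adjust for multiple testing
#'
#' Runs [fit_bgc_logistic()] on each class column and applies
#' Benjamini-Hochberg adjustment across the non-degenerate fits (degenerate
#' classes are excluded from the adjustment and keep `NA`).
#'
#' @param table a genome feature table.
#' @param classes class column names; defaults to every 0/1 column other
#'   than the standard id/rate columns.
#' @return a tibble with one row per class, including `p_adjusted`.
#' @export
fit_bgc_all <- function(table, classes = NULL) {
  classes <- classes %||% presence_columns(table)
  if (length(classes) == 0) abort("no presence columns found")
  out <- dplyr::bind_rows(lapply(classes, function(cl) fit_bgc_logistic(table, cl)))
  out$p_adjusted <- NA_real_
  ok <- !out$degenerate
  out$p_adjusted[ok] <- bh_adjust(out$p_value[ok])
  out
}

presence_columns <- function(table) {
  reserved <- c("genome_id", "doubling_time_hr", "ci_lower_hr", "ci_upper_hr",
                "growth_rate_hr")
  cand <- setdiff(names(table), reserved)
  cand[vapply(cand, function(cl) {
    v <- table[[cl]]
    is.numeric(v) && all(v %in% c(0, 1))
  }, logical(1))]
}

#' Benjamini-Hochberg adjusted p values
#'
#' The standard step-up procedure: order the m raw p values increasingly,
#' scale `p_(i)` by `m / i`, and enforce monotonicity by taking running
#' minima from the largest rank down, capping at 1.
#'
#' @param p numeric vector of p values in `[0, 1]` (`NA`s allowed and
#'   returned as `NA`).
#' @return adjusted p values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv)
  scaled <- pv[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(scaled))))
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Robustness of the growth-rate correlations to doubling-time uncertainty
#'
#' Repeatedly redraws each genome's doubling time from its 95% CI, recomputes
#' growth rates, refits every class's logistic model and re-applies the
#' Benjamini-Hochberg correction. Two resampling schemes are available:
#' `uniform_ci` draws uniformly between the CI bounds, `normal_ci` draws from
#' a normal distribution centred on the point prediction with
#' `sd = sqrt(sample_size) * (upper - lower) / (2 * 1.96)`, truncated below
#' at `floor_hr`. A class is flagged robust when it is significant
#' (adjusted p < `alpha`) with the same coefficient sign as the unresampled
#' fit in at least `robust_frac` of replicates.
#'
#' Genomes with missing or inconsistent CI bounds are dropped with a
#' warning. Replicate fits use Wald p values for speed; the unresampled
#' reference fit is the full [fit_bgc_all()] result.
#'
#' @param table a genome feature table with CI columns.
#' @param scheme `"uniform_ci"` or `"normal_ci"`.
#' @param classes class columns (default: all presence columns).
#' @param n_reps number of resampling replicates (default 10000).
#' @param alpha significance level on adjusted p values (default 0.05).
#' @param seed integer seed (private RNG stream).
#' @param sample_size the `sample size` term of the printed sd formula for
#'   `normal_ci`; defaults to the number of genomes in the table.
#' @param floor_hr positive lower truncation for resampled doubling times
#'   (default 0.01 hr).
#' @param robust_frac fraction of replicates required for the robust flag
#'   (default 0.95).
#' @return a tibble, one row per class and scheme: `frac_significant`,
#'   `mean_beta`, `frac_sign_consistent`, `robust`.
#' @export
resample_robustness <- function(table,
                                scheme = c("uniform_ci", "normal_ci"),
                                classes = NULL,
                                n_reps = 10000,
                                alpha = 0.05,
                                seed = 1,
                                sample_size = NULL,
                                floor_hr = 0.01,
                                robust_frac = 0.95) {
  scheme <- match.arg(scheme)
  if (n_reps < 1) abort("n_reps must be >= 1")
  table <- check_genome_table(table, need_ci = TRUE)
  classes <- classes %||% presence_columns(table)
  if (length(classes) == 0) abort("no presence columns found")
  n <- nrow(table)
  sample_size <- sample_size %||% n

  ref <- fit_bgc_all(table, classes)
  ref_sign <- sign(ref$beta)

  d0 <- table$doubling_time_hr
  lo <- table$ci_lower_hr
  hi <- table$ci_upper_hr
  sd_norm <- sqrt(sample_size) * (hi - lo) / (2 * 1.96)
  ymat <- as.matrix(table[classes])

  sig <- matrix(FALSE, n_reps, length(classes))
  signs <- matrix(NA_real_, n_reps, length(classes))
  betas <- matrix(NA_real_, n_reps, length(classes))

  with_private_seed(seed, {
    for (r in seq_len(n_reps)) {
      d <- switch(scheme,
        uniform_ci = runif(n, lo, hi),
        normal_ci = pmax(rnorm(n, d0, sd_norm), floor_hr)
      )
      x <- cbind(1, log(2) / d)
      pv <- numeric(length(classes))
      for (j in seq_along(classes)) {
        y <- ymat[, j]
        if (length(unique(y)) < 2) { pv[j] <- NA; next }
        f <- suppressWarnings(
          glm.fit(x, y, family = binomial(link = "logit"))
        )
        b <- f$coefficients[2]
        betas[r, j] <- b
        signs[r, j] <- sign(b)
        # Wald z test on the slope
        w <- f$weights
        XtWX <- crossprod(x * sqrt(w))
        se <- tryCatch(sqrt(solve(XtWX)[2, 2]), error = function(e) NA_real_)
        pv[j] <- if (is.na(se) || !f$converged || abs(b) > 50) NA
                 else 2 * pnorm(-abs(b / se))
      }
      adj <- bh_adjust(pv)
      sig[r, ] <- !is.na(adj) & adj < alpha
    }
  })

  tibble::tibble(
    class = classes,
    scheme = scheme,
    frac_significant = colMeans(sig),
    mean_beta = colMeans(betas, na.rm = TRUE),
    frac_sign_consistent = vapply(seq_along(classes), function(j) {
      if (is.na(ref_sign[j])) return(NA_real_)
      mean(signs[, j] == ref_sign[j], na.rm = TRUE)
    }, numeric(1)),
    robust = colMeans(sig &
      sweep(signs, 2, ref_sign, FUN = "==")) >= robust_frac
  )
}
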