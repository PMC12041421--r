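test_that("growth rate is ln(2) over the doubling time", {
  expect_equal(growth_rate_from_doubling(log(2)), 1)
  expect_equal(growth_rate_from_doubling(1), 0.6931, tolerance = 1e-4)
  expect_equal(growth_rate_from_doubling(2), 0.3466, tolerance = 1e-4)
  expect_error(growth_rate_from_doubling(0), "positive")
  expect_error(growth_rate_from_doubling(-2), "positive")
})

test_that("the synthetic table generator is seeded and self-consistent", {
  t1 <- synth_genome_table(200, betas = c(a = 2, b = 0), seed = 5)
  t2 <- synth_genome_table(200, betas = c(a = 2, b = 0), seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$ci_lower_hr <= t1$doubling_time_hr &
                  t1$doubling_time_hr <= t1$ci_upper_hr))
  expect_true(all(t1$ci_lower_hr > 0))
  expect_equal(t1$growth_rate_hr, log(2) / t1$doubling_time_hr)
  expect_true(all(t1$a %in% c(0, 1)))

  # a zero-effect class occurs at rate plogis(intercept) in the large-n limit
  big <- synth_genome_table(1e5, betas = c(null = 0), intercepts = -1,
                            seed = 9)
  expect_equal(mean(big$null), plogis(-1), tolerance = 0.02)
})

test_that("logistic fits match an independent IRLS oracle on small tables", {
  set.seed(21)
  for (i in 1:5) {
    tab <- synth_genome_table(20, betas = c(x = 1.5), seed = i)
    if (length(unique(tab$x)) < 2) next
    rec <- fit_bgc_logistic(tab, "x")
    if (rec$degenerate) next
    oracle <- irls_fit(tab$growth_rate_hr, tab$x, "logistic")
    expect_equal(rec$beta, unname(oracle[2]), tolerance = 1e-6)
  }
})

test_that("logistic regression recovers known effects and flags degeneracy", {
  # null effect: slope not significant in the clear majority of seeds
  p_null <- vapply(1:20, function(s) {
    tab <- synth_genome_table(500, betas = c(k = 0), seed = s)
    fit_bgc_logistic(tab, "k")$p_value
  }, numeric(1))
  expect_gte(mean(p_null > 0.05, na.rm = TRUE), 0.9)

  # strong effect: CI covers the truth in most seeds
  covered <- vapply(1:30, function(s) {
    tab <- synth_genome_table(1000, betas = c(k = 2), intercepts = -1,
                              seed = s)
    rec <- fit_bgc_logistic(tab, "k")
    rec$ci_lower <= 2 && 2 <= rec$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)

  tab <- synth_genome_table(50, betas = c(k = 0), seed = 1)
  tab$k <- 1
  expect_true(fit_bgc_logistic(tab, "k")$degenerate)
})

test_that("estimator consistency: median beta error shrinks with n", {
  err <- function(n) {
    es <- vapply(1:15, function(s) {
      rec <- fit_bgc_logistic(
        synth_genome_table(n, betas = c(k = 1.5), seed = 100 + s), "k")
      abs(rec$beta - 1.5)
    }, numeric(1))
    median(es, na.rm = TRUE)
  }
  expect_lt(err(1000), err(100))
})

test_that("Poisson fits recover count effects and validate input", {
  covered <- vapply(1:20, function(s) {
    tab <- synth_genome_table(1000, betas = c(k = 0),
                              count_effects = c(n_tox = 0.5),
                              count_intercepts = 0.5, seed = s)
    rec <- fit_count_poisson(tab, "n_tox")
    rec$ci_lower <= 0.5 && 0.5 <= rec$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)

  tab <- synth_genome_table(300, betas = c(k = 0), seed = 2)
  tab$cnt <- 4L
  expect_lt(abs(fit_count_poisson(tab, "cnt")$beta), 0.3)
  tab$bad <- -1L
  expect_error(fit_count_poisson(tab, "bad"), "non-negative")
  tab$zero <- 0L
  expect_error(fit_count_poisson(tab, "zero"), "all-zero")

  # small-table agreement with the IRLS oracle
  small <- synth_genome_table(20, betas = c(k = 0),
                              count_effects = c(cnt = 0.4), seed = 3)
  rec <- fit_count_poisson(small, "cnt")
  oracle <- irls_fit(small$growth_rate_hr, small$cnt, "poisson")
  expect_equal(rec$beta, unname(oracle[2]), tolerance = 1e-6)
})

test_that("Benjamini-Hochberg matches the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_equal(bh_adjust(c(0.01, NA, 0.5)),
               p.adjust(c(0.01, NA, 0.5), method = "BH"))
})

test_that("multi-class fitting adjusts only the non-degenerate fits", {
  tab <- synth_genome_table(400, betas = c(a = 2, b = 0, c = -1), seed = 4)
  tab$allone <- 1
  out <- fit_bgc_all(tab)
  expect_setequal(out$class, c("a", "b", "c", "allone"))
  expect_true(out$degenerate[out$class == "allone"])
  expect_true(is.na(out$p_adjusted[out$class == "allone"]))
  ok <- !out$degenerate
  expect_equal(out$p_adjusted[ok], bh_adjust(out$p_value[ok]))
})

test_that("resampling robustness behaves at its fixed points", {
  tab <- synth_genome_table(300, betas = c(a = 3, b = 0), intercepts = -1,
                            seed = 6)
  # degenerate CIs: every replicate reproduces the unresampled fit
  deg <- tab
  deg$ci_lower_hr <- deg$doubling_time_hr
  deg$ci_upper_hr <- deg$doubling_time_hr
  out <- resample_robustness(deg, scheme = "uniform_ci", n_reps = 20,
                             seed = 2)
  ref <- fit_bgc_all(deg)
  expect_equal(out$frac_significant,
               as.numeric(ref$p_adjusted < 0.05))
  expect_equal(out$mean_beta, ref$beta, tolerance = 1e-8)

  # a strong effect with tight CIs is flagged robust under both schemes
  for (scheme in c("uniform_ci", "normal_ci")) {
    rr <- resample_robustness(tab, scheme = scheme, classes = "a",
                              n_reps = 100, seed = 3,
                              sample_size = 1)
    expect_true(rr$robust)
    expect_true(all(rr$frac_significant >= 0 & rr$frac_significant <= 1))
  }
})

test_that("resampling requires usable confidence intervals", {
  tab <- synth_genome_table(100, betas = c(a = 1), seed = 7)
  noci <- dplyr::select(tab, -ci_lower_hr, -ci_upper_hr)
  expect_error(resample_robustness(noci, n_reps = 2), "ci_lower_hr")
  tab$ci_upper_hr[3] <- NA
  expect_warning(resample_robustness(tab, n_reps = 2, seed = 1),
                 "dropping 1")
})
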