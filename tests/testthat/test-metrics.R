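test_that("fitness fractions and strict thresholds follow the definitions", {
  res <- fake_result(c(8, 1, 1), c("susceptible", "resistant", "producer"))
  f <- fitness_summary(res, initial_frequency = 0.1)
  expect_equal(f$producer_fraction_total, 0.1)
  expect_false(f$invaded)            # strictly greater than, not equal
  expect_equal(f$producer_fraction_vs_resistant, 0.5)
  expect_false(f$beats_resistant)

  res2 <- fake_result(c(1, 1, 3), c("susceptible", "resistant", "producer"))
  f2 <- fitness_summary(res2, initial_frequency = 0.1)
  expect_equal(f2$producer_fraction_vs_resistant, 0.75)
  expect_true(f2$beats_resistant)
  expect_true(f2$invaded)

  res3 <- fake_result(c(5, 2, 0), c("susceptible", "resistant", "producer"))
  f3 <- fitness_summary(res3, initial_frequency = 0.1)
  expect_equal(f3$producer_fraction_total, 0)
  expect_equal(f3$producer_fraction_vs_resistant, 0)

  res4 <- fake_result(c(0, 0), c("susceptible", "producer"))
  expect_error(fitness_summary(res4), "all-zero")
})

test_that("fitness fractions are invariant to uniform biomass rescaling", {
  set.seed(3)
  for (i in 1:10) {
    b <- runif(6, 0, 1)
    roles <- c("susceptible", "susceptible", "resistant", "resistant",
               "producer", "producer")
    f1 <- fitness_summary(fake_result(b, roles), 0.1)
    f2 <- fitness_summary(fake_result(b * 1e7, roles), 0.1)
    expect_equal(f1, f2)
  }
})

test_that("maximum toxin CV handles point masses, maxima and empty fields", {
  stats_of <- function(fields) {
    m <- vapply(fields, mean, numeric(1))
    s <- vapply(fields, function(f) sqrt(mean((f - mean(f))^2)), numeric(1))
    tibble::tibble(time = seq_along(fields), mean = m, sd = s,
                   cv = ifelse(m > 0, s / m, NA_real_))
  }
  uniform <- matrix(4, 50, 50)
  expect_equal(toxin_cv_max(fake_result(c(1, 1), c("susceptible", "producer"),
    toxin_stats = stats_of(list(uniform, uniform)))), 0)

  point <- matrix(0, 50, 50); point[7, 9] <- 3
  expect_equal(toxin_cv_max(fake_result(c(1, 1), c("susceptible", "producer"),
    toxin_stats = stats_of(list(point)))), sqrt(2499))

  two <- tibble::tibble(time = 1:2, mean = c(1, 1), sd = c(0.2, 0.7),
                        cv = c(0.2, 0.7))
  expect_equal(toxin_cv_max(fake_result(c(1, 1), c("susceptible", "producer"),
    toxin_stats = two)), 0.7)

  empty <- fake_result(c(1, 1), c("susceptible", "producer"))
  expect_warning(out <- toxin_cv_max(empty), "positive toxin")
  expect_equal(out, 0)
})

test_that("toxin CV is invariant to uniform field rescaling", {
  set.seed(11)
  f <- matrix(rexp(2500), 50, 50)
  cv_of <- function(field) {
    m <- mean(field); s <- sqrt(mean((field - m)^2))
    toxin_cv_max(fake_result(c(1, 1), c("susceptible", "producer"),
      toxin_stats = tibble::tibble(time = 1, mean = m, sd = s, cv = s / m)))
  }
  expect_equal(cv_of(f), cv_of(f * 1e6))
})

test_that("proximity slope reduces to two-point OLS and sign properties", {
  # two susceptibles at 0.1 and 0.2 cm from a single producer
  res <- fake_result(c(0.5, 1.0, 2.0),
                     c("susceptible", "susceptible", "producer"),
                     rows = c(0L, 0L, 0L), cols = c(10L, 20L, 0L))
  # scaled by the max susceptible biomass (1.0): values 0.5 and 1.0
  expect_equal(proximity_effect(res), (1.0 - 0.5) / (0.2 - 0.1))

  flat <- fake_result(c(0.7, 0.7, 1), c("susceptible", "susceptible",
                                        "producer"),
                      rows = c(0L, 0L, 0L), cols = c(5L, 30L, 0L))
  expect_equal(proximity_effect(flat), 0)

  expect_error(proximity_effect(
    fake_result(c(1, 1), c("susceptible", "producer"))), "two susceptible")
  same <- fake_result(c(1, 2, 3), c("susceptible", "susceptible", "producer"),
                      rows = c(0L, 0L, 5L), cols = c(3L, 3L, 3L))
  expect_error(proximity_effect(same), "variance")
})

test_that("fitness classification uses strict and exact comparisons", {
  expect_equal(as.character(classify_fitness(0.55, 0.5)), "high")
  expect_equal(as.character(classify_fitness(0.5, 0.5)), "intermediate")
  expect_equal(as.character(classify_fitness(0, 0.5)), "low")
  expect_equal(as.character(classify_fitness(c(0.05, 0.1, 0.2), 0.1)),
               c("low", "intermediate", "high"))
  expect_error(classify_fitness(-0.1, 0.5), "non-negative")
})
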