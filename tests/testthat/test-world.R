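test_that("colony placement is seeded, distinct and capacity-checked", {
  reg <- place_colonies(1, c(susceptible = 40, resistant = 5, producer = 5),
                        50, 50)
  expect_equal(nrow(reg), 50L)
  expect_equal(anyDuplicated(reg$row * 50 + reg$col), 0L)
  expect_true(all(reg$row >= 0 & reg$row < 50))
  expect_identical(reg,
    place_colonies(1, c(susceptible = 40, resistant = 5, producer = 5),
                   50, 50))
  expect_error(place_colonies(1, c(susceptible = 2501), 50, 50),
               "too many")
})

test_that("placement leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  place_colonies(3, c(producer = 5), 20, 20)
  expect_identical(.Random.seed, before)
})

test_that("diffusion conserves mass, preserves equilibria and symmetry", {
  uni <- matrix(2.5, 20, 20)
  expect_equal(diffusion_step(uni, 5e-6, 0.1, 0.01), uni)

  set.seed(1)
  f <- matrix(runif(400), 20, 20)
  g <- diffusion_step(f, 5e-6, 0.1, 0.01)
  expect_equal(sum(g), sum(f), tolerance = 1e-10)
  expect_true(all(g >= 0))

  point <- matrix(0, 21, 21); point[11, 11] <- 1
  h <- diffusion_step(point, 5e-7, 0.5, 0.01)
  expect_equal(h, h[21:1, ])          # vertical mirror symmetry
  expect_equal(h, h[, 21:1])          # horizontal mirror symmetry
  expect_equal(h, t(h))               # diagonal symmetry

  expect_identical(diffusion_step(f, 0, 0.1, 0.01), f)
})

test_that("one growth step reproduces the closed-form producer update", {
  # realized growth of 1/hr for a producer paying a 1% cost
  cfg <- simulation_config(growth_rate = 1.01,
                           counts = c(producer = 1),
                           lattice = lattice_config(nx = 5, ny = 5),
                           carbon_per_box = 1, # ample
                           initial_biomass = 2e-10)
  reg <- tibble::tibble(colony = 1L, role = "producer", row = 2L, col = 2L)
  st <- init_world(cfg, reg)
  st2 <- growth_step(st, dt = 0.1)
  dB <- sum(st2$bio) - sum(st$bio)
  expect_equal(dB, 2e-11, tolerance = 1e-12)
  expect_equal(sum(st$carbon) - sum(st2$carbon), 2.02e-11, tolerance = 1e-9)
  expect_equal(sum(st2$toxin), 3.03e-10, tolerance = 1e-12)
})

test_that("toxin at the response threshold stops susceptible growth", {
  cfg <- simulation_config(growth_rate = 1, counts = c(susceptible = 1),
                           lattice = lattice_config(nx = 3, ny = 3),
                           carbon_per_box = 1)
  reg <- tibble::tibble(colony = 1L, role = "susceptible", row = 1L, col = 1L)
  st <- init_world(cfg, reg)
  # per-box amount giving exactly K = 15 mmol/cm^3 in a 0.01 cm box
  st$toxin[2, 2] <- 15 * 0.01^3
  st2 <- growth_step(st, dt = 0.1)
  expect_equal(st2$bio, st$bio)
  expect_equal(st2$carbon, st$carbon)
})

test_that("a box with zero carbon yields no growth and no toxin", {
  cfg <- simulation_config(growth_rate = 1, counts = c(producer = 1),
                           lattice = lattice_config(nx = 3, ny = 3),
                           carbon_per_box = 0)
  st <- init_world(cfg)
  st2 <- growth_step(st, dt = 0.1)
  expect_equal(st2$bio, st$bio)
  expect_equal(sum(st2$toxin), 0)
})

test_that("shared-box carbon contention is split proportionally", {
  cfg <- simulation_config(growth_rate = 1,
                           counts = c(susceptible = 1, resistant = 1),
                           lattice = lattice_config(nx = 1, ny = 1),
                           carbon_per_box = 1e-12,  # scarce
                           initial_biomass = 2e-10)
  reg <- tibble::tibble(colony = 1:2, role = c("susceptible", "resistant"),
                        row = 0L, col = 0L)
  st <- init_world(cfg, reg)
  st$bio[1, 1, 2] <- 6e-10   # resistant three times larger
  st2 <- growth_step(st, dt = 0.1)
  gain <- (st2$bio - st$bio)[1, 1, ]
  # equal uptake rates, so gains are proportional to biomass (3:1) and the
  # whole carbon pool is consumed
  expect_equal(gain[2] / gain[1], 3, tolerance = 1e-9)
  expect_equal(sum(gain), 1e-12, tolerance = 1e-6)
  expect_equal(st2$carbon[1, 1], 0)
})

test_that("batch runs conserve carbon and toxin ledgers", {
  res <- run_batch(tiny_config())
  fin <- res$colony_biomass[nrow(res$colony_biomass), ]
  produced <- fin - res$colony_biomass[1, ]
  cost <- ifelse(res$registry$role == "producer", 0.01, 0)
  carbon_used <- sum((1 + cost) * produced)
  carbon_init <- 12 * 12 * res$config$carbon_per_box
  expect_equal(carbon_init - sum(res$final$carbon), carbon_used,
               tolerance = 1e-6)
  tox_expected <- 15 * 1.01 * sum(produced[res$registry$role == "producer"])
  expect_equal(sum(res$final$toxin), tox_expected, tolerance = 1e-6)
  # total biomass never exceeds inoculum plus carbon capacity
  expect_lt(max(rowSums(res$colony_biomass)),
            carbon_init + sum(res$colony_biomass[1, ]) + 1e-12)
})

test_that("zero growth rate leaves the world unchanged until stationarity", {
  res <- run_batch(tiny_config(growth_rate = 0))
  expect_equal(res$colony_biomass[nrow(res$colony_biomass), ],
               res$colony_biomass[1, ])
  expect_true(res$converged)
})

test_that("a susceptible-only world converts all carbon into biomass", {
  cfg <- simulation_config(growth_rate = 1,
                           counts = c(susceptible = 4),
                           lattice = lattice_config(nx = 10, ny = 10),
                           max_time = 60)
  res <- run_batch(cfg)
  carbon_init <- 100 * cfg$carbon_per_box
  expect_equal(sum(res$colony_biomass[nrow(res$colony_biomass), ]),
               4 * cfg$initial_biomass + carbon_init, tolerance = 1e-4)
})

test_that("halving the macro step changes final totals by under 1%", {
  strains <- function(dt) {
    res <- run_batch(tiny_config(dt = dt, spatial_seed = 2))
    fin <- res$colony_biomass[nrow(res$colony_biomass), ]
    vapply(split(fin, res$registry$role), sum, numeric(1))
  }
  a <- strains(0.1)
  b <- strains(0.05)
  expect_true(all(abs(a - b) / a < 0.01))
})

test_that("the well-mixed mode is deterministic and pools the environment", {
  cfg <- simulation_config(growth_rate = 1)
  r1 <- run_well_mixed(cfg)
  r2 <- run_well_mixed(cfg)
  expect_identical(r1$colony_biomass, r2$colony_biomass)
  expect_identical(r1$final$carbon, r2$final$carbon)
  # pooled carbon equals the whole lattice inventory
  expect_equal(r1$carbon_total[1], 50 * 50 * 4e-7)
  expect_equal(dim(r1$final$carbon), c(1L, 1L))
})

test_that("zero inoculum stays at zero biomass", {
  res <- run_batch(tiny_config(initial_biomass = 0))
  expect_equal(sum(res$colony_biomass), 0)
  expect_true(res$converged)
})

test_that("tidy and glance summarise a run faithfully", {
  res <- run_batch(tiny_config())
  td <- tidy(res)
  expect_equal(nrow(td), length(res$time) * nrow(res$registry))
  expect_equal(sum(td$biomass[td$time == max(td$time)]),
               sum(res$colony_biomass[nrow(res$colony_biomass), ]))
  gl <- glance(res)
  expect_equal(gl$biomass_producer +
                 gl$biomass_susceptible + gl$biomass_resistant,
               sum(res$colony_biomass[nrow(res$colony_biomass), ]))
})
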