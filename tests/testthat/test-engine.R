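test_that("event enumeration lists one channel set per protofilament", {
  p <- fitted_params()
  sol <- solution_from_fraction(1.25, 0)
  # a fully grown extra layer: 13 association + 13 dissociation channels
  lat <- grown_lattice("plus", layers = 1)
  ev <- enumerate_events(lat, p, sol)
  expect_identical(nrow(ev), 26L)
  expect_identical(sum(ev$type == "association"), 13L)
  # hand-computed total: 13 * kon * C plus koff over the tip weights
  # (twelve full-bucket tips and one 1.5-weight seam tip)
  f <- 0.025 / 86
  koff_sum <- 0.74 * 86 * (12 * f^2 + f^1.5)
  expect_equal(sum(ev$rate), 13 * 0.925 + koff_sum, tolerance = 1e-12)
  # seed-only lattice: association channels only
  blunt <- init_lattice(lattice_params(), "plus")
  ev0 <- enumerate_events(blunt, p, sol)
  expect_identical(nrow(ev0), 13L)
  expect_true(all(ev0$type == "association"))
  # minus-end never exchanges
  px <- fitted_params(k_exch_gdp = 0.4)
  latm <- grown_lattice("minus", layers = 1)
  evm <- enumerate_events(latm, px, solution_from_fraction(1.25, 0.2))
  expect_identical(sum(evm$type == "exchange"), 0L)
  latp <- grown_lattice("plus", layers = 1)
  evp <- enumerate_events(latp, px, solution_from_fraction(1.25, 0.2))
  expect_identical(sum(evp$type == "exchange"), 26L)
})

test_that("the stochastic step samples exponential times and rate-weighted
           channels", {
  tbl <- data.frame(pf = c(1L, 1L), type = c("association", "dissociation"),
                    replacement_nt = NA_character_, rate = c(1, 3))
  set.seed(99)
  n <- 20000
  picks <- integer(n)
  dts <- numeric(n)
  for (i in seq_len(n)) {
    st <- gillespie_step(tbl)
    picks[i] <- match(st$event$type, tbl$type)
    dts[i] <- st$dt
  }
  # waiting time ~ Exp(4): mean 0.25 within 3 standard errors
  expect_lt(abs(mean(dts) - 0.25), 3 * 0.25 / sqrt(n))
  # selection frequency 0.75 for the faster channel within binomial error
  p_hat <- mean(picks == 2)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  expect_error(gillespie_step(transform(tbl, rate = 0)), "zero")
})

test_that("the compiled engine reproduces the reference engine bitwise", {
  for (end in c("plus", "minus")) {
    for (f in c(0, 0.3)) {
      p <- fitted_params(k_exch_gdp = if (f > 0) 0.4 else 0)
      cfg <- sim_config(p, solution_from_fraction(1.25, f), end,
                        duration = 20, n_replicates = 1, rng_seed = 17)
      a <- run_trajectory(cfg, engine = "cpp", event_log = TRUE)
      b <- run_trajectory(cfg, engine = "r", event_log = TRUE)
      expect_identical(a$mean_length, b$mean_length)
      expect_identical(a$final_lattice$stacks, b$final_lattice$stacks)
      expect_identical(c(a$n_assoc, a$n_dissoc, a$n_exch),
                       c(b$n_assoc, b$n_dissoc, b$n_exch))
    }
  }
})

test_that("trajectories are reproducible and ensembles order-independent", {
  cfg <- sim_config(fitted_params(), solution_from_fraction(1.25, 0.1),
                    "plus", duration = 60, n_replicates = 4, rng_seed = 5)
  e1 <- run_ensemble(cfg)
  e2 <- run_ensemble(cfg)
  expect_identical(lapply(e1, `[[`, "mean_length"),
                   lapply(e2, `[[`, "mean_length"))
  # replicates differ from one another
  expect_false(identical(e1[[1]]$mean_length, e1[[2]]$mean_length))
})

test_that("event counts and length changes balance exactly", {
  set.seed(1)
  for (i in 1:5) {
    end <- sample(c("plus", "minus"), 1)
    f <- sample(c(0, 0.25), 1)
    cfg <- sim_config(fitted_params(k_exch_gdp = 0.4),
                      solution_from_fraction(1.25, f), end,
                      duration = 120, n_replicates = 1,
                      rng_seed = sample.int(1e6, 1))
    tr <- run_trajectory(cfg)
    expect_equal((tr$n_assoc - tr$n_dissoc) * 8 / 13,
                 tr$mean_length[length(tr$mean_length)] - tr$mean_length[1])
    expect_silent(mtkmc:::validate_lattice(tr$final_lattice))
  }
})

test_that("starvation shrinks the lattice to the seed and freezes", {
  # weak affinities so that even doubly-supported tips release quickly
  weak <- kinetic_params(kon_plus = 1, kon_minus = 1, kd_long = 200,
                         kd_corner = 50)
  lat <- grown_lattice("plus", layers = 3)
  cfg <- sim_config(weak, solution_from_fraction(0, 0), "plus",
                    duration = 400, n_replicates = 1, rng_seed = 2,
                    lattice = lat)
  tr <- run_trajectory(cfg)
  expect_identical(lattice_heights(tr$final_lattice), rep(10L, 13))
  expect_equal(tr$mean_length[length(tr$mean_length)], 0)
  expect_identical(tr$n_exch, 0)
})

test_that("a single reversible protofilament matches the closed-form rate", {
  # net elongation kon*([tub] - KD_long) = 0.5 dimers/s -> 4 nm/s at 8 nm
  p <- kinetic_params(kon_plus = 1, kon_minus = 1, kd_long = 0.5,
                      kd_corner = 0.01)
  lat <- init_lattice(lattice_params(n_protofilaments = 1), "plus",
                      seed_layers = 10)
  cfg <- sim_config(p, solution_from_fraction(1, 0), "plus",
                    duration = 400, n_replicates = 40, rng_seed = 8,
                    lattice = lat)
  g <- ensemble_growth(run_ensemble(cfg), window = c(0, 400))
  se <- g$sd_nm_s / sqrt(g$n)
  expect_lt(abs(g$mean_nm_s - 4.0), 3 * se)
})

test_that("ensemble spread of the growth rate shrinks with duration", {
  p <- fitted_params()
  sol <- solution_from_fraction(1.25, 0)
  sd_of <- function(dur) {
    cfg <- sim_config(p, sol, "plus", duration = dur, n_replicates = 30,
                      rng_seed = 21)
    ensemble_growth(run_ensemble(cfg), window = c(30, dur))$sd_nm_s
  }
  expect_gt(sd_of(150), sd_of(1200))
})
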