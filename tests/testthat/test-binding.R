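test_that("competitive binding partitions tubulin between nucleotides", {
  expect_equal(cpp_tubulin_concentration(1.25, nucleotide_mix(0), 12.5), 1.25)
  expect_equal(cpp_tubulin_concentration(1.25, nucleotide_mix(25), 12.5),
               1.25 * 975 / 1287.5)  # 0.9466
  expect_equal(cpp_tubulin_concentration(1.25, nucleotide_mix(25), 1e12),
               0, tolerance = 1e-9)
  expect_error(cpp_tubulin_concentration(1, nucleotide_mix(0, 0, total = 0)),
               "no nucleotide")
  # the exact competitive form converges to the simplified one when the
  # analog concentration dwarfs its own KD
  for (gdp in c(10, 100, 500)) {
    mix <- nucleotide_mix(gdp)
    simple <- cpp_tubulin_concentration(1.25, mix, 12.5)
    exact <- cpp_tubulin_concentration(1.25, mix, 12.5,
                                       kd_cpp = 1, kd_gdp = 1 / 12.5)
    expect_lt(abs(simple - exact) / simple, 0.005)
  }
})

test_that("the mixed-nucleotide growth law behaves and clamps as stated", {
  expect_equal(minus_growth_prediction(1.25, 0), 0.9 * 1.25 - 0.05)
  # x-intercept: the GMPCPP-tubulin level where growth stalls
  expect_equal(0.9 * (0.05 / 0.9) - 0.05, 0)
  expect_warning(out <- minus_growth_prediction(1.25, 1000, clamp = TRUE),
                 "clamped")
  expect_equal(out, 0)
  expect_equal(minus_growth_prediction(1.25, 1000), -0.05)
  # monotone decreasing in GDP and in the affinity ratio
  gdp <- seq(0, 900, by = 100)
  pred <- minus_growth_prediction(1.25, gdp)
  expect_true(all(diff(pred) < 0))
  expect_true(all(minus_growth_prediction(1.25, 100, affinity_ratio = 25) <
                    minus_growth_prediction(1.25, 100, affinity_ratio = 5)))
})

test_that("the affinity ratio is recovered from growth data", {
  gdp <- c(5, 10, 25, 50, 100, 200)
  # noiseless: exact recovery
  clean <- data.frame(gdp_uM = gdp,
                      rate = minus_growth_prediction(1.25, gdp, 12.5),
                      sem = rep(0.01, 6))
  fit <- fit_affinity_ratio(clean, 1.25)
  expect_equal(fit$affinity_ratio, 12.5, tolerance = 1e-4)
  # no nucleotide preference
  flat <- data.frame(gdp_uM = gdp,
                     rate = minus_growth_prediction(1.25, gdp, 1),
                     sem = rep(0.01, 6))
  expect_equal(fit_affinity_ratio(flat, 1.25)$affinity_ratio, 1,
               tolerance = 1e-4)
  # noisy data: the interval covers the truth at roughly its nominal rate
  set.seed(12)
  hits <- 0
  for (i in 1:60) {
    d <- generate_growth_dataset("mixture", truth = list(affinity_ratio = 12.5),
                                 x = gdp, cv = 0.05, n_per_condition = 50,
                                 rng_seed = 1000 + i)
    names(d)[1] <- "gdp_uM"; names(d)[2] <- "rate"
    f <- fit_affinity_ratio(d, 1.25)
    if (f$ci95[1] <= 12.5 && 12.5 <= f$ci95[2]) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 75% coverage in 60 draws (nominal 95%)
})

test_that("quenching isotherm fits round-trip", {
  expect_equal(quench_isotherm(0, 0.6, 1, 2), 1)
  expect_equal(quench_isotherm(2, 0.6, 1, 2), 1 - 0.3)  # half saturation
  expect_error(quench_isotherm(-1, 0.6, 1, 2), "ligand")
  expect_error(quench_isotherm(1, 1.2, 1, 2), "amp_A")
  x <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
  d <- generate_binding_dataset("isotherm",
                                truth = list(amp_A = 0.55, base_B = 1.02,
                                             kd_6t = 2.3),
                                x = x, cv = 0, rng_seed = 3)
  fit <- fit_isotherm(d)
  expect_equal(fit$amp_A, 0.55, tolerance = 1e-6)
  expect_equal(fit$base_B, 1.02, tolerance = 1e-6)
  expect_equal(fit$kd_6t, 2.3, tolerance = 1e-5)
  expect_error(fit_isotherm(d[1:3, ]), "points")
})

test_that("competition fits recover the competitor affinity", {
  x <- c(0, 1, 3, 10, 30, 100, 300, 1000)
  truth <- list(amp_A = 0.6, floor_C = 0.35, kd_nuc = 12, kd_6t = 2,
                six_thio = 3)
  expect_equal(competition_model(0, 3, 0.6, 0.35, 12, 2), 0.35)
  expect_equal(competition_model(1e9, 3, 0.6, 0.35, 12, 2), 0.95,
               tolerance = 1e-6)
  d <- generate_binding_dataset("competition", truth = truth, x = x,
                                cv = 0, rng_seed = 4)
  fit <- fit_competition(d, amp_A = 0.6, kd_6t = 2)
  expect_equal(fit$kd_nuc, 12, tolerance = 1e-5)
  expect_equal(fit$floor_C, 0.35, tolerance = 1e-6)
  expect_error(fit_competition(d, amp_A = NULL, kd_6t = 2), "amp_A")
  # a competitor pair with a 12.5-fold affinity difference fits back to
  # the same ratio through the full pipeline
  d_cpp <- generate_binding_dataset(
    "competition", truth = utils::modifyList(truth, list(kd_nuc = 12.5)),
    x = x, cv = 0, rng_seed = 5)
  d_gdp <- generate_binding_dataset(
    "competition", truth = utils::modifyList(truth, list(kd_nuc = 1)),
    x = x, cv = 0, rng_seed = 6)
  r <- fit_competition(d_cpp, 0.6, 2)$kd_nuc /
    fit_competition(d_gdp, 0.6, 2)$kd_nuc
  expect_equal(r, 12.5, tolerance = 1e-4)
})

test_that("SEM propagation follows the relative-error formula", {
  expect_equal(propagate_sem(c(100, 0), c(50, 0), c(10, 0)), 0)
  expect_equal(propagate_sem(c(100, 1), c(50, 1), c(10, 0.5)),
               sqrt(1e-4 + 4e-4 + 25e-4) * 0.5)
  e <- 0.03
  expect_equal(propagate_sem(c(10, 10 * e), c(5, 5 * e), c(2, 2 * e)),
               sqrt(3) * e * 0.5)
  expect_error(propagate_sem(c(0, 1), c(1, 1), c(1, 1)), "nonzero")
})
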