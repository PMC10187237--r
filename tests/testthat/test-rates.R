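test_that("the governing nucleotide follows the mechanism and end", {
  expect_identical(
    governing_nucleotide("interface_acting", "plus", "GDP", "CPP"), "CPP")
  expect_identical(
    governing_nucleotide("self_acting", "plus", "GDP", "CPP"), "GDP")
  expect_identical(
    governing_nucleotide("interface_acting", "minus", "GDP", "GDP"), "GDP")
  expect_identical(
    governing_nucleotide("self_acting", "minus", "GDP", "GDP"), "GDP")
  expect_error(governing_nucleotide("self_acting", "minus", "GDP", "CPP"),
               "minus")
})

test_that("site affinities reproduce the tabulated KD values", {
  p <- fitted_params()
  expect_equal(site_affinity("long_only", "CPP", p), 86)
  expect_equal(site_affinity("corner", "CPP", p), 0.025)
  expect_equal(site_affinity("long_only", "GDP", p), 86 * 3500)  # 3.01e5
  expect_equal(site_affinity("corner", "GDP", p), 87.5)          # printed 87
  expect_error(site_affinity("edge", "CPP", p), "site class")
})

test_that("affinity factorization and GDP weakening hold for every class", {
  for (p in list(fitted_params(), exploratory_params())) {
    for (nt in c("CPP", "GDP")) {
      expect_equal(
        site_affinity("bucket", nt, p) / site_affinity("corner", nt, p),
        site_affinity("corner", nt, p) / site_affinity("long_only", nt, p))
    }
    for (cls in c("long_only", "corner", "bucket")) {
      expect_equal(site_affinity(cls, "GDP", p) / site_affinity(cls, "CPP", p),
                   p$gdp_factor)
    }
  }
  # the continuous-weight form agrees with the discrete classes
  p <- fitted_params()
  expect_equal(mtkmc:::affinity_from_weight(c(0, 1, 2), "CPP", p),
               site_affinity(c("long_only", "corner", "bucket"), "CPP", p))
  # and interpolates geometrically at half weights
  expect_equal(mtkmc:::affinity_from_weight(0.5, "CPP", p),
               86 * sqrt(0.025 / 86))
})

test_that("association rates scale with concentration and species fraction", {
  sol1 <- solution_from_fraction(1, 0)
  expect_equal(association_rate(exploratory_params(), "plus", sol1), 1.0)
  expect_equal(association_rate(fitted_params(), "plus",
                                solution_from_fraction(1.25, 0)), 0.925)
  expect_equal(association_rate(fitted_params(), "plus",
                                solution_from_fraction(0, 0)), 0)
  # species-resolved rates partition by the GDP-tubulin fraction
  sol <- solution_from_fraction(2, 0.25)
  p <- exploratory_params()
  expect_equal(association_rate(p, "minus", sol, "GDP"), 1 * 2 * 0.25)
  expect_equal(association_rate(p, "minus", sol, "CPP") +
                 association_rate(p, "minus", sol, "GDP"),
               association_rate(p, "minus", sol))
})

test_that("dissociation rates follow koff = kon * KD at either end", {
  p <- fitted_params()
  corner_tip <- list(site_class = "corner", self_nt = "CPP",
                     interfacial_nt = "CPP")
  expect_equal(dissociation_rate(corner_tip, p, "plus"), 0.74 * 0.025)
  long_tip <- list(site_class = "long_only", self_nt = "CPP",
                   interfacial_nt = "CPP")
  expect_equal(dissociation_rate(long_tip, p, "minus"), 0.31 * 86)
  # KD -> 0 limit
  p0 <- kinetic_params(kd_corner = 1e-12, kd_long = 86)
  expect_lt(dissociation_rate(corner_tip, p0, "plus"), 1e-11)
  # detailed-balance-style check: at [tub] = KD the on and off rates match
  sol_kd <- solution_from_fraction(86, 0)
  expect_equal(dissociation_rate(long_tip, p, "plus"),
               association_rate(p, "plus", sol_kd))
})

test_that("terminal nucleotide exchange fires only at the plus-end", {
  p <- fitted_params(k_exch_gdp = 0.4)
  sol <- solution_from_mix(1.25, gdp_conc = 25)
  gdp_tip <- list(site_class = "corner", self_nt = "GDP",
                  interfacial_nt = "CPP")
  ev <- exchange_events(gdp_tip, p, sol, "plus")
  expect_equal(sum(ev$rate), 0.4)
  expect_equal(ev$rate[ev$replacement_nt == "CPP"] / sum(ev$rate), 0.975)
  cpp_tip <- list(site_class = "corner", self_nt = "CPP",
                  interfacial_nt = "CPP")
  ev2 <- exchange_events(cpp_tip, p, sol, "plus")
  expect_equal(sum(ev2$rate), 12.5 * 0.4)  # the analog leaves 12.5x faster
  expect_identical(nrow(exchange_events(gdp_tip, p, sol, "minus")), 0L)
  expect_identical(
    nrow(exchange_events(gdp_tip, fitted_params(), sol, "plus")), 0L)
})

test_that("solution constructors agree with the competitive binding model", {
  sol <- solution_from_mix(1.25, gdp_conc = 25)
  expect_equal(sol$cpp_conc, 975)
  expect_equal(sol$frac_gdp_tubulin, 1 - 975 / (975 + 25 * 12.5))
  # fraction -> mix -> fraction round-trip
  for (f in c(0, 0.1, 0.5, 0.9)) {
    s <- solution_from_fraction(1, f)
    s2 <- solution_from_mix(1, s$gdp_conc)
    expect_equal(s2$frac_gdp_tubulin, f, tolerance = 1e-12)
  }
  expect_error(solution_state(1, 500, 500, 1.5), "frac_gdp_tubulin")
  expect_error(kinetic_params(kd_corner = 90, kd_long = 86), "kd_corner")
})
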