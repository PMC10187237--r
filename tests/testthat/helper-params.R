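# Shared parameter sets and small builders used across the suite.

# Exploratory parameter set (arbitrary affinities that support elongation
# at ~1 uM): kon 1.0 both ends, KD_long 100 uM, KD_corner 0.1 uM,
# 3000-fold GDP weakening.
exploratory_params <- function(mechanism = "interface_acting",
                               k_exch_gdp = 0) {
  kinetic_params(kon_plus = 1, kon_minus = 1, kd_long = 100,
                 kd_corner = 0.1, gdp_factor = 3000,
                 mechanism = mechanism, k_exch_gdp = k_exch_gdp)
}

# Fitted GMPCPP parameter set: kon+ 0.74 / kon- 0.31, KD_long 86 uM,
# KD_corner 25 nM, 3500-fold GDP weakening.
fitted_params <- function(mechanism = "interface_acting", k_exch_gdp = 0) {
  kinetic_params(mechanism = mechanism, k_exch_gdp = k_exch_gdp)
}

# a small grown lattice: blunt seed plus `layers` full extra layers
grown_lattice <- function(end = "plus", layers = 1L, params = lattice_params(),
                          seed_layers = 10L, nt = "CPP") {
  lat <- init_lattice(params, end, seed_layers = seed_layers)
  for (l in seq_len(layers))
    for (pf in seq_len(params$n_protofilaments))
      lat <- mtkmc:::lattice_associate(lat, pf, nt)
  lat
}

# random tapered lattice for property checks (heights seed..seed+extra)
random_lattice <- function(end = "plus", extra = 4L, params = lattice_params(),
                           seed_layers = 10L, gdp_prob = 0.3) {
  lat <- init_lattice(params, end, seed_layers = seed_layers)
  for (pf in seq_len(params$n_protofilaments)) {
    for (l in seq_len(sample.int(extra + 1L, 1L) - 1L)) {
      nt <- if (stats::runif(1) < gdp_prob) "GDP" else "CPP"
      lat <- mtkmc:::lattice_associate(lat, pf, nt)
    }
  }
  lat
}
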