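#' Default configuration
#'
#' One structured document with sections `lattice`, `kinetics`, `solution`,
#' `simulation` and `calibration`; the kinetic defaults are the fitted
#' GMPCPP parameter set (kon+ 0.74 / kon- 0.31 uM^-1 s^-1, KD_long 86 uM,
#' KD_corner 0.025 uM, 3500-fold GDP weakening) at 1.25 uM tubulin.
#'
#' @return A nested list of class `mtkmc_config`.
#' @export
default_config <- function() {
  structure(list(
    lattice = list(n_protofilaments = 13L, seam_offset = 1L, dimer_rise = 8,
                   seed_layers = 10L),
    kinetics = list(kon_plus = 0.74, kon_minus = 0.31, kd_long = 86,
                    kd_corner = 0.025, gdp_factor = 3500,
                    mechanism = "interface_acting", k_exch_gdp = 0,
                    affinity_ratio = 12.5),
    solution = list(tubulin_total = 1.25, frac_gdp_tubulin = 0,
                    total_nucleotide = 1000),
    simulation = list(end = "plus", duration = 600, n_replicates = 50,
                      record_interval = 1, rng_seed = 1L),
    calibration = list(bounds = c(0.05, 1.5), duration = 300,
                       n_replicates = 50)
  ), class = "mtkmc_config")
}

#' Read / write a configuration file (YAML)
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config` returns an `mtkmc_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop(sprintf("unknown config section '%s'", section), call. = FALSE)
    cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble model objects from a configuration
#'
#' @param config An `mtkmc_config` list.
#' @return `config_kinetic_params` a [kinetic_params()];
#'   `config_solution` a [solution_state()];
#'   `config_sim` a ready-to-run [sim_config()].
#' @export
config_kinetic_params <- function(config) {
  k <- config$kinetics
  kinetic_params(kon_plus = k$kon_plus, kon_minus = k$kon_minus,
                 kd_long = k$kd_long, kd_corner = k$kd_corner,
                 gdp_factor = k$gdp_factor, mechanism = k$mechanism,
                 k_exch_gdp = k$k_exch_gdp,
                 affinity_ratio = k$affinity_ratio)
}

#' @rdname config_kinetic_params
#' @export
config_solution <- function(config) {
  s <- config$solution
  solution_from_fraction(s$tubulin_total, s$frac_gdp_tubulin,
                         total_nucleotide = s$total_nucleotide,
                         affinity_ratio = config$kinetics$affinity_ratio)
}

#' @rdname config_kinetic_params
#' @export
config_sim <- function(config) {
  l <- config$lattice
  sim <- config$simulation
  lat <- init_lattice(
    lattice_params(l$n_protofilaments, l$seam_offset, l$dimer_rise),
    sim$end, seed_layers = l$seed_layers)
  sim_config(config_kinetic_params(config), config_solution(config),
             end = sim$end, duration = sim$duration,
             n_replicates = sim$n_replicates,
             record_interval = sim$record_interval,
             rng_seed = sim$rng_seed, lattice = lat)
}
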