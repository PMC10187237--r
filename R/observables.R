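#' Growth rate of a single trajectory
#'
#' Ordinary least-squares slope of mean length versus time over a window.
#' The default window starts at 30 s to skip the transient caused by blunt
#' initialization (a blunt end briefly over-supplies bucket sites).
#'
#' @param traj An `mt_trajectory`.
#' @param window `c(t0, t1)` in seconds; `NA` for `t1` means the trajectory
#'   end.
#' @return Growth rate in nm/s.
#' @export
trajectory_growth_rate <- function(traj, window = c(30, NA)) {
  stopifnot(inherits(traj, "mt_trajectory"))
  t0 <- window[1]
  t1 <- if (is.na(window[2])) max(traj$times) else window[2]
  keep <- traj$times >= t0 & traj$times <= t1
  if (sum(keep) < 2L)
    stop("growth-rate window contains fewer than 2 samples", call. = FALSE)
  x <- traj$times[keep]
  y <- traj$mean_length[keep]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Ensemble growth statistics
#'
#' Per-trajectory slopes are computed first and then averaged, so the
#' reported spread is the standard deviation across replicates (the error
#' bar convention for simulated conditions).
#'
#' @param trajs List of `mt_trajectory` (e.g. from [run_ensemble()]).
#' @param window Passed to [trajectory_growth_rate()].
#' @return A one-row data frame: `end`, `mechanism`, `tubulin_uM`,
#'   `gdp_frac`, `mean_nm_s`, `sd_nm_s`, `n`.
#' @export
ensemble_growth <- function(trajs, window = c(30, NA)) {
  if (length(trajs) < 1L) stop("empty ensemble", call. = FALSE)
  rates <- vapply(trajs, trajectory_growth_rate, numeric(1), window = window)
  if (length(rates) == 1L) {
    warning("single trajectory: SD reported as 0")
    s <- 0
  } else {
    s <- stats::sd(rates)
  }
  t1 <- trajs[[1]]
  data.frame(end = t1$end, mechanism = t1$mechanism,
             tubulin_uM = t1$tubulin, gdp_frac = t1$frac_gdp_tubulin,
             mean_nm_s = mean(rates), sd_nm_s = s, n = length(rates),
             stringsAsFactors = FALSE)
}

#' Simulate a growth-rate versus concentration series
#'
#' Runs one ensemble per tubulin concentration (all-GMPCPP unless a
#' GDP-tubulin fraction is given) and collects ensemble growth statistics —
#' the simulated analog of a concentration titration.
#'
#' @param params A [kinetic_params()].
#' @param end `"plus"` or `"minus"`.
#' @param concentrations Tubulin concentrations (uM).
#' @param gdp_fraction GDP-tubulin fraction applied to every condition.
#' @param n_replicates,duration,record_interval,rng_seed Ensemble settings
#'   (see [sim_config()]); each condition uses a distinct derived seed.
#' @param window Growth-rate fit window.
#' @return Data frame of per-condition growth measurements.
#' @export
growth_concentration_series <- function(params, end, concentrations,
                                        gdp_fraction = 0,
                                        n_replicates = 50, duration = 600,
                                        record_interval = 1, rng_seed = 1L,
                                        window = c(30, NA)) {
  rows <- lapply(seq_along(concentrations), function(i) {
    sol <- solution_from_fraction(concentrations[i], gdp_fraction,
                                  affinity_ratio = params$affinity_ratio)
    cfg <- sim_config(params, sol, end = end, duration = duration,
                      n_replicates = n_replicates,
                      record_interval = record_interval,
                      rng_seed = substream_seed(rng_seed, 1000 + i))
    ensemble_growth(run_ensemble(cfg), window = window)
  })
  do.call(rbind, rows)
}

#' Simulate a mixed-nucleotide series at fixed tubulin
#'
#' Runs one ensemble per GDP-tubulin fraction at a constant total tubulin
#' concentration, the simulated analog of the mixed GMPCPP/GDP titration.
#'
#' @inheritParams growth_concentration_series
#' @param tubulin_total Tubulin concentration (uM).
#' @param gdp_fractions GDP-tubulin fractions (0..1).
#' @return Data frame of per-condition growth measurements.
#' @export
mixture_series <- function(params, end, tubulin_total, gdp_fractions,
                           n_replicates = 50, duration = 600,
                           record_interval = 1, rng_seed = 1L,
                           window = c(30, NA)) {
  rows <- lapply(seq_along(gdp_fractions), function(i) {
    sol <- solution_from_fraction(tubulin_total, gdp_fractions[i],
                                  affinity_ratio = params$affinity_ratio)
    cfg <- sim_config(params, sol, end = end, duration = duration,
                      n_replicates = n_replicates,
                      record_interval = record_interval,
                      rng_seed = substream_seed(rng_seed, 2000 + i))
    ensemble_growth(run_ensemble(cfg), window = window)
  })
  do.call(rbind, rows)
}

#' Weighted linear fit of growth rate versus tubulin concentration
#'
#' Fits `rate = slope * conc + intercept` by least squares, weighting each
#' point by the inverse of its standard error of the mean (residuals are
#' divided by the SEM) when SEMs are available. Reports the apparent
#' on-rate constant both in nm s^-1 uM^-1 (the slope) and in dimers s^-1
#' uM^-1 per microtubule (slope divided by the mean length one subunit
#' adds), and the apparent critical concentration as the x-intercept.
#'
#' @param measurements Data frame with `tubulin_uM` (or `conc`), `mean_nm_s`
#'   (or `rate`), and either `sem` or `sd_nm_s` + `n`.
#' @param dimer_rise,n_protofilaments Geometry used for the unit conversion.
#' @return An object of class `growth_fit`: slope/intercept with standard
#'   errors, `kon_app_nm`, `kon_app_dimers`, `cc_app_uM`.
#' @examples
#' d <- data.frame(tubulin_uM = c(0.5, 1, 1.5),
#'                 mean_nm_s = 0.9 * c(0.5, 1, 1.5) - 0.05)
#' concentration_series_fit(d)
#' @export
concentration_series_fit <- function(measurements, dimer_rise = 8,
                                     n_protofilaments = 13) {
  conc <- measurements$tubulin_uM
  if (is.null(conc)) conc <- measurements$conc
  rate <- measurements$mean_nm_s
  if (is.null(rate)) rate <- measurements$rate
  if (length(conc) < 3L)
    stop("need at least 3 concentrations", call. = FALSE)
  sem <- measurements$sem
  if (is.null(sem) && !is.null(measurements$sd_nm_s) &&
      !is.null(measurements$n)) {
    sem <- measurements$sd_nm_s / sqrt(measurements$n)
  }
  w <- if (!is.null(sem) && all(sem > 0)) 1 / sem^2 else rep(1, length(conc))
  fit <- stats::lm(rate ~ conc, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf["conc", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  if (abs(slope) < .Machine$double.eps^0.5)
    warning("flat concentration series: critical concentration undefined")
  len_per_sub <- dimer_rise / n_protofilaments
  structure(
    list(slope = slope, intercept = intercept,
         slope_se = cf["conc", "Std. Error"],
         intercept_se = cf["(Intercept)", "Std. Error"],
         kon_app_nm = slope,
         kon_app_dimers = slope / len_per_sub,
         cc_app_uM = if (abs(slope) < .Machine$double.eps^0.5) NA_real_
                     else -intercept / slope,
         fit = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    paste0("growth-curve fit:\n",
           "  kon_app  %.3g nm s^-1 uM^-1  (%.3g dimers s^-1 uM^-1 MT^-1)\n",
           "  intercept %.3g nm/s, Cc_app %.3g uM\n"),
    x$kon_app_nm, x$kon_app_dimers, x$intercept, x$cc_app_uM))
  invisible(x)
}

#' Normalize a mixed-nucleotide series to a reference condition
#'
#' Divides every mean rate (and its SD) by the mean rate of the reference
#' condition, which maps to 1 — the convention used to compare suppression
#' between ends.
#'
#' @param measurements Data frame from [mixture_series()] (or with columns
#'   `mean_nm_s`, `sd_nm_s`).
#' @param reference Row index of the reference condition, or a logical
#'   vector selecting it; default the first row (usually 0% GDP).
#' @return The input with `norm_mean` and `norm_sd` columns added.
#' @export
normalized_mixture_curve <- function(measurements, reference = 1L) {
  ref <- measurements[reference, , drop = FALSE]
  if (nrow(ref) != 1L) stop("reference must select one row", call. = FALSE)
  if (ref$mean_nm_s <= 0)
    stop("reference mean rate must be positive", call. = FALSE)
  measurements$norm_mean <- measurements$mean_nm_s / ref$mean_nm_s
  measurements$norm_sd <- measurements$sd_nm_s / ref$mean_nm_s
  measurements
}

#' Stoichiometric-dilution prediction for normalized growth
#'
#' If GDP-tubulin contributed nothing to growth, replacing a fraction `f` of
#' the tubulin by GDP-tubulin would be equivalent to diluting: normalized
#' rate = (C(1-f) - Cc) / (C - Cc), linear in `f`. Deviations below this
#' line indicate super-stoichiometric suppression (protofilament
#' poisoning).
#'
#' @param gdp_fraction GDP-tubulin fraction(s).
#' @param tubulin_total Tubulin concentration (uM).
#' @param cc_app Apparent critical concentration (uM).
#' @return Predicted normalized growth rate(s).
#' @export
stoichiometric_dilution <- function(gdp_fraction, tubulin_total, cc_app) {
  (tubulin_total * (1 - gdp_fraction) - cc_app) / (tubulin_total - cc_app)
}

#' Write growth measurements as CSV
#'
#' @param measurements Data frame of growth measurements.
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(measurements, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, format, character(1))), con)
  }
  utils::write.csv(measurements, con, row.names = FALSE)
  invisible(path)
}
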