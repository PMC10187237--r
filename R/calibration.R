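#' Simulation loss for a growth-rate target
#'
#' SEM-weighted squared error between ensemble-mean simulated growth rates
#' and a target dataset over a set of conditions. Each evaluation re-uses
#' the same per-condition replicate seeds (common random numbers), so the
#' loss is a deterministic function of the candidate parameter and a
#' derivative-free scalar optimizer can search it.
#'
#' @noRd
calibration_loss <- function(sim_rates, target_rates, sem) {
  sum(((sim_rates - target_rates) / sem)^2)
}

#' Calibrate the minus-end on-rate constant against growth data
#'
#' Optimizes `kon_minus` so that simulated minus-end ensemble growth rates
#' best recapitulate a target concentration series, holding the interaction
#' affinities fixed. The loss is the SEM-weighted squared error; replicate
#' seeds are shared across candidate values (common random numbers) so the
#' stochastic loss is smooth enough for Brent's method.
#'
#' @param target Data frame with `tubulin_uM`, `mean_nm_s`, and `sem` (or
#'   `sd_nm_s` + `n`) for at least 3 concentrations.
#' @param params A [kinetic_params()]; its `kon_minus` is ignored.
#' @param bounds Search interval for `kon_minus` (uM^-1 s^-1).
#' @param n_replicates,duration Ensemble settings per loss evaluation
#'   (50 x 300 s matches the calibration protocol).
#' @param rng_seed Master seed shared by every candidate evaluation.
#' @param window Growth-rate fit window.
#' @param tol Convergence tolerance for [stats::optimize()].
#' @return List with `kon_minus`, the achieved `loss`, and `profile`
#'   (a data frame of every evaluated candidate and its loss).
#' @export
fit_kon_minus <- function(target, params, bounds = c(0.05, 1.5),
                          n_replicates = 50, duration = 300,
                          rng_seed = 1L, window = c(30, NA),
                          tol = 0.005) {
  conc <- target$tubulin_uM
  if (length(conc) < 3L)
    stop("target must cover at least 3 concentrations", call. = FALSE)
  sem <- target$sem
  if (is.null(sem)) sem <- target$sd_nm_s / sqrt(target$n)
  if (any(sem <= 0)) stop("target SEMs must be > 0", call. = FALSE)
  if (any(bounds <= 0)) stop("bounds must be positive", call. = FALSE)
  evals <- list()
  loss_fn <- function(kon) {
    p <- params
    p$kon_minus <- kon
    sim <- growth_concentration_series(
      p, "minus", conc, n_replicates = n_replicates, duration = duration,
      rng_seed = rng_seed, window = window)
    loss <- calibration_loss(sim$mean_nm_s, target$mean_nm_s, sem)
    evals[[length(evals) + 1]] <<- data.frame(kon_minus = kon, loss = loss)
    loss
  }
  opt <- stats::optimize(loss_fn, interval = bounds, tol = tol)
  profile <- do.call(rbind, evals)
  if (opt$objective > min(profile$loss) + 1e-12)
    warning("loss profile non-convex: optimizer minimum exceeds a probed value")
  list(kon_minus = opt$minimum, loss = opt$objective, profile = profile)
}

#' Scan the terminal nucleotide-exchange rate
#'
#' Simulates plus-end growth over a grid of GDP exchange rates and
#' GDP-tubulin fractions at fixed tubulin, returning the growth surface.
#' `k_exch_gdp = 0` reproduces the no-exchange model exactly; faster
#' exchange shortens the residence of terminal GDP and relieves
#' protofilament poisoning, so growth at fixed fraction is non-decreasing
#' in the exchange rate.
#'
#' @param k_exch_grid Exchange rates to probe (s^-1, >= 2 values).
#' @param gdp_fractions GDP-tubulin fractions (0..1).
#' @param params A [kinetic_params()]; its `k_exch_gdp` is overridden.
#' @param tubulin_total Tubulin concentration (uM).
#' @param n_replicates,duration,rng_seed,window Ensemble settings; all grid
#'   points share the same replicate seeds (common random numbers).
#' @return Data frame with `k_exch`, `gdp_frac`, `mean_nm_s`, `sd_nm_s`,
#'   `n`, of class `exchange_scan`.
#' @export
exchange_scan <- function(k_exch_grid, gdp_fractions, params,
                          tubulin_total = 1.25, n_replicates = 50,
                          duration = 600, rng_seed = 1L,
                          window = c(30, NA)) {
  if (length(k_exch_grid) < 2L)
    stop("grid must contain at least 2 exchange rates", call. = FALSE)
  if (any(k_exch_grid < 0))
    stop("exchange rates must be >= 0", call. = FALSE)
  rows <- list()
  for (k in k_exch_grid) {
    p <- params
    p$k_exch_gdp <- k
    m <- mixture_series(p, "plus", tubulin_total, gdp_fractions,
                        n_replicates = n_replicates, duration = duration,
                        rng_seed = rng_seed, window = window)
    m$k_exch <- k
    rows[[length(rows) + 1]] <- m
  }
  out <- do.call(rbind, rows)
  out <- out[, c("k_exch", "gdp_frac", "mean_nm_s", "sd_nm_s", "n")]
  class(out) <- c("exchange_scan", "data.frame")
  out
}

#' Pick the exchange rate that best matches a target suppression curve
#'
#' For each grid rate, compares the simulated growth rates (or normalized
#' rates) across GDP-tubulin fractions to a target curve by SEM-weighted
#' squared distance and returns the argmin.
#'
#' @param scan An [exchange_scan()] result.
#' @param target Data frame with `gdp_frac`, `rate` (same scale as the
#'   comparison), and optional `sem`.
#' @param normalized Compare normalized curves (each rate divided by the
#'   same-`k_exch` value at the smallest fraction present in the scan)?
#' @return List with `best_k_exch` and the per-rate `distance` table.
#' @export
best_exchange_rate <- function(scan, target, normalized = FALSE) {
  stopifnot(all(c("gdp_frac", "rate") %in% names(target)))
  sem <- target$sem
  if (is.null(sem)) sem <- rep(1, nrow(target))
  rates <- sort(unique(scan$k_exch))
  dist <- vapply(rates, function(k) {
    sub <- scan[scan$k_exch == k, ]
    sub <- sub[order(sub$gdp_frac), ]
    sim <- sub$mean_nm_s
    if (normalized) {
      ref <- sim[which.min(sub$gdp_frac)]
      if (ref <= 0) return(Inf)
      sim <- sim / ref
    }
    m <- match(target$gdp_frac, sub$gdp_frac)
    if (anyNA(m)) stop("target fractions missing from the scan", call. = FALSE)
    sum(((sim[m] - target$rate) / sem)^2)
  }, numeric(1))
  list(best_k_exch = rates[which.min(dist)],
       distance = data.frame(k_exch = rates, distance = dist))
}

#' Write an exchange scan as CSV
#'
#' @param scan An [exchange_scan()] result.
#' @param path Output path.
#' @param meta Optional named list for the `#` metadata header.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path, meta = NULL) {
  write_growth_csv(as.data.frame(scan), path, meta = meta)
}
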