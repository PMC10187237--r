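#' Simulation configuration
#'
#' Bundles everything one stochastic growth simulation needs: kinetic
#' parameters, solution composition, end polarity, duration, ensemble size,
#' sampling interval and the master RNG seed.
#'
#' @param params A [kinetic_params()] object (carries the mechanism).
#' @param solution A [solution_state()].
#' @param end `"plus"` or `"minus"`.
#' @param duration Simulated time (s).
#' @param n_replicates Independent trajectories in an ensemble.
#' @param record_interval Sampling interval for the length record (s);
#'   default 1 s, matching 1 frame/s imaging.
#' @param rng_seed Master seed; replicate seeds are derived deterministically
#'   so ensembles are reproducible and order-independent.
#' @param lattice Optional starting [init_lattice()] lattice; default a blunt
#'   13-protofilament, 10-seed-layer lattice with the stated polarity.
#' @param seed_layers Seed depth for the default lattice.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, solution, end = c("plus", "minus"),
                       duration = 600, n_replicates = 50,
                       record_interval = 1, rng_seed = 1L,
                       lattice = NULL, seed_layers = 10L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(solution, "solution_state"))
  end <- match.arg(end)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (record_interval > duration)
    stop("`record_interval` must not exceed `duration`", call. = FALSE)
  if (is.null(lattice)) {
    lattice <- init_lattice(lattice_params(), end, seed_layers = seed_layers)
  } else {
    stopifnot(inherits(lattice, "end_lattice"))
    if (lattice$end != end)
      stop("lattice polarity does not match `end`", call. = FALSE)
  }
  structure(
    list(params = params, solution = solution, end = end,
         duration = duration, n_replicates = as.integer(n_replicates),
         record_interval = record_interval,
         rng_seed = as.integer(rng_seed), lattice = lattice),
    class = "sim_config"
  )
}

# deterministic, order-independent replicate seeds below 2^31
substream_seed <- function(master, i) {
  m <- ((as.double(master) %% 2147483647) * 48271 +
          as.double(i) * 30269) %% 2147483647
  as.integer(m)
}

#' Enumerate all reaction channels for the current lattice
#'
#' One association channel per protofilament (rate `kon * [tubulin]`), one
#' dissociation channel per dissociable tip (rate from
#' [dissociation_rate()]), and the exchange channels from
#' [exchange_events()]. Channels are listed protofilament-by-protofilament
#' in the fixed order association, dissociation, exchange->CPP,
#' exchange->GDP, which is also the order the stochastic step selects in.
#'
#' @param lattice An `end_lattice`.
#' @param params A [kinetic_params()].
#' @param solution A [solution_state()].
#' @return Data frame with columns `pf`, `type`, `replacement_nt`, `rate`.
#' @export
enumerate_events <- function(lattice, params, solution) {
  stopifnot(inherits(lattice, "end_lattice"))
  tips <- tip_sites(lattice)
  a_rate <- association_rate(params, lattice$end, solution)
  rows <- vector("list", lattice$params$n_protofilaments)
  for (pf in seq_len(lattice$params$n_protofilaments)) {
    r <- data.frame(pf = pf, type = "association",
                    replacement_nt = NA_character_, rate = a_rate,
                    stringsAsFactors = FALSE)
    ti <- tips[tips$pf == pf, ]
    if (nrow(ti) == 1L) {
      r <- rbind(r, data.frame(
        pf = pf, type = "dissociation", replacement_nt = NA_character_,
        rate = dissociation_rate(ti, params, lattice$end),
        stringsAsFactors = FALSE))
      ex <- exchange_events(ti, params, solution, lattice$end)
      if (nrow(ex) > 0L) {
        r <- rbind(r, data.frame(
          pf = pf, type = "exchange", replacement_nt = ex$replacement_nt,
          rate = ex$rate, stringsAsFactors = FALSE))
      }
    }
    rows[[pf]] <- r
  }
  do.call(rbind, rows)
}

#' One Gillespie (direct method) step
#'
#' Draws the exponential waiting time for the next reaction and selects the
#' firing channel with probability proportional to its rate, consuming
#' exactly two uniforms from the R RNG stream.
#'
#' @param event_table Output of [enumerate_events()].
#' @return A list with `event` (the chosen row) and `dt` (s).
#' @export
gillespie_step <- function(event_table) {
  total <- sum(event_table$rate)
  if (total <= 0) stop("total rate is zero; no event can fire", call. = FALSE)
  u1 <- stats::runif(1)
  dt <- -log(u1) / total
  u2 <- stats::runif(1)
  idx <- which(cumsum(event_table$rate) > u2 * total)[1]
  list(event = event_table[idx, ], dt = dt)
}

# apply one selected event; draws the landing nucleotide for associations
# (one uniform, only when GDP-tubulin is present, matching the C++ engine)
apply_kmc_event <- function(lattice, event, solution) {
  if (event$type == "association") {
    nt <- NT_CPP
    if (solution$frac_gdp_tubulin > 0) {
      nt <- if (stats::runif(1) < solution$frac_gdp_tubulin) NT_GDP else NT_CPP
    }
    lattice_associate(lattice, event$pf, nt)
  } else if (event$type == "dissociation") {
    lattice_dissociate(lattice, event$pf)
  } else {
    lattice_exchange(lattice, event$pf, event$replacement_nt)
  }
}

new_trajectory <- function(times, mean_length, counts, config, final_lattice,
                           event_log = NULL) {
  structure(
    list(times = times, mean_length = mean_length,
         n_assoc = counts[1], n_dissoc = counts[2], n_exch = counts[3],
         end = config$end, mechanism = config$params$mechanism,
         tubulin = config$solution$tubulin_total,
         frac_gdp_tubulin = config$solution$frac_gdp_tubulin,
         dimer_rise = config$lattice$params$dimer_rise,
         n_protofilaments = config$lattice$params$n_protofilaments,
         final_lattice = final_lattice, event_log = event_log),
    class = "mt_trajectory"
  )
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf(
    "%s-end trajectory (%s): %.0f s, %d samples, final length %.1f nm\n",
    x$end, x$mechanism, max(x$times), length(x$times),
    x$mean_length[length(x$mean_length)]))
  cat(sprintf("  events: %d assoc / %d dissoc / %d exchange\n",
              x$n_assoc, x$n_dissoc, x$n_exch))
  invisible(x)
}

#' Run one stochastic growth trajectory
#'
#' Simulates the event system from the configured starting lattice until
#' `duration`, recording the mean protofilament length (nm above the seed)
#' on the sampling grid. The default engine is the compiled Gillespie loop;
#' `engine = "r"` runs the pure-R reference implementation
#' ([enumerate_events()] + [gillespie_step()]), which consumes the RNG
#' stream identically and therefore reproduces the compiled engine's event
#' sequence bitwise under the same seed.
#'
#' @param config A [sim_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @param event_log Keep the per-event record (time, type, pf, nucleotide)?
#' @param set_seed Seed the RNG from `config$rng_seed` first? (Ensembles
#'   manage per-replicate seeds themselves.)
#' @return An `mt_trajectory`.
#' @examples
#' cfg <- sim_config(kinetic_params(), solution_from_fraction(1.25, 0),
#'                   end = "plus", duration = 30, n_replicates = 1,
#'                   rng_seed = 42)
#' run_trajectory(cfg)
#' @export
run_trajectory <- function(config, engine = c("cpp", "r"),
                           event_log = FALSE, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  if (set_seed) set.seed(config$rng_seed)
  if (engine == "cpp") run_trajectory_cpp(config, event_log)
  else run_trajectory_r(config, event_log)
}

run_trajectory_cpp <- function(config, event_log = FALSE) {
  lat <- config$lattice
  p <- config$params
  s <- config$solution
  nuc_total <- s$cpp_conc + s$gdp_conc
  p_cpp_nuc <- if (nuc_total > 0) s$cpp_conc / nuc_total else 1
  res <- run_kmc_cpp(
    lat$stacks, lat$seed_layers, lat$end == "plus",
    lat$params$seam_offset, lat$params$dimer_rise,
    kon_for_end(p, lat$end), p$kd_long, p$kd_corner, p$gdp_factor,
    p$mechanism == "interface_acting",
    p$k_exch_gdp, p$affinity_ratio,
    s$tubulin_total, s$frac_gdp_tubulin, p_cpp_nuc,
    config$duration, config$record_interval, event_log)
  final <- lat
  final$stacks <- res$final_stacks
  log <- NULL
  if (event_log) {
    log <- data.frame(
      time = res$event_time,
      event = c("association", "dissociation", "exchange")[res$event_type],
      pf = res$event_pf,
      nucleotide = nt_label(res$event_nt),
      stringsAsFactors = FALSE)
  }
  new_trajectory(res$times, res$mean_length,
                 c(res$n_assoc, res$n_dissoc, res$n_exch),
                 config, final, log)
}

run_trajectory_r <- function(config, event_log = FALSE) {
  lat <- config$lattice
  s <- config$solution
  ri <- config$record_interval
  n_grid <- floor(config$duration / ri + 1e-9)
  rec_t <- 0
  rec_len <- mean_length_nm(lat)
  next_rec <- 1
  counts <- c(0, 0, 0)
  log <- if (event_log) list() else NULL
  t <- 0
  while (t < config$duration) {
    ev_table <- enumerate_events(lat, config$params, s)
    total <- sum(ev_table$rate)
    if (total <= 0) break
    step <- gillespie_step(ev_table)
    t_new <- t + step$dt
    while (next_rec <= n_grid &&
           next_rec * ri <= min(t_new, config$duration)) {
      rec_t <- c(rec_t, next_rec * ri)
      rec_len <- c(rec_len, mean_length_nm(lat))
      next_rec <- next_rec + 1
    }
    if (t_new >= config$duration) break
    lat <- apply_kmc_event(lat, step$event, s)
    i <- match(step$event$type, c("association", "dissociation", "exchange"))
    counts[i] <- counts[i] + 1
    if (event_log) {
      nt <- switch(step$event$type,
        association = nt_label(lat$stacks[[step$event$pf]][
          length(lat$stacks[[step$event$pf]])]),
        dissociation = NA_character_,
        exchange = step$event$replacement_nt)
      log[[length(log) + 1]] <- data.frame(
        time = t_new, event = step$event$type, pf = step$event$pf,
        nucleotide = nt, stringsAsFactors = FALSE)
    }
    t <- t_new
  }
  while (next_rec <= n_grid) {
    rec_t <- c(rec_t, next_rec * ri)
    rec_len <- c(rec_len, mean_length_nm(lat))
    next_rec <- next_rec + 1
  }
  if (rec_t[length(rec_t)] < config$duration - 1e-9) {
    rec_t <- c(rec_t, config$duration)
    rec_len <- c(rec_len, mean_length_nm(lat))
  }
  new_trajectory(rec_t, rec_len, counts, config, lat,
                 if (event_log) do.call(rbind, log) else NULL)
}

#' Run an ensemble of independent trajectories
#'
#' Each replicate is seeded from a deterministic substream of the master
#' seed, so the ensemble is reproducible and independent of execution order.
#'
#' @inheritParams run_trajectory
#' @return A list of `mt_trajectory` objects of length
#'   `config$n_replicates`.
#' @export
run_ensemble <- function(config, engine = c("cpp", "r"), event_log = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  lapply(seq_len(config$n_replicates), function(i) {
    set.seed(substream_seed(config$rng_seed, i))
    run_trajectory(config, engine = engine, event_log = event_log,
                   set_seed = FALSE)
  })
}

#' Write a trajectory (and optionally its event log) as CSV
#'
#' @param traj An `mt_trajectory`.
#' @param path Output CSV path for the (time_s, mean_length_nm) record.
#' @param event_log_path Optional path for the per-event CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, event_log_path = NULL) {
  meta <- c(
    sprintf("# end: %s", traj$end),
    sprintf("# mechanism: %s", traj$mechanism),
    sprintf("# tubulin_uM: %g", traj$tubulin),
    sprintf("# frac_gdp_tubulin: %g", traj$frac_gdp_tubulin)
  )
  con <- file(path, "w")
  writeLines(meta, con)
  utils::write.csv(data.frame(time_s = traj$times,
                              mean_length_nm = traj$mean_length),
                   con, row.names = FALSE)
  close(con)
  if (!is.null(event_log_path)) {
    if (is.null(traj$event_log))
      stop("trajectory was run without an event log", call. = FALSE)
    utils::write.csv(traj$event_log, event_log_path, row.names = FALSE)
  }
  invisible(path)
}
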