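#' Kinetic parameter set
#'
#' Bimolecular on-rate constants per protofilament for each end, the
#' longitudinal-only and corner interaction affinities, the multiplicative
#' weakening of a GDP-governed longitudinal interface, the nucleotide
#' mechanism, and the terminal nucleotide-exchange kinetics.
#'
#' Dissociation rates follow `koff = kon * KD`, where the site KD is set by
#' the number and type of tubulin:tubulin contacts and by the governing
#' nucleotide (see [site_affinity()]). The bucket affinity (one longitudinal
#' plus two lateral contacts) is `KD_corner^2 / KD_long`, i.e. the second
#' lateral bond contributes the same free energy as the first.
#'
#' Defaults are the fitted GMPCPP parameter set: `kon_plus` 0.74 and
#' `kon_minus` 0.31 uM^-1 s^-1, `kd_long` 86 uM, `kd_corner` 0.025 uM and a
#' 3500-fold GDP weakening. With that weakening factor the GDP corner
#' affinity evaluates to 87.5 uM (tabulations elsewhere round it to 87) and
#' the GDP longitudinal affinity to 3.01e5 uM (rounded 3e5).
#'
#' @param kon_plus,kon_minus On-rate constants (uM^-1 s^-1 per protofilament).
#' @param kd_long Longitudinal-only affinity (uM).
#' @param kd_corner Corner affinity: one longitudinal + one lateral (uM).
#' @param gdp_factor Fold-weakening of a GDP-governed longitudinal interface
#'   (>= 1; dimensionless).
#' @param mechanism `"interface_acting"` (trans) or `"self_acting"` (cis).
#' @param k_exch_gdp Dissociation rate of GDP from a solvent-exposed terminal
#'   E-site (s^-1); 0 disables exchange.
#' @param affinity_ratio KD(GMPCPP)/KD(GDP) for nucleotide binding to
#'   unpolymerized tubulin; also the factor by which terminal GMPCPP leaves
#'   faster than terminal GDP.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()
#' kinetic_params(kon_plus = 1, kon_minus = 1, kd_long = 100,
#'                kd_corner = 0.1, gdp_factor = 3000)
#' @export
kinetic_params <- function(kon_plus = 0.74, kon_minus = 0.31,
                           kd_long = 86, kd_corner = 0.025,
                           gdp_factor = 3500,
                           mechanism = c("interface_acting", "self_acting"),
                           k_exch_gdp = 0, affinity_ratio = 12.5) {
  mechanism <- match.arg(mechanism)
  if (any(c(kon_plus, kon_minus, kd_long, kd_corner, affinity_ratio) <= 0))
    stop("rates and affinities must be strictly positive", call. = FALSE)
  if (gdp_factor < 1)
    stop("`gdp_factor` must be >= 1", call. = FALSE)
  if (kd_corner >= kd_long)
    stop("`kd_corner` must be smaller than `kd_long`", call. = FALSE)
  if (k_exch_gdp < 0)
    stop("`k_exch_gdp` must be >= 0", call. = FALSE)
  structure(
    list(kon_plus = kon_plus, kon_minus = kon_minus,
         kd_long = kd_long, kd_corner = kd_corner,
         gdp_factor = gdp_factor, mechanism = mechanism,
         k_exch_gdp = k_exch_gdp, affinity_ratio = affinity_ratio),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    paste0("kinetic parameters (%s):\n",
           "  kon+ %.3g, kon- %.3g uM^-1 s^-1\n",
           "  KD_long %.3g uM, KD_corner %.3g uM, GDP weakening x%g\n",
           "  k_exch(GDP) %.3g s^-1, nucleotide affinity ratio %.3g\n"),
    x$mechanism, x$kon_plus, x$kon_minus, x$kd_long, x$kd_corner,
    x$gdp_factor, x$k_exch_gdp, x$affinity_ratio))
  invisible(x)
}

kon_for_end <- function(params, end) {
  if (end == "plus") params$kon_plus else params$kon_minus
}

#' Solution composition
#'
#' Unpolymerized tubulin plus the nucleotide mixture it equilibrates with.
#' The solution is treated as an infinite reservoir: single microtubules do
#' not measurably deplete micromolar tubulin or millimolar nucleotide.
#'
#' Two constructors are provided: [solution_from_mix()] derives the
#' GDP-tubulin fraction from nucleotide concentrations through the
#' competitive binding model ([cpp_tubulin_concentration()]), and
#' [solution_from_fraction()] starts from a stated GDP-tubulin fraction and
#' back-computes the consistent nucleotide mixture (used when a simulation
#' condition is given directly as "percent GDP-tubulin").
#'
#' @param tubulin_total Total unpolymerized tubulin (uM).
#' @param cpp_conc,gdp_conc GMPCPP and GDP concentrations (uM).
#' @param frac_gdp_tubulin Fraction of tubulin that is GDP-bound (0..1).
#' @return An object of class `solution_state`.
#' @export
solution_state <- function(tubulin_total, cpp_conc, gdp_conc,
                           frac_gdp_tubulin) {
  if (tubulin_total < 0 || cpp_conc < 0 || gdp_conc < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (frac_gdp_tubulin < 0 || frac_gdp_tubulin > 1)
    stop("`frac_gdp_tubulin` must lie in [0, 1]", call. = FALSE)
  structure(
    list(tubulin_total = tubulin_total, cpp_conc = cpp_conc,
         gdp_conc = gdp_conc, frac_gdp_tubulin = frac_gdp_tubulin),
    class = "solution_state"
  )
}

#' @rdname solution_state
#' @param total_nucleotide Total nucleotide concentration (uM; 1000 in the
#'   mixed-nucleotide experimental design).
#' @param affinity_ratio KD(GMPCPP)/KD(GDP) used to partition tubulin between
#'   the two nucleotides.
#' @export
solution_from_mix <- function(tubulin_total, gdp_conc,
                              total_nucleotide = 1000,
                              affinity_ratio = 12.5) {
  if (gdp_conc < 0 || gdp_conc > total_nucleotide)
    stop("`gdp_conc` must lie in [0, total_nucleotide]", call. = FALSE)
  cpp_conc <- total_nucleotide - gdp_conc
  cpp_tub <- cpp_tubulin_concentration(tubulin_total,
                                       nucleotide_mix(gdp_conc, cpp_conc),
                                       affinity_ratio)
  frac <- if (tubulin_total > 0) 1 - cpp_tub / tubulin_total else 0
  solution_state(tubulin_total, cpp_conc, gdp_conc, frac)
}

#' @rdname solution_state
#' @export
solution_from_fraction <- function(tubulin_total, frac_gdp_tubulin,
                                   total_nucleotide = 1000,
                                   affinity_ratio = 12.5) {
  if (frac_gdp_tubulin < 0 || frac_gdp_tubulin > 1)
    stop("`frac_gdp_tubulin` must lie in [0, 1]", call. = FALSE)
  # invert f = r*gdp / (cpp + r*gdp) with cpp + gdp = total
  f <- frac_gdp_tubulin
  r <- affinity_ratio
  gdp <- f * total_nucleotide / (r * (1 - f) + f)
  solution_state(tubulin_total, total_nucleotide - gdp, gdp, f)
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf(
    "solution: %.3g uM tubulin (%.1f%% GDP-bound); %.4g uM GMPCPP / %.4g uM GDP\n",
    x$tubulin_total, 100 * x$frac_gdp_tubulin, x$cpp_conc, x$gdp_conc))
  invisible(x)
}

#' Which nucleotide governs a tubulin:lattice bond
#'
#' Under the interface-acting (trans) mechanism the nucleotide buried at the
#' longitudinal interface sets the bond strength; under the self-acting (cis)
#' mechanism the terminal subunit's own nucleotide does. At the minus-end the
#' terminal subunit's E-site *is* the interfacial nucleotide, so both inputs
#' coincide and the mechanisms become indistinguishable.
#'
#' @param mechanism `"interface_acting"` or `"self_acting"`.
#' @param end `"plus"` or `"minus"`.
#' @param self_nt,interfacial_nt `"CPP"` or `"GDP"` (vectorized).
#' @return The governing nucleotide(s).
#' @examples
#' governing_nucleotide("interface_acting", "plus", "GDP", "CPP")  # "CPP"
#' governing_nucleotide("self_acting", "plus", "GDP", "CPP")       # "GDP"
#' @export
governing_nucleotide <- function(mechanism, end, self_nt, interfacial_nt) {
  mechanism <- match.arg(mechanism, c("interface_acting", "self_acting"))
  end <- match.arg(end, c("plus", "minus"))
  if (end == "minus" && any(self_nt != interfacial_nt))
    stop("at the minus-end the self and interfacial nucleotides coincide",
         call. = FALSE)
  if (mechanism == "interface_acting") interfacial_nt else self_nt
}

#' Interaction affinity of a binding site
#'
#' Base affinities are `kd_long` (longitudinal contact only), `kd_corner`
#' (longitudinal + one lateral) and `kd_corner^2 / kd_long` (bucket:
#' longitudinal + two laterals, assuming the second lateral bond adds the
#' same binding energy as the first). A GDP governing nucleotide weakens the
#' longitudinal interface by `gdp_factor`; since the weakening acts on the
#' longitudinal bond the lateral factors are unchanged, so the corner/long
#' affinity ratio is the same for both nucleotides.
#'
#' @param site_class `"long_only"`, `"corner"` or `"bucket"` (vectorized).
#' @param governing_nt `"CPP"` or `"GDP"` (vectorized).
#' @param params A [kinetic_params()] object.
#' @return KD in uM.
#' @examples
#' p <- kinetic_params()
#' site_affinity("long_only", "CPP", p)   # 86
#' site_affinity("corner", "GDP", p)      # 87.5
#' @export
site_affinity <- function(site_class, governing_nt, params) {
  stopifnot(inherits(params, "kinetic_params"))
  base <- c(long_only = params$kd_long,
            corner = params$kd_corner,
            bucket = params$kd_corner^2 / params$kd_long)
  if (!all(site_class %in% names(base)))
    stop("unknown site class", call. = FALSE)
  if (!all(governing_nt %in% c("CPP", "GDP")))
    stop("unknown nucleotide", call. = FALSE)
  kd <- unname(base[site_class])
  kd * ifelse(governing_nt == "GDP", params$gdp_factor, 1)
}

# f^w evaluated in half-bond steps (w a multiple of 0.5), so the compiled
# engine reproduces the same double-precision product bitwise
lateral_kd_factor <- function(f, w) {
  m <- as.integer(round(2 * w))
  out <- 1
  if (m >= 2) for (i in seq_len(m %/% 2)) out <- out * f
  if (m %% 2 == 1L) out <- out * sqrt(f)
  out
}

# Continuous-weight generalization of site_affinity: KD = KD_long * f^w with
# f = KD_corner/KD_long, times the GDP weakening when governed by GDP.
# Reduces to site_affinity at integer weights 0/1/2.
affinity_from_weight <- function(weight, governing_nt, params) {
  f <- params$kd_corner / params$kd_long
  kd <- params$kd_long *
    vapply(weight, function(w) lateral_kd_factor(f, w), numeric(1))
  kd * ifelse(governing_nt == "GDP", params$gdp_factor, 1)
}

#' First-order association rate onto one protofilament tip
#'
#' `kon * [tubulin]`, with the same on-rate constant for GDP- and
#' GMPCPP-tubulin; when `nt` is given, only the tubulin carrying that
#' nucleotide counts, so the total landing rate partitions by the solution's
#' GDP-tubulin fraction.
#'
#' @param params A [kinetic_params()] object.
#' @param end `"plus"` or `"minus"`.
#' @param solution A [solution_state()].
#' @param nt Optional `"CPP"` or `"GDP"` to select one tubulin species.
#' @return Rate in s^-1 per protofilament.
#' @export
association_rate <- function(params, end, solution, nt = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(solution, "solution_state"))
  end <- match.arg(end, c("plus", "minus"))
  conc <- solution$tubulin_total
  if (!is.null(nt)) {
    if (!nt %in% c("CPP", "GDP")) stop("unknown nucleotide", call. = FALSE)
    frac <- if (nt == "GDP") solution$frac_gdp_tubulin else
      1 - solution$frac_gdp_tubulin
    conc <- conc * frac
  }
  kon_for_end(params, end) * conc
}

#' Dissociation rate of a terminal subunit
#'
#' `koff = kon * KD`, with the site KD evaluated at the nucleotide selected
#' by the mechanism ([governing_nucleotide()]). When the tip entry carries a
#' `lateral_weight` (from [tip_sites()]) the KD uses the continuous bond
#' weight `KD_long * (KD_corner/KD_long)^w`, which handles the fractional
#' seam bonds; otherwise the discrete `site_class` is used via
#' [site_affinity()].
#'
#' @param tip_entry One row of [tip_sites()] (or a list with `site_class`,
#'   `self_nt`, `interfacial_nt`, optionally `lateral_weight`).
#' @param params A [kinetic_params()] object.
#' @param end `"plus"` or `"minus"`.
#' @return Rate in s^-1.
#' @examples
#' p <- kinetic_params()
#' tip <- list(site_class = "corner", self_nt = "CPP", interfacial_nt = "CPP")
#' dissociation_rate(tip, p, "plus")  # 0.74 * 0.025 = 0.0185
#' @export
dissociation_rate <- function(tip_entry, params, end) {
  end <- match.arg(end, c("plus", "minus"))
  nt <- governing_nucleotide(params$mechanism, end,
                             tip_entry$self_nt, tip_entry$interfacial_nt)
  kd <- if (!is.null(tip_entry$lateral_weight)) {
    affinity_from_weight(tip_entry$lateral_weight, nt, params)
  } else {
    site_affinity(tip_entry$site_class, nt, params)
  }
  kon_for_end(params, end) * kd
}

#' Terminal nucleotide exchange channels
#'
#' At the plus-end the terminal subunit's E-site nucleotide is solvent
#' exposed and can exchange; the rate-limiting step is dissociation of the
#' bound nucleotide, so the total rate is `k_exch_gdp` for a bound GDP and
#' `affinity_ratio * k_exch_gdp` for a bound GMPCPP (the weaker-bound analog
#' leaves proportionally faster). On firing, the replacement nucleotide is
#' drawn from the solution's fractional nucleotide concentrations. At the
#' minus-end the terminal E-site is buried and no exchange occurs.
#'
#' @inheritParams dissociation_rate
#' @param solution A [solution_state()].
#' @return A data frame with columns `replacement_nt` and `rate` (s^-1);
#'   zero rows at the minus-end or when exchange is disabled.
#' @export
exchange_events <- function(tip_entry, params, solution, end) {
  end <- match.arg(end, c("plus", "minus"))
  empty <- data.frame(replacement_nt = character(0), rate = numeric(0),
                      stringsAsFactors = FALSE)
  if (end == "minus" || params$k_exch_gdp <= 0) return(empty)
  total <- if (tip_entry$self_nt == "GDP") params$k_exch_gdp
           else params$affinity_ratio * params$k_exch_gdp
  nuc_total <- solution$cpp_conc + solution$gdp_conc
  if (nuc_total <= 0)
    stop("exchange requires nucleotide in solution", call. = FALSE)
  p_cpp <- solution$cpp_conc / nuc_total
  data.frame(replacement_nt = c("CPP", "GDP"),
             rate = total * c(p_cpp, 1 - p_cpp),
             stringsAsFactors = FALSE)
}
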