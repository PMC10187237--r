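#' Nucleotide mixture
#'
#' A GDP/GMPCPP mixture at fixed total nucleotide (1000 uM in the
#' mixed-nucleotide experimental design).
#'
#' @param gdp_conc GDP concentration (uM).
#' @param cpp_conc GMPCPP concentration (uM); default `total - gdp_conc`.
#' @param total Total nucleotide (uM).
#' @return An object of class `nucleotide_mix`.
#' @export
nucleotide_mix <- function(gdp_conc, cpp_conc = NULL, total = 1000) {
  if (is.null(cpp_conc)) cpp_conc <- total - gdp_conc
  if (gdp_conc < 0 || cpp_conc < 0)
    stop("nucleotide concentrations must be >= 0", call. = FALSE)
  if (abs(gdp_conc + cpp_conc - total) > 1e-9 * max(total, 1))
    stop("gdp_conc + cpp_conc must equal the stated total", call. = FALSE)
  structure(list(gdp_conc = gdp_conc, cpp_conc = cpp_conc, total = total),
            class = "nucleotide_mix")
}

#' GMPCPP-tubulin concentration under competitive nucleotide binding
#'
#' GDP and GMPCPP compete for the tubulin E-site like competitive inhibitors
#' of an enzyme. With GMPCPP far above its own KD the bound fraction
#' simplifies to
#' `[tubulin_CPP] = [tubulin_total] * [CPP] / ([CPP] + [GDP] * ratio)`,
#' where `ratio = KD_CPP / KD_GDP`. Supplying both absolute KDs evaluates
#' the exact competitive form instead.
#'
#' @param tub_total Total unpolymerized tubulin (uM).
#' @param mix A [nucleotide_mix()].
#' @param affinity_ratio KD(GMPCPP)/KD(GDP).
#' @param kd_cpp,kd_gdp Optional absolute KDs (uM) for the exact form.
#' @return GMPCPP-tubulin concentration (uM).
#' @examples
#' cpp_tubulin_concentration(1.25, nucleotide_mix(25), 12.5)  # 0.9466
#' @export
cpp_tubulin_concentration <- function(tub_total, mix, affinity_ratio = 12.5,
                                      kd_cpp = NULL, kd_gdp = NULL) {
  stopifnot(inherits(mix, "nucleotide_mix"))
  if (affinity_ratio <= 0)
    stop("`affinity_ratio` must be > 0", call. = FALSE)
  if (mix$cpp_conc == 0 && mix$gdp_conc == 0)
    stop("no nucleotide in the mixture", call. = FALSE)
  if (!is.null(kd_cpp) && !is.null(kd_gdp)) {
    return(tub_total * mix$cpp_conc /
             (mix$cpp_conc + kd_cpp * (1 + mix$gdp_conc / kd_gdp)))
  }
  tub_total * mix$cpp_conc /
    (mix$cpp_conc + mix$gdp_conc * affinity_ratio)
}

#' Predicted minus-end growth rate in a nucleotide mixture
#'
#' Applies the all-GMPCPP minus-end growth law
#' `GR = slope * [tubulin_CPP] + intercept` (defaults 0.9 and -0.05 nm/s)
#' to the GMPCPP-tubulin concentration from the competitive binding model,
#' assuming only GMPCPP-tubulin contributes to minus-end growth. The affine
#' law can go negative at high GDP; the signed value is returned for fitting
#' and `clamp = TRUE` floors it at zero for display.
#'
#' @param tub_total Total tubulin (uM).
#' @param gdp_conc GDP concentration (uM), 0..total nucleotide.
#' @param affinity_ratio KD(GMPCPP)/KD(GDP).
#' @param slope,intercept All-GMPCPP growth-law coefficients (nm/s per uM,
#'   nm/s); replaceable by a fresh [concentration_series_fit()].
#' @param total_nucleotide Total nucleotide (uM).
#' @param clamp Floor negative predictions at zero (with a warning)?
#' @return Growth rate (nm/s).
#' @examples
#' minus_growth_prediction(1.25, 0)  # 1.075
#' @export
minus_growth_prediction <- function(tub_total, gdp_conc,
                                    affinity_ratio = 12.5,
                                    slope = 0.9, intercept = -0.05,
                                    total_nucleotide = 1000,
                                    clamp = FALSE) {
  if (any(gdp_conc < 0) || any(gdp_conc > total_nucleotide))
    stop("`gdp_conc` must lie in [0, total_nucleotide]", call. = FALSE)
  cpp <- total_nucleotide - gdp_conc
  tub_cpp <- ifelse(cpp + gdp_conc * affinity_ratio > 0,
                    tub_total * cpp / (cpp + gdp_conc * affinity_ratio), 0)
  gr <- slope * tub_cpp + intercept
  if (clamp && any(gr < 0)) {
    warning("negative predicted rate(s) clamped to zero")
    gr <- pmax(gr, 0)
  }
  gr
}

#' Fit the nucleotide affinity ratio to minus-end growth data
#'
#' SEM-weighted nonlinear least squares of the mixed-nucleotide minus-end
#' growth law with the affinity ratio KD(GMPCPP)/KD(GDP) as the single free
#' parameter (the growth-law slope and intercept are fixed inputs from the
#' all-GMPCPP fit).
#'
#' @param data Data frame with `gdp_uM` (or `x_uM`), `rate` (or `y`), and
#'   `sem` (> 0, used as inverse weights).
#' @param tub_total Total tubulin (uM).
#' @param slope,intercept Fixed growth-law coefficients.
#' @param total_nucleotide Total nucleotide (uM).
#' @param start Starting value for the ratio.
#' @return List with `affinity_ratio`, `se`, `ci95`, and the `nls` fit.
#' @export
fit_affinity_ratio <- function(data, tub_total, slope = 0.9,
                               intercept = -0.05, total_nucleotide = 1000,
                               start = 5) {
  gdp <- data$gdp_uM
  if (is.null(gdp)) gdp <- data$x_uM
  y <- data$rate
  if (is.null(y)) y <- data$y
  sem <- data$sem
  if (length(gdp) < 3L)
    stop("need at least 3 GDP concentrations", call. = FALSE)
  if (is.null(sem)) sem <- rep(1, length(gdp))
  if (any(sem <= 0)) stop("SEM weights must be > 0", call. = FALSE)
  df <- data.frame(gdp = gdp, y = y, w = 1 / sem^2)
  fit <- minpack.lm::nlsLM(
    y ~ minus_growth_prediction(tub_total, gdp, ratio, slope, intercept,
                                total_nucleotide),
    data = df, start = list(ratio = start), weights = df$w,
    lower = 1e-3, upper = 1e4,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)[["ratio"]]
  se <- summary(fit)$coefficients["ratio", "Std. Error"]
  list(affinity_ratio = est, se = se,
       ci95 = est + c(-1, 1) * stats::qt(0.975, stats::df.residual(fit)) * se,
       fit = fit)
}

#' Fluorescence-quenching binding isotherm
#'
#' Tryptophan fluorescence falls as 6-Thio-GTP binds:
#' `y = B - A * L / (L + KD)`, where `B` is the unquenched baseline, `A` the
#' quench amplitude and `KD` the 6-Thio-GTP affinity.
#'
#' @param ligand 6-Thio-GTP concentration(s) (uM).
#' @param amp_A,base_B,kd_6t Isotherm parameters (`amp_A <= base_B`).
#' @return Predicted signal(s).
#' @export
quench_isotherm <- function(ligand, amp_A, base_B, kd_6t) {
  if (any(ligand < 0)) stop("`ligand` must be >= 0", call. = FALSE)
  if (kd_6t <= 0) stop("`kd_6t` must be > 0", call. = FALSE)
  if (amp_A > base_B) stop("`amp_A` must not exceed `base_B`", call. = FALSE)
  base_B - amp_A * ligand / (ligand + kd_6t)
}

#' Fit the quenching isotherm
#'
#' SEM-weighted nonlinear least squares for (A, B, KD).
#'
#' @param data Data frame with `x_uM` (ligand), `y` (signal), optional `sem`.
#' @param start Optional named list of starting values.
#' @return List with `amp_A`, `base_B`, `kd_6t`, standard errors, and the
#'   `nls` fit.
#' @export
fit_isotherm <- function(data, start = NULL) {
  if (nrow(data) < 4L)
    stop("need more points than parameters (3)", call. = FALSE)
  sem <- data$sem
  if (is.null(sem)) sem <- rep(1, nrow(data))
  if (any(sem <= 0)) stop("SEM weights must be > 0", call. = FALSE)
  if (is.null(start)) {
    b0 <- max(data$y)
    a0 <- max(b0 - min(data$y), 1e-3)
    start <- list(A = a0, B = b0, KD = stats::median(data$x_uM))
  }
  df <- data.frame(x = data$x_uM, y = data$y, w = 1 / sem^2)
  fit <- minpack.lm::nlsLM(
    y ~ B - A * x / (x + KD), data = df, start = start, weights = df$w,
    lower = c(0, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  list(amp_A = cf["A", "Estimate"], base_B = cf["B", "Estimate"],
       kd_6t = cf["KD", "Estimate"],
       se = stats::setNames(cf[, "Std. Error"], rownames(cf)), fit = fit)
}

#' Competition (unquenching) model
#'
#' An unlabeled nucleotide competes 6-Thio-GTP off tubulin, restoring
#' fluorescence:
#' `y = C + A * N / (N + KD_nuc * (1 + S / KD_6T))`, with `S` the fixed
#' 6-Thio-GTP concentration, `C` the fully quenched baseline, and `A` the
#' amplitude constrained from the isotherm measurement.
#'
#' @param nuc Competitor concentration(s) (uM).
#' @param six_thio 6-Thio-GTP concentration (uM; 3 in the assay design).
#' @param amp_A Amplitude (fixed, externally constrained).
#' @param floor_C Quenched baseline.
#' @param kd_nuc Competitor affinity (uM).
#' @param kd_6t 6-Thio-GTP affinity (uM; fixed from the isotherm fit).
#' @return Predicted signal(s).
#' @export
competition_model <- function(nuc, six_thio, amp_A, floor_C, kd_nuc, kd_6t) {
  if (any(nuc < 0)) stop("`nuc` must be >= 0", call. = FALSE)
  if (kd_nuc <= 0 || kd_6t <= 0) stop("KDs must be > 0", call. = FALSE)
  floor_C + amp_A * nuc / (nuc + kd_nuc * (1 + six_thio / kd_6t))
}

#' Fit the competition model
#'
#' SEM-weighted fit for the competitor affinity `KD_nuc` and the quenched
#' baseline `C`, with the amplitude `A` and the 6-Thio-GTP affinity fixed
#' (they are constrained by the isotherm experiment, not refit here).
#'
#' @param data Data frame with `x_uM` (competitor), `y`, optional `sem`.
#' @param amp_A Fixed amplitude (required).
#' @param kd_6t Fixed 6-Thio-GTP KD (uM; required).
#' @param six_thio Fixed 6-Thio-GTP concentration (uM).
#' @param start Optional named list (`KDn`, `C`).
#' @return List with `kd_nuc`, `floor_C`, standard errors, and the fit.
#' @export
fit_competition <- function(data, amp_A, kd_6t, six_thio = 3, start = NULL) {
  if (missing(amp_A) || is.null(amp_A))
    stop("`amp_A` must be supplied (constrained externally)", call. = FALSE)
  if (missing(kd_6t) || is.null(kd_6t))
    stop("`kd_6t` must be supplied (from the isotherm fit)", call. = FALSE)
  if (nrow(data) < 3L)
    stop("need more points than parameters (2)", call. = FALSE)
  sem <- data$sem
  if (is.null(sem)) sem <- rep(1, nrow(data))
  if (any(sem <= 0)) stop("SEM weights must be > 0", call. = FALSE)
  if (is.null(start))
    start <- list(KDn = stats::median(data$x_uM[data$x_uM > 0]),
                  C = min(data$y))
  df <- data.frame(x = data$x_uM, y = data$y, w = 1 / sem^2)
  fit <- minpack.lm::nlsLM(
    y ~ C + amp_A * x / (x + KDn * (1 + six_thio / kd_6t)),
    data = df, start = start, weights = df$w,
    lower = c(1e-9, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  list(kd_nuc = cf["KDn", "Estimate"], floor_C = cf["C", "Estimate"],
       se = stats::setNames(cf[, "Std. Error"], rownames(cf)), fit = fit)
}

#' Propagate SEMs of the inner-filter-corrected fluorescence ratio
#'
#' The tubulin signal is divided by a matched BSA signal (inner-filter
#' correction) after blank subtraction; the SEM of the corrected ratio
#' combines the relative errors:
#' `SEM = sqrt((SEM_BSA/BSA)^2 + (SEM_tub/tub)^2 + (SEM_blank/blank)^2) *
#' (tub/BSA)`.
#'
#' @param bsa_stats,tub_stats,blank_stats Numeric `c(mean, sem)` pairs.
#' @return SEM of the corrected ratio.
#' @examples
#' propagate_sem(c(100, 1), c(50, 1), c(10, 0.5))  # 0.02739
#' @export
propagate_sem <- function(bsa_stats, tub_stats, blank_stats) {
  stats_list <- list(bsa_stats, tub_stats, blank_stats)
  means <- vapply(stats_list, `[`, numeric(1), 1)
  sems <- vapply(stats_list, `[`, numeric(1), 2)
  if (any(means == 0)) stop("means must be nonzero", call. = FALSE)
  if (any(sems < 0)) stop("SEMs must be >= 0", call. = FALSE)
  sqrt(sum((sems / means)^2)) * (means[2] / means[1])
}
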