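#' Gas constant, J mol^-1 K^-1
#' @export
GAS_CONSTANT <- 8.314462618

#' Molarity of pure water at 298.15 K, mol dm^-3
#' @export
WATER_MOLARITY <- 55.345

#' Gibbs energy of micellisation for an ionic surfactant
#'
#' Charged-pseudophase model with counterion binding:
#' `dG_mic = (0.5 + beta) R T ln(X_cmc)`,
#' where `beta` is the degree of counterion binding and `X_cmc` the critical
#' micelle concentration expressed as a mole fraction.  Concentrations in
#' mol dm^-3 are converted by `X = C / (C + water_molarity)` with the water
#' molarity fixed at its 298.15 K value by default (configurable).
#'
#' @param cmc Critical micelle (or transition) concentration, mol dm^-3.
#' @param beta Counterion binding degree, in `[0, 1]`.
#' @param temperature Temperature, K.
#' @param water_molarity Molar concentration of water used in the mole
#'   fraction conversion, mol dm^-3.
#' @param x_cmc Optional mole fraction given directly (overrides `cmc`).
#' @return Gibbs energy, kJ mol^-1 (negative for spontaneous micellisation).
#' @export
gibbs_micellisation <- function(cmc, beta, temperature,
                                water_molarity = WATER_MOLARITY,
                                x_cmc = NULL) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.null(x_cmc)) {
    if (cmc <= 0) stop("cmc must be positive", call. = FALSE)
    x_cmc <- cmc / (cmc + water_molarity)
  }
  if (x_cmc > 1) stop("mole fraction above 1", call. = FALSE)
  (0.5 + beta) * GAS_CONSTANT * temperature * log(x_cmc) / 1000
}

#' Entropy of micellisation from the Gibbs-Helmholtz relation
#'
#' `T dS = dH - dG` exactly; `dS = 1000 * T dS / T` in J mol^-1 K^-1.
#'
#' @param dh Enthalpy of micellisation, kJ mol^-1.
#' @param dg Gibbs energy of micellisation, kJ mol^-1.
#' @param temperature Temperature, K.
#' @return Named list with `tds` (kJ mol^-1) and `ds` (J mol^-1 K^-1).
#' @export
entropy_micellisation <- function(dh, dg, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  tds <- dh - dg
  list(tds = tds, ds = 1000 * tds / temperature)
}

#' Back-solve the counterion binding degree from a Gibbs energy
#'
#' One-dimensional bisection of [gibbs_micellisation()] in `beta`, useful
#' when `dG` is tabulated but the conductometric `beta` is not.
#'
#' @param dg Gibbs energy, kJ mol^-1.
#' @param cmc Concentration, mol dm^-3.
#' @param temperature Temperature, K.
#' @param water_molarity See [gibbs_micellisation()].
#' @return `beta` in `[0, 1]`.
#' @export
solve_beta <- function(dg, cmc, temperature, water_molarity = WATER_MOLARITY) {
  f <- function(b) gibbs_micellisation(cmc, b, temperature, water_molarity) - dg
  uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Micellisation thermodynamics from a fitted enthalpogram
#'
#' Combines the inflection concentration(s), the baseline enthalpy
#' difference(s), the Gibbs energy with counterion binding and the
#' Gibbs-Helmholtz entropy into a tidy table with one row per process
#' (micellisation; plus the shape transformation for double-sigmoid fits,
#' which uses `C_trans` in place of the c.m.c in the same relations).
#'
#' @param fit An `itc_fit` from [fit_enthalpogram()].
#' @param beta Counterion binding degree at this temperature.
#' @param temperature Temperature, K (defaults to the curve's).
#' @param water_molarity See [gibbs_micellisation()].
#' @return Tibble with columns `process`, `temperature`, `concentration`,
#'   `beta`, `x`, `dg`, `dh`, `tds`, `ds`.
#' @export
thermo_from_fit <- function(fit, beta, temperature = NULL,
                            water_molarity = WATER_MOLARITY) {
  if (is.null(temperature)) temperature <- attr(fit$curve, "temperature")
  if (is.null(temperature) || is.na(temperature))
    stop("temperature must be supplied", call. = FALSE)
  if (fit$steps == 1) {
    conc <- cmc_from_second_derivative(fit$params)
    dh <- micellisation_enthalpy(fit$params, at = conc)
    process <- "micellisation"
  } else {
    conc <- double_inflections(fit$params)
    dh <- micellisation_enthalpy(fit$params, at = conc)
    process <- c("micellisation", "transition")
  }
  dg <- vapply(conc, gibbs_micellisation, numeric(1), beta = beta,
               temperature = temperature, water_molarity = water_molarity)
  ent <- entropy_micellisation(dh, dg, temperature)
  tibble::tibble(process = process, temperature = temperature,
                 concentration = as.numeric(conc), beta = beta,
                 x = conc / (conc + water_molarity),
                 dg = dg, dh = as.numeric(dh), tds = ent$tds, ds = ent$ds)
}
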