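#' Radius of the sphere with the same volume
#'
#' `R = (3 V / (4 pi))^(1/3)`.
#'
#' @param volume Micelle volume, cubic Angstrom.
#' @return Radius, Angstrom.
#' @export
equal_volume_radius <- function(volume) {
  stopifnot(all(volume > 0))
  (3 * volume / (4 * pi))^(1 / 3)
}

# IUPAC 2021 standard atomic weights
ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, Br = 79.904)
AVOGADRO <- 6.02214076e23

#' Molecular formula of an 8-s-8 gemini dication
#'
#' Alkanediyl-alpha,omega-bis(dimethyloctylammonium): two octyl tails, four
#' N-methyls and an s-carbon spacer on two quaternary nitrogens, giving
#' `C(20+s) H(46+2s) N2` for the dication.  Bromide counterions are excluded
#' from the mass by default (the convention under which published micelle
#' densities are reproduced); set `counterions = TRUE` to include two Br.
#'
#' @param spacer Spacer carbon count `s >= 2`.
#' @param counterions Include the two bromides in the mass.
#' @return List with `c`, `h`, `n`, `br` element counts and `mass`
#'   (g mol^-1).
#' @export
gemini_formula <- function(spacer, counterions = FALSE) {
  stopifnot(spacer >= 2)
  nc <- 20 + spacer
  nh <- 46 + 2 * spacer
  nbr <- if (counterions) 2L else 0L
  mass <- nc * ATOMIC_MASS[["C"]] + nh * ATOMIC_MASS[["H"]] +
    2 * ATOMIC_MASS[["N"]] + nbr * ATOMIC_MASS[["Br"]]
  list(c = nc, h = nh, n = 2L, br = nbr, mass = mass)
}

#' Micelle density from building-unit count, formula and volume
#'
#' `d = N M / (N_A V)` with `M` the molar mass of the building unit and `V`
#' in cubic Angstrom (converted internally to cm^3).
#'
#' @param n_units Number of building units in the micelle.
#' @param volume Micelle volume, cubic Angstrom.
#' @param spacer Spacer length used to build the formula (ignored when
#'   `formula` is given).
#' @param formula Optional [gemini_formula()] result.
#' @return Density, g cm^-3.
#' @export
micelle_density <- function(n_units, volume, spacer = NULL, formula = NULL) {
  stopifnot(n_units >= 1, volume > 0)
  if (is.null(formula)) {
    if (is.null(spacer)) stop("either spacer or formula is required", call. = FALSE)
    formula <- gemini_formula(spacer)
  }
  n_units * formula$mass / (AVOGADRO * volume * 1e-24)
}

#' Energetic gain of spacer elongation
#'
#' Least-squares slope of the single-molecule SCF energy against the spacer
#' carbon count, returned as the magnitude of the energy lowering per CH2
#' unit added to the spacer.
#'
#' @param spacer Spacer lengths (at least two distinct values).
#' @param e_scf SCF energies, in units of 1e-15 J per molecule.
#' @return Energy gain per CH2, same units as `e_scf`.
#' @export
spacer_energy_increment <- function(spacer, e_scf) {
  if (length(unique(spacer)) < 2)
    stop("at least two distinct spacer lengths are required", call. = FALSE)
  if (length(spacer) != length(e_scf)) stop("length mismatch", call. = FALSE)
  abs(unname(coef(lm(e_scf ~ spacer))[2]))
}

#' Consistency checks for a micelle descriptor table
#'
#' Verifies, for every column of a descriptor table in the layout of
#' [cosmo_micelle_descriptors()], that the reported equal-volume radius
#' matches `(3V/4pi)^(1/3)` and that the reported density matches
#' `N M / (N_A V)` under the dication-mass convention.
#'
#' @param table Descriptor tibble with columns `surfactant`, `spacer`,
#'   `n_units`, `volume`, `area`, `radius`, `density`, `rg`.
#' @param tol_radius Radius tolerance, Angstrom.
#' @param tol_density Density tolerance, g cm^-3.
#' @return The table with added `radius_calc`, `density_calc`, `radius_ok`,
#'   `density_ok` columns.
#' @export
check_descriptor_table <- function(table, tol_radius = 0.01, tol_density = 1e-3) {
  table$radius_calc <- equal_volume_radius(table$volume)
  table$density_calc <- mapply(micelle_density, table$n_units, table$volume,
                               table$spacer)
  table$radius_ok <- abs(table$radius_calc - table$radius) <= tol_radius
  table$density_ok <- abs(table$density_calc - table$density) <= tol_density
  table
}
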