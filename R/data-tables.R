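# Published reference tables for the 8-s-8 gemini surfactant series,
# consumed as inputs by the descriptor and thermodynamics checks.

#' COSMO micelle descriptors for 8-s-8 gemini surfactants
#'
#' Quantum-chemical (COSMO solvation) micelle descriptors for the
#' dimethyloctylammonium gemini series: assumed building-unit count `N`,
#' micelle volume `V` and surface area `A` (cubic/square Angstrom), the
#' equal-volume sphere radius `R`, the density `d` and the radius of
#' gyration `Rg` (Angstrom).  Seven micelle models cover the four
#' surfactants; volume, area and `Rg` are consumed as given, radius and
#' density are reproducible from `V`, `N` and the dication molar mass (see
#' [check_descriptor_table()]).
#'
#' @return Tibble with columns `surfactant`, `spacer`, `n_units`, `volume`,
#'   `area`, `radius`, `density`, `rg`.
#' @export
cosmo_micelle_descriptors <- function() {
  tibble::tibble(
    surfactant = c("8-6-8", "8-6-8", "8-7-8", "8-7-8", "8-8-8", "8-9-8", "8-9-8"),
    spacer     = c(6L, 6L, 7L, 7L, 8L, 9L, 9L),
    n_units    = c(6L, 9L, 6L, 8L, 8L, 7L, 13L),
    volume     = c(3724.9, 5720.9, 3860.0, 5205.0, 5409.8, 4807.8, 9133.3),
    area       = c(1502.5, 2152.9, 1559.7, 1895.4, 2020.2, 1807.7, 3103.6),
    radius     = c(9.62, 11.09, 9.73, 10.75, 10.89, 10.47, 12.97),
    density    = c(1.0666, 1.0417, 1.0655, 1.0535, 1.0481, 1.0658, 1.0419),
    rg         = c(7.47, 9.16, 7.71, 8.61, 8.72, 8.20, 10.52))
}

#' Micellisation thermodynamics of aqueous 8-8-8 (reference values)
#'
#' ITC-derived temperature dependence of the critical micelle concentration,
#' the transition concentration and the thermodynamic functions for aqueous
#' 8-8-8 gemini surfactant.  Rows with `process = "transition"` describe the
#' micelle shape-transformation step of bell-shaped enthalpograms (present
#' only in the transition temperature window).  Units: `temperature` K,
#' `concentration` mol dm^-3, `dg`, `dh`, `tds` kJ mol^-1, `ds`
#' J mol^-1 K^-1.
#'
#' @return Tibble with one row per process and temperature.
#' @export
gemini_888_thermo_reference <- function() {
  m <- function(T, c, dg, dh, tds, ds)
    tibble::tibble(process = "micellisation", temperature = T, concentration = c,
                   dg = dg, dh = dh, tds = tds, ds = ds)
  t <- function(T, c, dg, dh, tds, ds)
    tibble::tibble(process = "transition", temperature = T, concentration = c,
                   dg = dg, dh = dh, tds = tds, ds = ds)
  rbind(
    m(283.15, 0.092, -17.12, 5.66, 22.78, 80.45),
    m(288.15, 0.082, -17.57, 5.80, 23.37, 81.12),
    m(293.15, 0.077, -17.90, 4.52, 22.42, 76.45),
    m(298.15, 0.071, -18.27, 3.67, 21.94, 73.58),
    m(303.15, 0.065, -18.64, 3.29, 21.93, 72.33),
    m(308.15, 0.062, -18.90, 2.31, 21.20, 68.80),
    m(313.15, 0.063, -19.02, 1.39, 20.41, 65.17),
    m(318.15, 0.049, -19.83, 1.36, 21.19, 66.60),
    t(318.15, 0.116, -17.40, -2.10, 15.30, 48.09),
    m(323.15, 0.032, -21.15, 0.47, 21.62, 66.91),
    t(323.15, 0.088, -18.29, -2.16, 16.14, 49.95),
    m(328.15, 0.023, -22.22, 0.52, 22.74, 69.29),
    t(328.15, 0.113, -17.67, -2.82, 14.85, 45.25),
    m(333.15, 0.122, -17.56, -3.99, 13.57, 40.73),
    m(338.15, 0.130, -17.46, -4.10, 13.36, 39.52),
    m(343.15, 0.145, -17.24, -4.05, 13.19, 38.44))
}

#' Single-molecule SCF energies of the 8-s-8 conformers (reference values)
#'
#' B3LYP/def2-TZVP SCF energies of single surfactant molecules in implicit
#' aqueous solution, one value per spacer length (the gauche and trans
#' conformers are degenerate at the printed precision).  Units: 1e-15 J per
#' molecule.
#'
#' @return Tibble with `surfactant`, `spacer`, `e_scf`.
#' @export
scf_conformer_energies <- function() {
  tibble::tibble(
    surfactant = c("8-6-8", "8-7-8", "8-8-8", "8-9-8"),
    spacer = c(6L, 7L, 8L, 9L),
    e_scf = c(-4.95, -5.12, -5.29, -5.46))
}
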