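#' Face-centred cubic lattice specification
#'
#' The simulation lattice is the even-parity sublattice of an `L^3`
#' simple-cubic grid (sites with `x + y + z` even), which realizes an FCC
#' packing with coordination number 12 and bond length `a * sqrt(2)` under
#' periodic boundary conditions in all three directions.  The box holds
#' `L^3 / 2` lattice sites.
#'
#' @param L Even integer box edge, in lattice-constant units (`L >= 2`; with
#'   `L = 2` the four sites see some periodic images more than once and the
#'   12-fold neighbour multiplicity is retained).
#' @return An object of class `fcc_lattice`: a list with elements `L`,
#'   `n_sites`, and the 12 nearest-neighbour `offsets` (a 12 x 3 integer
#'   matrix of `(+-1, +-1, 0)`-type vectors).
#' @examples
#' sp <- fcc_lattice(6)
#' sp$n_sites  # 108
#' @export
fcc_lattice <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1 || is.na(L) || L < 2 || L %% 2 != 0)
    stop("L must be a single even integer >= 2", call. = FALSE)
  structure(
    list(L = L, n_sites = as.integer(L^3 / 2), offsets = fcc_offsets()),
    class = "fcc_lattice")
}

fcc_offsets <- function() {
  off <- rbind(
    c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
    c( 1, 0,  1), c( 1, 0, -1), c(-1, 0,  1), c(-1, 0, -1),
    c(0,  1,  1), c(0,  1, -1), c(0, -1,  1), c(0, -1, -1))
  storage.mode(off) <- "integer"
  off
}

#' Enumerate the sites of an FCC lattice box
#'
#' Mostly used by tests and small enumeration oracles; large boxes never need
#' the explicit site list.
#'
#' @param spec An [fcc_lattice()] object.
#' @return Integer matrix (`n_sites` x 3) of site coordinates.
#' @export
fcc_sites <- function(spec) {
  g <- as.matrix(expand.grid(x = 0:(spec$L - 1), y = 0:(spec$L - 1), z = 0:(spec$L - 1)))
  storage.mode(g) <- "integer"
  g[(g[, 1] + g[, 2] + g[, 3]) %% 2 == 0, , drop = FALSE]
}

#' Neighbour list of an FCC lattice box
#'
#' @param spec An [fcc_lattice()] object.
#' @return Integer matrix (`n_sites` x 12); entry `[i, k]` is the row index in
#'   [fcc_sites()] of the k-th periodic nearest neighbour of site `i`.  With
#'   periodic images a neighbour can appear more than once for very small `L`;
#'   the multiplicity is kept, matching the energy convention.
#' @export
fcc_neighbor_list <- function(spec) {
  sites <- fcc_sites(spec)
  L <- spec$L
  key <- function(m) (m[, 1] %% L) + L * ((m[, 2] %% L) + L * (m[, 3] %% L))
  lookup <- integer(L^3)
  lookup[key(sites) + 1L] <- seq_len(nrow(sites))
  off <- spec$offsets
  nb <- matrix(0L, nrow(sites), 12)
  for (k in 1:12)
    nb[, k] <- lookup[key(sweep_add(sites, off[k, ])) + 1L]
  nb
}

sweep_add <- function(m, v) {
  m[, 1] <- m[, 1] + v[1]; m[, 2] <- m[, 2] + v[2]; m[, 3] <- m[, 3] + v[3]
  m
}

#' Gemini pentablock chain topology
#'
#' A single gemini surfactant molecule is coarse-grained as an
#' A8-B2-A6-B2-A8 pentablock chain of `N = 26` monomers: A monomers are
#' hydrocarbon (tail and spacer) segments, B monomers are the two cationic
#' heads (two B monomers per head).
#'
#' @param blocks Integer vector of block lengths, alternating A/B starting
#'   with A.  Default `c(8, 2, 6, 2, 8)`.
#' @return List with `species` (integer vector, 1 = A, 2 = B), `N`, and the
#'   per-species counts.
#' @export
gemini_topology <- function(blocks = c(8L, 2L, 6L, 2L, 8L)) {
  blocks <- as.integer(blocks)
  if (any(blocks < 1)) stop("block lengths must be positive", call. = FALSE)
  species <- unlist(mapply(function(len, sp) rep(sp, len), blocks,
                           rep(c(1L, 2L), length.out = length(blocks)),
                           SIMPLIFY = FALSE))
  list(species = as.integer(species), N = length(species),
       n_A = sum(species == 1L), n_B = sum(species == 2L))
}

#' Number of chains at a nominal volume fraction
#'
#' The monomer budget is `phi * L^3 / 2` lattice sites; dividing by the chain
#' length `N` gives a fractional chain count.  The count is rounded to the
#' nearest tenth of a chain and then to the nearest integer (half to even),
#' the convention that reproduces the published configuration sizes for the
#' `L = 78`, `N = 26` system (182, 365, ..., 1825 chains for
#' `phi = 0.02 ... 0.2`).
#'
#' @param phi Copolymer volume fraction, `0 < phi <= 0.3`.
#' @param L Box edge.
#' @param N Chain length (monomers).
#' @return Integer chain count.
#' @export
chain_count <- function(phi, L = 78L, N = 26L) {
  stopifnot(phi > 0, phi <= 0.3)
  as.integer(round(round(phi * L^3 / 2 / N, 1)))
}

#' Place self-avoiding chains on the lattice
#'
#' Grows `chain_count(phi, L, N)` mutually avoiding nearest-neighbour walks
#' on the FCC lattice; all remaining sites are solvent.  Deterministic for a
#' fixed seed.
#'
#' @param L Even box edge.
#' @param phi Volume fraction of chain monomers.
#' @param seed Integer RNG seed.
#' @param topology Chain topology from [gemini_topology()].
#' @param n_chains Optional explicit chain count overriding `phi`.
#' @return A `lattice_state` object: list with `L`, `coords` (unwrapped
#'   integer monomer coordinates, one row per monomer, chains stored
#'   contiguously in bonded order), `species`, `chain_len`, `n_chains`, `phi`.
#' @export
place_chains <- function(L, phi, seed = 1L, topology = gemini_topology(),
                         n_chains = NULL) {
  spec <- fcc_lattice(L)
  if (is.null(n_chains)) n_chains <- chain_count(phi, L, topology$N)
  if (n_chains < 1) stop("no chains to place; increase phi", call. = FALSE)
  res <- cpp_place_chains(spec$L, as.integer(n_chains), topology$N, seed)
  new_lattice_state(spec$L, res$coords,
                    rep(topology$species, n_chains), topology$N,
                    phi = n_chains * topology$N / spec$n_sites)
}

new_lattice_state <- function(L, coords, species, chain_len, phi = NA_real_) {
  structure(
    list(L = as.integer(L), coords = coords, species = as.integer(species),
         chain_len = as.integer(chain_len),
         n_chains = as.integer(nrow(coords) / chain_len), phi = phi),
    class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("FCC lattice state: L = %d (%d sites), %d chains x %d monomers (phi = %.4f)\n",
              x$L, x$L^3 / 2, x$n_chains, x$chain_len, x$phi))
  invisible(x)
}

#' Total reduced interaction energy of a lattice state
#'
#' Counts every A-B and A-S nearest-neighbour contact once (all other pairs
#' are athermal), giving the configurational energy in units of the contact
#' energy `eps = chi * k * T / (z - 2)`.  Pairs bonded within a chain are
#' included.
#'
#' @param state A `lattice_state`.
#' @return Non-negative reduced energy `E*`.
#' @export
total_reduced_energy <- function(state) {
  cpp_total_energy(state$L, state$coords, state$species)
}

#' Validate the hard constraints of a lattice state
#'
#' Checks that successive monomers of every chain are FCC nearest neighbours
#' (bond length exactly `a * sqrt(2)`), that all monomers sit on even-parity
#' sites and that no two monomers share a site.
#'
#' @param state A `lattice_state`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_state <- function(state) {
  co <- state$coords
  if (any((co[, 1] + co[, 2] + co[, 3]) %% 2 != 0))
    stop("monomer on odd-parity site", call. = FALSE)
  wrapped <- (co[, 1] %% state$L) + state$L * ((co[, 2] %% state$L) + state$L * (co[, 3] %% state$L))
  if (anyDuplicated(wrapped)) stop("site collision", call. = FALSE)
  idx <- seq_len(nrow(co))
  within <- (idx - 1L) %% state$chain_len
  bonded <- which(within < state$chain_len - 1L)
  d <- co[bonded + 1L, , drop = FALSE] - co[bonded, , drop = FALSE]
  if (any(rowSums(d^2) != 2)) stop("stretched or broken bond", call. = FALSE)
  invisible(TRUE)
}
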