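#' Run plain Metropolis sweeps at one temperature
#'
#' One Monte Carlo step (MCS) attempts to move every monomer once, in random
#' order, with the simple-motion move set: a monomer exchanges with a solvent
#' site among its 12 nearest neighbours, provided every bond to its chain
#' neighbours stays at length `a * sqrt(2)`.  Moves are accepted with the
#' Metropolis probability `min(1, exp(-dE*/T*))`; `tstar = Inf` gives the
#' athermal limit in which every geometrically valid move is accepted.
#'
#' @param state A `lattice_state`.
#' @param tstar Reduced temperature `T* = kT / eps` (may be `Inf`).
#' @param n_sweeps Number of MCS.
#' @param seed Integer RNG seed (deterministic replay).
#' @param sample_stride Record the reduced energy every this many MCS
#'   (0 disables recording).
#' @param check_every Recount the energy from scratch every this many MCS and
#'   stop on any bookkeeping drift (testing aid; 0 disables).
#' @return List with the updated `state`, the sampled `energy_series`, final
#'   `energy`, an independent `energy_recount`, the move `acceptance` rate
#'   over all proposals and `acceptance_valid` over geometrically valid
#'   proposals only (the latter is 1 in the athermal limit).
#' @export
mc_sweeps <- function(state, tstar, n_sweeps, seed = 1L, sample_stride = 0L,
                      check_every = 0L) {
  stopifnot(tstar > 0, n_sweeps >= 0)
  res <- cpp_run_mc(state$L, state$coords, state$species, state$chain_len,
                    tstar, as.integer(n_sweeps), seed,
                    as.integer(sample_stride), as.integer(check_every))
  state$coords <- res$coords
  list(state = state,
       energy = res$energy,
       energy_recount = res$energy_recount,
       energy_series = res$energy_series,
       acceptance = if (res$n_proposed > 0) res$n_accepted / res$n_proposed else NA_real_,
       acceptance_valid = if (res$n_valid > 0) res$n_accepted / res$n_valid else NA_real_)
}

#' Geometric ladder of reduced temperatures for parallel tempering
#'
#' @param t_min,t_max Ladder ends (reduced temperature).
#' @param n Number of replicas.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
pt_ladder <- function(t_min = 1.0, t_max = 5.0, n = 72L) {
  stopifnot(t_min > 0, t_max > t_min, n >= 2)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Parallel tempering sweeps over a replica ladder
#'
#' Runs every replica at its own reduced temperature and attempts
#' configuration swaps between adjacent temperatures every `swap_every` MCS,
#' alternating even and odd pairs, with acceptance
#' `min(1, exp((1/T*_i - 1/T*_j) (E*_i - E*_j)))`.
#'
#' @param states List of `lattice_state` objects (one per temperature, all
#'   sharing box, topology and chain count).
#' @param temps Strictly increasing reduced temperatures.
#' @param n_sweeps MCS to run.
#' @param swap_every Interval between swap attempts (MCS).
#' @param seed Integer seed; one independent stream per replica is derived.
#' @param sample_stride Energy sampling stride (0 disables).
#' @return List with updated `states`, final `energy` per replica, the
#'   `energy_series` matrix (samples x replicas) and per-pair
#'   `swap_acceptance` rates.
#' @export
pt_sweeps <- function(states, temps, n_sweeps, swap_every = 10L, seed = 1L,
                      sample_stride = 0L) {
  stopifnot(length(states) == length(temps), length(temps) >= 2,
            all(diff(temps) > 0))
  s1 <- states[[1]]
  res <- cpp_run_pt(s1$L, lapply(states, `[[`, "coords"), s1$species,
                    s1$chain_len, temps, as.integer(n_sweeps),
                    as.integer(swap_every), seed, as.integer(sample_stride))
  for (i in seq_along(states)) states[[i]]$coords <- res$coords[[i]]
  list(states = states, energy = res$energy, energy_series = res$energy_series,
       swap_acceptance = ifelse(res$swap_proposed > 0,
                                res$swap_accepted / res$swap_proposed, NA_real_))
}

#' Specific heat from energy fluctuations
#'
#' `C_V = (<E*^2> - <E*>^2) / (n_c * T*^2)`, the variance of the total
#' reduced energy per chain.  Uses the population variance of the sampled
#' series.
#'
#' @param energy Numeric series of total reduced energies.
#' @param tstar Reduced temperature.
#' @param n_chains Number of chains.
#' @return Non-negative specific heat per chain.
#' @export
specific_heat <- function(energy, tstar, n_chains) {
  stopifnot(length(energy) >= 2, tstar > 0, n_chains >= 1)
  m <- mean(energy)
  mean((energy - m)^2) / (n_chains * tstar^2)
}

#' Mean-squared radius of gyration per chain
#'
#' Computed from the unwrapped (periodic-image-consistent) monomer
#' coordinates about each chain's centroid, averaged over chains, in squared
#' lattice-constant units.
#'
#' @param state A `lattice_state`.
#' @return Scalar mean `R_g^2`.
#' @export
mean_sq_rg <- function(state) {
  co <- state$coords
  ch <- rep(seq_len(state$n_chains), each = state$chain_len)
  rg2 <- vapply(split(seq_len(nrow(co)), ch), function(idx) {
    p <- co[idx, , drop = FALSE]
    c0 <- colMeans(p)
    mean((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2 + (p[, 3] - c0[3])^2)
  }, numeric(1))
  mean(rg2)
}

#' Simulation schedule
#'
#' The production protocol equilibrates athermally, then thermally with
#' parallel tempering, then collects data with replica swapping switched off.
#' `preset = "paper"` uses the full protocol (3e6 + 3e6 + 2e6 MCS, 72
#' replicas); `preset = "desk"` is the scaled-down preset used throughout the
#' tests (1e5 + 1e5 + 1e5 MCS, 12 replicas).
#'
#' @param preset `"paper"` or `"desk"`.
#' @return List with `athermal`, `pt_equil`, `collect` MCS counts,
#'   `n_replicas`, `swap_every` and `sample_stride`.
#' @export
mc_schedule <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper")
    list(athermal = 3e6, pt_equil = 3e6, collect = 2e6, n_replicas = 72L,
         swap_every = 10L, sample_stride = 100L)
  else
    list(athermal = 1e5, pt_equil = 1e5, collect = 1e5, n_replicas = 12L,
         swap_every = 10L, sample_stride = 100L)
}

#' Full self-assembly protocol at one volume fraction
#'
#' Places chains, equilibrates each replica in the athermal limit, thermally
#' equilibrates the ladder with parallel tempering, then collects data at
#' each temperature with swapping disabled.  Fully reproducible for a fixed
#' seed.
#'
#' @param L Box edge.
#' @param phi Copolymer volume fraction.
#' @param temps Reduced-temperature ladder (increasing).
#' @param schedule Schedule list from [mc_schedule()] (or a compatible list).
#' @param seed Integer master seed.
#' @param classify Also run cluster analysis and phase classification on the
#'   final configuration of every temperature.
#' @param thresholds Classification thresholds, see [phase_thresholds()].
#' @return An object of class `mc_run`: list with `observables` (a tibble
#'   with one row per temperature: `tstar`, `e_per_chain`, `cv`, `rg2`, `na`,
#'   `phase`), the final `states`, the energy `series` matrix and run
#'   metadata.
#' @export
run_assembly <- function(L, phi, temps = pt_ladder(n = 12L),
                         schedule = mc_schedule("desk"), seed = 1L,
                         classify = TRUE, thresholds = phase_thresholds()) {
  if (any(diff(temps) <= 0)) stop("temperature ladder must increase", call. = FALSE)
  bad <- vapply(c("athermal", "pt_equil", "collect"),
                function(k) is.null(schedule[[k]]) || schedule[[k]] < 0, logical(1))
  if (any(bad)) stop("schedule must give athermal, pt_equil and collect MCS", call. = FALSE)

  n_rep <- length(temps)
  base <- place_chains(L, phi, seed = seed)
  states <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    st <- if (r == 1) base else place_chains(L, phi, seed = seed + 7919L * r)
    if (schedule$athermal > 0)
      st <- mc_sweeps(st, Inf, schedule$athermal, seed = seed + 104729L * r)$state
    states[[r]] <- st
  }
  if (schedule$pt_equil > 0)
    states <- pt_sweeps(states, temps, schedule$pt_equil,
                        swap_every = schedule$swap_every,
                        seed = seed + 15485863L)$states

  n_chains <- base$n_chains
  series <- NULL
  obs <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    res <- mc_sweeps(states[[r]], temps[r], schedule$collect,
                     seed = seed + 32452843L + r,
                     sample_stride = schedule$sample_stride)
    states[[r]] <- res$state
    e <- if (length(res$energy_series) > 0) res$energy_series else res$energy
    if (is.null(series)) series <- matrix(NA_real_, length(e), n_rep)
    series[seq_along(e), r] <- e
    cl <- find_clusters(states[[r]])
    phase <- if (classify) classify_phase(states[[r]], clusters = cl,
                                          thresholds = thresholds)$label
             else NA_character_
    obs[[r]] <- tibble::tibble(
      tstar = temps[r],
      e_per_chain = mean(e) / n_chains,
      cv = if (length(e) >= 2) specific_heat(e, temps[r], n_chains) else 0,
      rg2 = mean_sq_rg(states[[r]]),
      na = cl$n_a,
      phase = phase)
  }
  structure(list(observables = do.call(rbind, obs), states = states,
                 series = series, temps = temps, phi = base$phi, L = L,
                 n_chains = n_chains, schedule = schedule, seed = seed),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("Lattice MC run: L = %d, phi = %.4f, %d chains, %d temperatures\n",
              x$L, x$phi, x$n_chains, length(x$temps)))
  print(x$observables)
  invisible(x)
}

#' Export a configuration as extended XYZ text
#'
#' Species labels A/B with the chain index as a fourth column; suitable for
#' visualisation tools that read extended XYZ.
#'
#' @param state A `lattice_state`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(state, file) {
  co <- state$coords
  lab <- c("A", "B")[state$species]
  chain <- rep(seq_len(state$n_chains), each = state$chain_len)
  lines <- c(sprintf("%d", nrow(co)),
             sprintf("Lattice state L=%d phi=%.4f", state$L, state$phi),
             sprintf("%s %d %d %d %d", lab, co[, 1], co[, 2], co[, 3], chain))
  writeLines(lines, file)
  invisible(file)
}
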