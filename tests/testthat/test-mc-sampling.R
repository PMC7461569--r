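test_that("athermal limit accepts every geometrically valid move", {
  st <- place_chains(16, 0.06, seed = 3)
  r <- mc_sweeps(st, tstar = Inf, n_sweeps = 100, seed = 4)
  expect_equal(r$acceptance_valid, 1)
  expect_true(r$acceptance < 1)    # vacancy/bond rejections still occur
})

test_that("bond lengths stay a*sqrt(2) through any sweep sequence", {
  st <- place_chains(14, 0.1, seed = 8)
  for (tstar in c(0.8, 2, Inf)) {
    r <- mc_sweeps(st, tstar = tstar, n_sweeps = 200, seed = 9)
    expect_true(validate_state(r$state))
    st <- r$state
  }
})

test_that("runs with identical seeds are bit-identical", {
  st <- place_chains(14, 0.08, seed = 2)
  r1 <- mc_sweeps(st, 1.5, 300, seed = 42, sample_stride = 10)
  r2 <- mc_sweeps(st, 1.5, 300, seed = 42, sample_stride = 10)
  expect_identical(r1$energy_series, r2$energy_series)
  expect_identical(r1$state$coords, r2$state$coords)
  r3 <- mc_sweeps(st, 1.5, 300, seed = 43, sample_stride = 10)
  expect_false(identical(r1$energy_series, r3$energy_series))
})

test_that("tetramer sampling matches exact Boltzmann enumeration", {
  # all-A tetramer on the 4^3 box; exhaustive state enumeration oracle
  energies <- enumerate_tetramer()
  tstar <- 1
  w <- exp(-energies / tstar)
  exact <- tapply(w, energies, sum) / sum(w)
  co <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  st <- make_state(4L, co, rep(1L, 4), 4L)
  r <- mc_sweeps(st, tstar = tstar, n_sweeps = 1e6, seed = 20260923,
                 sample_stride = 250)
  emp <- as.numeric(table(factor(r$energy_series, levels = names(exact)))) /
    length(r$energy_series)
  # thinned samples retain some autocorrelation, so compare level
  # probabilities directly; the calibrated chi-square version runs on a
  # longer series in the acceptance suite
  expect_lt(max(abs(emp - as.numeric(exact))), 0.03)
  # every enumerated energy level is actually visited (ergodicity)
  expect_true(all(emp[as.numeric(exact) > 0.01] > 0))
})

test_that("parallel tempering leaves single-temperature marginals intact", {
  co <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  st <- make_state(4L, co, rep(1L, 4), 4L)
  temps <- c(1, 2.5)
  pt <- pt_sweeps(list(st, st), temps, n_sweeps = 2e5, swap_every = 5,
                  seed = 31, sample_stride = 100)
  expect_true(all(pt$swap_acceptance > 0))
  solo <- lapply(temps, function(tt)
    mc_sweeps(st, tt, 2e5, seed = 77, sample_stride = 100)$energy_series)
  for (i in seq_along(temps)) {
    m_pt <- mean(pt$energy_series[-(1:200), i])
    m_solo <- mean(solo[[i]][-(1:200)])
    se <- sd(solo[[i]]) / sqrt(length(solo[[i]]) / 30)   # generous ESS margin
    expect_lt(abs(m_pt - m_solo), 5 * se,
              label = sprintf("replica %d mean energy", i))
  }
})

test_that("favourable replica swaps are always accepted", {
  # identical configurations have equal energies: the very first swap attempt
  # has acceptance exp(0) = 1, so with zero intervening sweeps the states swap
  co <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  st <- make_state(4L, co, rep(1L, 4), 4L)
  pt <- pt_sweeps(list(st, st), c(1, 2), n_sweeps = 30, swap_every = 1,
                  seed = 5, sample_stride = 1)
  expect_gt(pt$swap_acceptance[1], 0.5)
})
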