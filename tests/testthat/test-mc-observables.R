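test_that("specific heat follows the fluctuation formula", {
  expect_equal(specific_heat(rep(7, 50), tstar = 2, n_chains = 3), 0)
  # series {0, 2}: population variance 1
  expect_equal(specific_heat(c(0, 2), tstar = 1, n_chains = 1), 1)
  expect_equal(specific_heat(c(0, 2), tstar = 2, n_chains = 5), 1 / 20)
  expect_error(specific_heat(3, 1, 1))
})

test_that("radius of gyration uses unwrapped coordinates", {
  # hand-placed 4-monomer chain: Rg^2 computed by direct arithmetic
  co <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(2, 1, 1))
  st <- make_state(10L, co, rep(1L, 4), 4L)
  ctr <- colMeans(co)
  byhand <- mean(rowSums(sweep(co, 2, ctr)^2))
  expect_equal(mean_sq_rg(st), byhand)
  # translation invariance, including across the periodic boundary
  st_shift <- make_state(10L, co + matrix(rep(c(9, 9, 8), each = 4), 4), rep(1L, 4), 4L)
  expect_equal(mean_sq_rg(st_shift), byhand)
  # degenerate case: all monomers at the same point has zero Rg^2
  st0 <- make_state(10L, matrix(rep(c(0L, 0L, 0L), 1), 1), 1L, 1L)
  expect_equal(mean_sq_rg(st0), 0)
})

test_that("cluster decomposition matches a brute-force contact check", {
  # two chains in contact plus one isolated: components {2, 1}, Na = 1.5
  c1 <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  c2 <- rbind(c(1, -1, 0), c(2, -2, 0), c(3, -1, 0))  # first monomer touches c1
  c3 <- rbind(c(10, 10, 10), c(11, 11, 10), c(12, 10, 10))
  st <- make_state(22L, rbind(c1, c2, c3), rep(1L, 9), 3L)
  cl <- find_clusters(st)
  expect_equal(sort(cl$sizes), c(1L, 2L))
  expect_equal(cl$n_a, 1.5)
  expect_equal(cl$n_a_weight, (4 + 1) / 3)
  # partitions equal the transitive-closure oracle on random states
  for (seed in c(5, 11)) {
    r <- mc_sweeps(place_chains(10, 0.1, seed = seed), 1.5, 300, seed = seed + 1)
    a <- find_clusters(r$state)$membership
    b <- brute_clusters(r$state)
    canon <- function(m) unname(split(seq_along(m), m)[order(vapply(split(seq_along(m), m), min, 1))])
    expect_equal(canon(a), canon(b), label = sprintf("partition seed %d", seed))
  }
  # head-head contacts do not aggregate chains
  h1 <- rbind(c(0, 0, 0), c(1, 1, 0))
  h2 <- rbind(c(1, -1, 0), c(2, 0, 0))
  sth <- make_state(12L, rbind(h1, h2), c(1L, 2L, 2L, 1L), 2L)
  expect_equal(find_clusters(sth)$n_clusters, 2L)
})

test_that("constructed morphologies are classified as intended", {
  # compact isotropic blobs -> micellar
  bs <- blob_state()
  mb <- cluster_metrics(bs)
  expect_true(all(mb$asphericity < 0.4))
  expect_true(all(mb$n_perc_axes == 0))
  expect_equal(classify_phase(bs)$label, "M")
  # torus-spanning straight filament -> cylindrical
  fs <- filament_state()
  mf <- cluster_metrics(fs)
  expect_true(mf$perc_x)
  expect_lt(mf$branch_points, 2)
  expect_equal(classify_phase(fs)$label, "C")
  # branched network percolating in two directions -> channels
  ns <- network_state()
  mn <- cluster_metrics(ns)
  expect_equal(mn$n_perc_axes, 2)
  expect_gte(mn$branch_points, 2)
  expect_equal(classify_phase(ns)$label, "CH")
  # no clusters at all -> disordered
  expect_equal(classify_phase(metrics = tibble::tibble())$label, "disordered")
})

test_that("phase labels are deterministic functions of the configuration", {
  st <- mc_sweeps(place_chains(14, 0.08, seed = 3), 1.3, 500, seed = 4)$state
  expect_identical(classify_phase(st)$label, classify_phase(st)$label)
})
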