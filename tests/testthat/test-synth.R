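test_that("ITC generator is exact at zero noise and seed-deterministic", {
  p <- c(h_ia = 5, h_ib = 0, h_fa = 1, h_fb = 0, cmc = 0.07, width = 0.005, n = 1)
  g0 <- gen_itc_curve(p, noise_sd = 0)
  expect_equal(g0$curve$dh, eval_sigmoid(g0$curve$conc, p), tolerance = 1e-14)
  g1 <- gen_itc_curve(p, noise_sd = 0.05, seed = 4)
  g2 <- gen_itc_curve(p, noise_sd = 0.05, seed = 4)
  expect_identical(g1$curve$dh, g2$curve$dh)
  g3 <- gen_itc_curve(p, noise_sd = 0.05, seed = 5)
  expect_false(identical(g1$curve$dh, g3$curve$dh))
  # the generator never disturbs the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_itc_curve(p, noise_sd = 0.05, seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("two-step generator produces a bell-like curve with an exothermic step", {
  pd <- c(a1 = 4, b1 = 0, a2 = 6, b2 = 0, a3 = 1, b3 = 0,
          c1 = 0.05, w1 = 0.004, n1 = 1, c2 = 0.12, w2 = 0.006, n2 = 1)
  g <- gen_itc_curve(pd, n_points = 100, noise_sd = 0)
  dh <- g$curve$dh
  # rises to the mid plateau, then falls past the second step: bell shape
  peak <- which.max(dh)
  expect_gt(peak, 5)
  expect_lt(peak, 95)
  expect_gt(max(dh) - dh[1], 1)
  expect_gt(max(dh) - dh[100], 1)
})

test_that("scattering generator matches the analytic sphere form factor exactly", {
  g <- gen_scattering_curve(2.2, i0 = 7, noise = 0)
  expect_equal(g$curve$intensity, 7 * sphere_form_factor(g$curve$q, 2.2),
               tolerance = 1e-10)
  expect_equal(g$truth$rg, sqrt(3 / 5) * 2.2)
})

test_that("polydispersity, background and upturn alter the curve as constructed", {
  base <- gen_scattering_curve(2.2, i0 = 10, noise = 0)
  poly <- gen_scattering_curve(2.2, i0 = 10, poly_sigma = 0.15, noise = 0)
  # polydispersity fills in the sharp form-factor minima
  expect_gt(min(poly$curve$intensity), min(base$curve$intensity))
  up <- gen_scattering_curve(2.2, i0 = 10, noise = 0, upturn_amp = 0.01, upturn_exp = 3)
  lowq <- up$curve$q[1]
  powerlaw <- 0.01 * lowq^-3
  expect_gt(powerlaw / up$curve$intensity[1], 0.5)  # upturn dominates lowest Q
  bg <- gen_scattering_curve(2.2, i0 = 10, background = 0.5, noise = 0)
  expect_equal(tail(bg$curve$intensity, 1) - tail(base$curve$intensity, 1), 0.5,
               tolerance = 1e-6)
})

test_that("scattering noise is seed-deterministic with a populated sigma column", {
  g1 <- gen_scattering_curve(2.2, i0 = 10, noise = 0.05, seed = 6)
  g2 <- gen_scattering_curve(2.2, i0 = 10, noise = 0.05, seed = 6)
  expect_identical(g1$curve$intensity, g2$curve$intensity)
  expect_true(all(g1$curve$sigma > 0))
})
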