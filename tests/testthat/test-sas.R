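q_default <- exp(seq(log(0.063), log(5.8), length.out = 120))

test_that("Guinier fit recovers an exact Guinier curve to numerical precision", {
  cv <- scattering_curve(q_default, 10 * exp(-q_default^2 * 1.7^2 / 3))
  gf <- guinier_fit(cv)
  expect_equal(gf$rg, 1.7, tolerance = 1e-6)
  expect_equal(gf$i0, 10, tolerance = 1e-6)
  expect_lte(gf$qrg_max_observed, 1.3 + 1e-9)
})

test_that("Guinier fit on a sphere form factor gives Rg = sqrt(3/5) R", {
  R <- radius_from_rg(1.7)
  g <- gen_scattering_curve(R, i0 = 10, noise = 0)
  gf <- guinier_fit(g$curve)
  expect_equal(gf$rg, 1.7, tolerance = 0.02)
})

test_that("flat curves have vanishing radius of gyration", {
  fl <- scattering_curve(q_default, rep(3, length(q_default)))
  expect_equal(guinier_fit(fl)$rg, 0)
})

test_that("Guinier fit rejects unusable windows", {
  bad <- scattering_curve(q_default[1:10], c(-1, rep(2, 9)))
  expect_error(guinier_fit(bad), "non-positive")
  expect_error(guinier_fit(scattering_curve(q_default[1:3], rep(1, 3))), "few points")
})

test_that("shape indicator applies the printed thresholds with a gap class", {
  expect_equal(shape_indicator(1.25), "globular")
  expect_equal(shape_indicator(0.7), "elongated")
  expect_equal(shape_indicator(0.85), "indeterminate")
  expect_equal(shape_indicator(1.35), "indeterminate")
  expect_error(shape_indicator(-1))
})

test_that("Kratky transform is exact, including uncertainty propagation", {
  cv <- scattering_curve(q_default, 1 / q_default^2, sigma = 0.1 / q_default^2)
  kr <- kratky_transform(cv)
  expect_equal(kr$q2i, rep(1, length(q_default)))
  expect_equal(kr$sigma, rep(0.1, length(q_default)))
})

test_that("Kratky compactness separates spheres from flexible chains", {
  R <- radius_from_rg(1.7)
  sphere <- gen_scattering_curve(R, i0 = 10, noise = 0)$curve
  expect_true(kratky_compactness(sphere)$compact)
  flexible <- scattering_curve(q_default, debye_form_factor(q_default, 1.7))
  expect_false(kratky_compactness(flexible)$compact)
})

test_that("sphere radius relations are exact closed forms", {
  expect_equal(rg_from_radius(1), sqrt(3 / 5), tolerance = 1e-12)
  expect_equal(rg_from_radius(1), 0.7746, tolerance = 1e-4)
  expect_equal(radius_from_rg(1.9), 2.453, tolerance = 1e-3)
  expect_equal(radius_from_rg(rg_from_radius(2.7)), 2.7, tolerance = 1e-12)
})

test_that("IFT recovers the analytic sphere pair distance distribution", {
  R <- radius_from_rg(1.7)
  g <- gen_scattering_curve(R, i0 = 10, noise = 0)
  pf <- pddf_ift(g$curve, d_max = 2 * R)
  step <- pf$r[2] - pf$r[1]
  # peak position against the analytic sphere PDDF maximum
  peak_analytic <- optimize(function(r) -sphere_pddf(r, R), c(0, 2 * R))$minimum
  expect_lt(abs(pf$r[which.max(pf$p)] - peak_analytic), step + 1e-12)
  # boundary conditions and non-negativity
  expect_equal(pf$p[1], 0)
  expect_equal(pf$p[length(pf$p)], 0)
  expect_true(all(pf$p >= 0))
  # Rg from p(r) agrees with the Guinier route within 5%
  gf <- guinier_fit(g$curve)
  expect_lt(abs(pf$rg - gf$rg) / gf$rg, 0.05)
  # forward transform reproduces the input intensities
  expect_lt(max(abs(pf$i_fit - pf$intensity)) / max(pf$intensity), 1e-3)
})

test_that("estimated maximum dimension matches the sphere diameter", {
  R <- radius_from_rg(1.7)
  for (noise in c(0, 0.01)) {
    g <- gen_scattering_curve(R, i0 = 10, noise = noise, seed = 5)
    est <- estimate_dmax(g$curve, d_max_upper = 3 * R)
    expect_lt(abs(est - 2 * R), 3 * R / 100,
              label = sprintf("dmax at %.0f%% noise", 100 * noise))
  }
})

test_that("analyses are unit-safe between nm^-1 and A^-1", {
  R <- radius_from_rg(1.7)
  g <- gen_scattering_curve(R, i0 = 10, noise = 0.02, seed = 8)
  rg_nm <- guinier_fit(g$curve)$rg
  curve_A <- convert_q_unit(g$curve, "A-1")
  rg_A <- guinier_fit(curve_A)$rg          # in Angstrom: 10x the nm number
  expect_equal(rg_A, rg_nm * 10, tolerance = 1e-9)
  expect_equal(convert_q_unit(curve_A, "nm-1")$q, g$curve$q, tolerance = 1e-12)
})

test_that("curve container enforces Q monotonicity and positive errors", {
  expect_error(scattering_curve(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(scattering_curve(c(-0.1, 0.1), c(1, 1)), "positive")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, 1), sigma = c(1, 0)), "sigma")
})
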