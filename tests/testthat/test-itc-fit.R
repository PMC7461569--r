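single_truth <- c(h_ia = 5, h_ib = 3, h_fa = 1, h_fb = -2,
                  cmc = 0.07, width = 0.005, n = 1)
double_truth <- c(a1 = 4, b1 = 2, a2 = 1.5, b2 = 0, a3 = -0.5, b3 = -1,
                  c1 = 0.05, w1 = 0.004, n1 = 1, c2 = 0.12, w2 = 0.006, n2 = 1)

test_that("noise-free synthetic curves are recovered to numerical precision", {
  g <- gen_itc_curve(single_truth, noise_sd = 0)
  fit <- fit_enthalpogram(g$curve, steps = 1)
  for (nm in names(single_truth))
    expect_equal(fit$params[[nm]], single_truth[[nm]], tolerance = 1e-6,
                 label = paste("parameter", nm))
})

test_that("noisy single-sigmoid fits recover the centre within its uncertainty", {
  g <- gen_itc_curve(single_truth, noise_sd = 0.05, n_points = 60, seed = 17)
  fit <- fit_enthalpogram(g$curve, steps = 1)
  expect_lt(abs(fit$params[["cmc"]] - single_truth[["cmc"]]), 3 * fit$se[["cmc"]])
  ci <- confint_param(fit, "cmc")
  expect_lt(ci[["lower"]], ci[["upper"]])
})

test_that("double-sigmoid fits recover both ordered centres", {
  g <- gen_itc_curve(double_truth, n_points = 80, noise_sd = 0.05, seed = 3)
  fit <- fit_enthalpogram(g$curve, steps = 2)
  expect_lt(fit$params[["c1"]], fit$params[["c2"]])
  expect_equal(fit$params[["c1"]], 0.05, tolerance = 0.05)
  expect_equal(fit$params[["c2"]], 0.12, tolerance = 0.05)
  infl <- double_inflections(fit$params)
  expect_lt(infl[["cmc"]], infl[["c_trans"]])
  # step heights recovered within fit tolerance
  dh <- micellisation_enthalpy(fit$params)
  dh_true <- micellisation_enthalpy(double_truth)
  expect_equal(unname(dh), unname(dh_true), tolerance = 0.15)
})

test_that("fit input contracts are enforced", {
  short <- enthalpogram(seq(0.01, 0.05, length.out = 6), rnorm(6))
  expect_error(fit_enthalpogram(short, steps = 1), "at least 8")
  mid <- enthalpogram(seq(0.01, 0.05, length.out = 12), rnorm(12))
  expect_error(fit_enthalpogram(mid, steps = 2), "at least 14")
})

test_that("gibbs energy follows the counterion-binding pseudophase model", {
  # ln(1) = 0 regardless of beta and temperature
  expect_equal(gibbs_micellisation(NA, 0.7, 300, x_cmc = 1), 0)
  # independent hand evaluation of the formula
  x <- 0.01 / (0.01 + 55.345)
  expect_equal(gibbs_micellisation(0.01, 0.5, 300),
               (0.5 + 0.5) * 8.314462618 * 300 * log(x) / 1000)
  expect_error(gibbs_micellisation(0.05, 1.2, 300), "beta")
  expect_error(gibbs_micellisation(0.05, 0.5, 300, x_cmc = 1.2), "fraction")
})

test_that("beta back-solved from a published Gibbs energy is physically sensible", {
  # bisection oracle, written independently of solve_beta
  f <- function(b) (0.5 + b) * 8.314462618 * 298.15 *
    log(0.071 / (0.071 + 55.345)) / 1000 + 18.27
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  oracle <- (lo + hi) / 2
  expect_equal(solve_beta(-18.27, 0.071, 298.15), oracle, tolerance = 1e-8)
  expect_equal(solve_beta(-18.27, 0.071, 298.15), 0.61, tolerance = 0.01)
})

test_that("Gibbs-Helmholtz entropy closes exactly", {
  ent <- entropy_micellisation(-4.05, -17.24, 343.15)
  expect_equal(ent$tds, 13.19, tolerance = 0.005)
  expect_equal(ent$ds, 38.44, tolerance = 0.02)
  ent2 <- entropy_micellisation(5.66, -17.12, 283.15)
  expect_equal(ent2$tds, 22.78, tolerance = 0.005)
  expect_equal(ent2$ds, 80.45, tolerance = 0.02)
  expect_equal(entropy_micellisation(-3, -3, 310), list(tds = 0, ds = 0))
})

test_that("thermo_from_fit assembles a consistent thermodynamics row", {
  g <- gen_itc_curve(single_truth, noise_sd = 0, temperature = 298.15)
  fit <- fit_enthalpogram(g$curve)
  tab <- thermo_from_fit(fit, beta = 0.61)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$tds, tab$dh - tab$dg, tolerance = 1e-12)
  expect_equal(tab$ds * tab$temperature / 1000, tab$tds, tolerance = 1e-12)
  expect_lt(tab$dg, 0)
  g2 <- gen_itc_curve(double_truth, n_points = 80, noise_sd = 0, temperature = 318.15)
  fit2 <- fit_enthalpogram(g2$curve, steps = 2)
  tab2 <- thermo_from_fit(fit2, beta = 0.56)
  expect_equal(tab2$process, c("micellisation", "transition"))
  expect_lt(tab2$concentration[1], tab2$concentration[2])
})
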