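test_that("sigmoid model reaches its baselines in both concentration limits", {
  p <- c(h_ia = 5, h_ib = 0, h_fa = 1, h_fb = 0, cmc = 0.07, width = 0.005, n = 1)
  expect_equal(eval_sigmoid(0.07 - 50 * 0.005, p), 5, tolerance = 1e-9)
  expect_equal(eval_sigmoid(0.07 + 50 * 0.005, p), 1, tolerance = 1e-9)
  # symmetric logistic evaluates to the baseline midpoint at its centre
  expect_equal(eval_sigmoid(0.07, p), 3)
  # sloped baselines: the limits follow the lines, not the intercepts
  ps <- c(h_ia = 5, h_ib = 2, h_fa = 1, h_fb = -1, cmc = 0.07, width = 0.005, n = 1.4)
  lo <- 0.07 - 50 * 0.005
  hi <- 0.07 + 50 * 0.005
  expect_equal(eval_sigmoid(lo, ps), 5 + 2 * lo, tolerance = 1e-9)
  expect_equal(eval_sigmoid(hi, ps), 1 - hi, tolerance = 1e-9)
})

test_that("invalid sigmoid parameters are rejected", {
  p <- c(h_ia = 5, h_ib = 0, h_fa = 1, h_fb = 0, cmc = 0.07, width = 0.005, n = 1)
  bad_w <- replace(p, "width", -1)
  bad_n <- replace(p, "n", 0)
  expect_error(eval_sigmoid(0.05, bad_w), "width")
  expect_error(eval_sigmoid(0.05, bad_n), "exponent")
  pd <- c(a1 = 1, b1 = 0, a2 = 0, b2 = 0, a3 = -1, b3 = 0,
          c1 = 0.1, w1 = 0.01, n1 = 1, c2 = 0.05, w2 = 0.01, n2 = 1)
  expect_error(eval_double_sigmoid(0.05, pd), "c1 < c2")
})

test_that("double sigmoid interpolates its three baselines", {
  pd <- c(a1 = 4, b1 = 2, a2 = 1.5, b2 = 0, a3 = -0.5, b3 = -1,
          c1 = 0.05, w1 = 0.002, n1 = 1, c2 = 0.15, w2 = 0.002, n2 = 1)
  expect_equal(eval_double_sigmoid(0.01, pd), 4 + 2 * 0.01, tolerance = 1e-8)
  expect_equal(eval_double_sigmoid(0.10, pd), 1.5, tolerance = 1e-6)
  expect_equal(eval_double_sigmoid(0.30, pd), -0.5 - 0.30, tolerance = 1e-8)
})

test_that("inflection finder agrees with a dense finite-difference grid scan", {
  grid_oracle <- function(p, span = 20) {
    f <- function(x) eval_sigmoid(x, p)
    g <- seq(p[["cmc"]] - span * p[["width"]], p[["cmc"]] + span * p[["width"]],
             length.out = 100001)
    h <- g[2] - g[1]
    v <- f(g)
    d2 <- (v[-c(1, 2)] - 2 * v[-c(1, length(v))] + v[-c(length(v) - 1, length(v))]) / h^2
    x <- g[-c(1, length(g))]
    sgn <- sign(d2)
    nz <- which(sgn != 0)
    lo <- nz[which(sgn[nz][-1] * sgn[nz][-length(nz)] < 0)]
    hi <- nz[match(lo, nz) + 1L]
    # linear interpolation across each sign-change bracket
    roots <- x[lo] - d2[lo] * (x[hi] - x[lo]) / (d2[hi] - d2[lo])
    roots[which.min(abs(roots - p[["cmc"]]))]
  }
  # symmetric case: inflects exactly at the centre
  p1 <- c(h_ia = 5, h_ib = 0, h_fa = 1, h_fb = 0, cmc = 0.07, width = 0.005, n = 1)
  expect_equal(cmc_from_second_derivative(p1), 0.07, tolerance = 1e-9)
  # skewed and sloped cases against the brute-force oracle (absolute
  # agreement to 1e-6 mol/dm3)
  p2 <- replace(p1, "n", 2)
  expect_lt(abs(cmc_from_second_derivative(p2) - grid_oracle(p2)), 1e-6)
  p3 <- c(h_ia = 5, h_ib = 2, h_fa = 1, h_fb = -1, cmc = 0.07, width = 0.005, n = 1)
  expect_lt(abs(cmc_from_second_derivative(p3) - grid_oracle(p3)), 1e-6)
  # random valid models
  set.seed(402)
  for (i in 1:40) {
    p <- c(h_ia = runif(1, -5, 8), h_ib = runif(1, -10, 10),
           h_fa = runif(1, -5, 5), h_fb = runif(1, -10, 10),
           cmc = runif(1, 0.03, 0.15), width = runif(1, 0.002, 0.01),
           n = runif(1, 0.3, 3))
    found <- cmc_from_second_derivative(p)
    expect_lt(abs(found - grid_oracle(p)), 1e-6,
              label = sprintf("model %d inflection error", i))
  }
})

test_that("micellisation enthalpy is the baseline difference at the inflection", {
  flat <- c(h_ia = 5, h_ib = 0, h_fa = 1, h_fb = 0, cmc = 0.08, width = 0.004, n = 1)
  expect_equal(micellisation_enthalpy(flat), -4)
  sloped <- c(h_ia = 2, h_ib = 10, h_fa = 0, h_fb = -5, cmc = 0.1, width = 0.004, n = 1)
  expect_equal(micellisation_enthalpy(sloped, at = 0.1), (0 - 0.5) - (2 + 1.0))
})

test_that("enthalpogram container enforces its invariants", {
  expect_error(enthalpogram(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(enthalpogram(c(-0.1, 0.1), c(1, 2)), "positive")
  expect_error(enthalpogram(c(0.1, 0.2), c(1, 2), sigma = c(0, 1)), "sigma")
  cv <- enthalpogram(seq(0.01, 0.1, length.out = 10), rnorm(10), 298.15)
  expect_s3_class(cv, "enthalpogram")
  expect_equal(attr(cv, "temperature"), 298.15)
})
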