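# Seeded generators of synthetic inputs with the statistical structure the
# analysis stages assume, so the whole pipeline runs without external data.

#' Generate a synthetic enthalpogram
#'
#' Forward-evaluates the single- or double-sigmoid model on a concentration
#' grid and adds homoscedastic Gaussian noise.  The ground truth is returned
#' beside the curve so that round-trip tests can score parameter recovery.
#' The default grid spans roughly a fifth of the first step centre up to a
#' few times the last centre, mimicking a demicellisation titration that
#' crosses the c.m.c early in the experiment.
#'
#' @param params Named parameters of [eval_sigmoid()] (single step) or
#'   [eval_double_sigmoid()] (two steps; detected by the presence of `c1`).
#' @param n_points Number of titration points.
#' @param noise_sd Gaussian noise standard deviation, kJ mol^-1.
#' @param conc Optional concentration grid (mol dm^-3); built from the
#'   centres when omitted.
#' @param temperature Temperature metadata, K.
#' @param seed Integer seed; fixed seed gives identical curves.
#' @return List with `curve` (an [enthalpogram()]) and `truth` (the
#'   generating parameters and noise level).
#' @export
gen_itc_curve <- function(params, n_points = 60L, noise_sd = 0.05,
                          conc = NULL, temperature = 298.15, seed = 1L) {
  p <- as.list(params)
  double <- "c1" %in% names(p)
  if (double) check_double_params(p) else check_sigmoid_params(p)
  centres <- if (double) c(p$c1, p$c2) else p$cmc
  if (is.null(conc))
    conc <- seq(centres[1] / 5, max(centres) * 2.5, length.out = n_points)
  if (any(centres <= min(conc)) || any(centres >= max(conc)))
    stop("step centres must lie inside the concentration grid", call. = FALSE)
  model <- if (double) eval_double_sigmoid(conc, p) else eval_sigmoid(conc, p)
  noise <- if (noise_sd > 0)
    with_seed(seed, rnorm(length(conc), sd = noise_sd))
  else rep(0, length(conc))
  sigma <- if (noise_sd > 0) rep(noise_sd, length(conc)) else NULL
  list(curve = enthalpogram(conc, model + noise, temperature, sigma = sigma),
       truth = c(p, list(noise_sd = noise_sd, seed = seed)))
}

#' Generate a synthetic small-angle scattering curve
#'
#' Sphere form factor, optionally averaged over a lognormal size
#' distribution (volume-squared weighting), plus a flat background, an
#' optional low-Q power-law upturn emulating micelle aggregation, and
#' relative Gaussian noise.  The uncertainty column is populated with the
#' noise level actually applied.
#'
#' @param radius Mean sphere radius, nm.
#' @param i0 Forward intensity scale.
#' @param poly_sigma Lognormal sigma of the radius distribution (0 for
#'   monodisperse).
#' @param background Flat background level.
#' @param noise Relative noise level (0 for noise-free).
#' @param upturn_amp,upturn_exp Low-Q power-law term `amp * Q^-exp`
#'   (`upturn_amp = 0` disables it).
#' @param q Momentum-transfer grid, nm^-1; the default log-spaced grid spans
#'   0.063-5.8 nm^-1, a typical pinhole instrument window.
#' @param n_points Number of Q points for the default grid.
#' @param seed Integer seed.
#' @return List with `curve` (a [scattering_curve()], unit nm^-1) and
#'   `truth`.
#' @export
gen_scattering_curve <- function(radius, i0 = 1, poly_sigma = 0,
                                 background = 0, noise = 0,
                                 upturn_amp = 0, upturn_exp = 3,
                                 q = NULL, n_points = 120L, seed = 1L) {
  stopifnot(radius > 0, poly_sigma >= 0, noise >= 0)
  if (is.null(q)) q <- exp(seq(log(0.063), log(5.8), length.out = n_points))
  if (poly_sigma == 0) {
    i_model <- i0 * sphere_form_factor(q, radius)
  } else {
    # volume-squared weighted average over the lognormal size distribution
    lr <- seq(log(radius) - 4 * poly_sigma, log(radius) + 4 * poly_sigma,
              length.out = 61)
    rr <- exp(lr)
    wts <- stats::dlnorm(rr, meanlog = log(radius), sdlog = poly_sigma) * rr
    wts <- wts * rr^6
    wts <- wts / sum(wts)
    pf <- vapply(q, function(qq) sum(wts * sphere_form_factor(qq, rr)), numeric(1))
    i_model <- i0 * pf
  }
  i_model <- i_model + background + upturn_amp * q^(-upturn_exp)
  sigma <- noise * pmax(i_model, .Machine$double.eps)
  i_obs <- if (noise > 0)
    i_model + with_seed(seed, rnorm(length(q), sd = sigma))
  else i_model
  curve <- scattering_curve(q, i_obs,
                            sigma = if (noise > 0) sigma else NULL,
                            unit = "nm-1")
  list(curve = curve,
       truth = list(radius = radius, rg = rg_from_radius(radius), i0 = i0,
                    poly_sigma = poly_sigma, background = background,
                    noise = noise, upturn_amp = upturn_amp,
                    upturn_exp = upturn_exp, seed = seed))
}
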