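#' Small-angle scattering curve container
#'
#' @param q Momentum transfer, strictly increasing and positive.
#' @param intensity Scattered intensity (arbitrary units).
#' @param sigma Optional intensity uncertainty (positive where given).
#' @param unit Q unit, `"nm-1"` or `"A-1"`.
#' @param temperature,concentration Optional metadata (K, mol dm^-3).
#' @return A `scattering_curve` object (tibble with attributes).
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             unit = c("nm-1", "A-1"),
                             temperature = NA_real_, concentration = NA_real_) {
  unit <- match.arg(unit)
  if (any(q <= 0)) stop("Q must be positive", call. = FALSE)
  if (any(diff(q) <= 0)) stop("Q must be strictly increasing", call. = FALSE)
  if (!is.null(sigma) && any(sigma <= 0))
    stop("sigma must be positive where given", call. = FALSE)
  out <- tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  structure(out, unit = unit, temperature = temperature,
            concentration = concentration,
            class = c("scattering_curve", class(out)))
}

#' Convert the Q unit of a scattering curve
#'
#' @param curve A [scattering_curve()].
#' @param to Target unit (`"nm-1"` or `"A-1"`); 1 A^-1 = 10 nm^-1.
#' @return The converted curve.
#' @export
convert_q_unit <- function(curve, to = c("nm-1", "A-1")) {
  to <- match.arg(to)
  from <- attr(curve, "unit")
  if (from == to) return(curve)
  f <- if (from == "A-1") 10 else 0.1   # Q scale factor
  curve$q <- curve$q * f
  attr(curve, "unit") <- to
  curve
}

#' Guinier fit of the low-Q region
#'
#' In the Guinier regime `I(Q) = I(0) exp(-Q^2 Rg^2 / 3)`, so a weighted
#' linear regression of `ln I` on `Q^2` over the low-Q window yields `I(0)`
#' and the radius of gyration.  The window is iterated to self-consistency:
#' starting from the `min_points` lowest-Q points it grows to the largest
#' window satisfying `Q * Rg <= qrg_max`.
#'
#' @param curve A [scattering_curve()].
#' @param qrg_max Upper cap on `Q * Rg` within the fitted window.
#' @param min_points Minimum points in the window.
#' @param skip_low_q Number of lowest-Q points to exclude (aggregation
#'   upturn region; 0 by default).
#' @param max_iter Window iteration limit.
#' @return A `guinier_fit` object: list with `i0`, `rg`, `qrg_max_observed`,
#'   `window` (index range), `n_points`, `r2` and the curve's unit.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 5L,
                        skip_low_q = 0L, max_iter = 50L) {
  q <- curve$q
  i <- curve$intensity
  s <- curve[["sigma"]]
  keep <- seq_along(q) > skip_low_q
  q <- q[keep]; i <- i[keep]
  s <- if (!is.null(s)) s[keep] else NULL
  if (sum(keep) < min_points) stop("too few points for a Guinier fit", call. = FALSE)

  fit_window <- function(idx) {
    if (any(i[idx] <= 0))
      stop("non-positive intensities in the Guinier window", call. = FALSE)
    y <- log(i[idx])
    x <- q[idx]^2
    w <- if (!is.null(s) && all(s[idx] > 0)) (i[idx] / s[idx])^2 else rep(1, length(idx))
    lm(y ~ x, weights = w)
  }

  upper <- max(min_points, min(length(q), max(min_points, floor(length(q) / 3))))
  idx <- seq_len(upper)
  sizes_seen <- integer(0)
  for (iter in seq_len(max_iter)) {
    fit <- fit_window(idx)
    rg <- sqrt(max(0, -3 * coef(fit)[["x"]]))
    if (rg == 0) break
    n_ok <- min(length(q), max(min_points, sum(q * rg <= qrg_max)))
    if (n_ok == length(idx)) break                   # self-consistent window
    if (n_ok %in% sizes_seen) {                      # 2-cycle: take the tighter window
      idx <- seq_len(min(n_ok, length(idx)))
      fit <- fit_window(idx)
      rg <- sqrt(max(0, -3 * coef(fit)[["x"]]))
      break
    }
    sizes_seen <- c(sizes_seen, length(idx))
    idx <- seq_len(n_ok)
    if (iter == max_iter)
      stop("Guinier window iteration did not converge", call. = FALSE)
  }
  # weighted R^2 computed directly (summary.lm warns on exact synthetic data)
  wts <- fit$weights %||% rep(1, length(idx))
  res <- stats::residuals(fit)
  yfit <- stats::fitted(fit)
  ybar <- sum(wts * (yfit + res)) / sum(wts)
  r2 <- 1 - sum(wts * res^2) / sum(wts * ((yfit + res) - ybar)^2)
  structure(list(i0 = exp(coef(fit)[["(Intercept)"]]), rg = rg,
                 qrg_max_observed = max(q[idx]) * rg,
                 window = range(idx) + skip_low_q, n_points = length(idx),
                 r2 = r2, unit = attr(curve, "unit")),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  len_unit <- if (identical(x$unit, "A-1")) "A" else "nm"
  cat(sprintf("Guinier fit: Rg = %.4g %s, I0 = %.4g, (Q Rg)max = %.3f, %d points\n",
              x$rg, len_unit, x$i0, x$qrg_max_observed, x$n_points))
  invisible(x)
}

#' Particle shape class from the Guinier window extent
#'
#' The largest `Q * Rg` product of the linear Guinier region indicates the
#' scatterer shape: globular for `0.9 < x < 1.3`, elongated for `x < 0.8`.
#' The printed thresholds leave `0.8 <= x <= 0.9` and `x >= 1.3`
#' unclassified, reported here as `"indeterminate"` rather than silently
#' extrapolated.
#'
#' @param qrg_max Observed `(Q Rg)max` (positive).
#' @return `"globular"`, `"elongated"` or `"indeterminate"`.
#' @export
shape_indicator <- function(qrg_max) {
  stopifnot(qrg_max > 0)
  if (qrg_max > 0.9 && qrg_max < 1.3) "globular"
  else if (qrg_max < 0.8) "elongated"
  else "indeterminate"
}

#' Kratky transform
#'
#' Returns `(Q, Q^2 I(Q))`; a bell-shaped maximum indicates a compact
#' (globular) particle, a plateau or monotonic rise a flexible one.
#' Uncertainties propagate exactly as `Q^2 sigma`.
#'
#' @param curve A [scattering_curve()].
#' @return Tibble with `q`, `q2i` and (when available) `sigma`.
#' @export
kratky_transform <- function(curve) {
  out <- tibble::tibble(q = curve$q, q2i = curve$q^2 * curve$intensity)
  if (!is.null(curve[["sigma"]])) out$sigma <- curve$q^2 * curve[["sigma"]]
  out
}

#' Compactness flag from a Kratky curve
#'
#' A compact particle shows a single interior maximum of `Q^2 I(Q)`; a
#' flexible chain (Debye-like) plateaus or keeps rising.  The curve is
#' lightly smoothed before the interior-maximum test.
#'
#' @param curve A [scattering_curve()].
#' @param smooth Half-width of the moving-average smoother (points).
#' @return List with `compact` (logical) and `q_peak`.
#' @export
kratky_compactness <- function(curve, smooth = 2L) {
  kr <- kratky_transform(curve)
  y <- kr$q2i
  if (smooth > 0) {
    k <- 2 * smooth + 1
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  }
  ok <- !is.na(y)
  yv <- y[ok]; qv <- kr$q[ok]
  pk <- which.max(yv)
  interior <- pk > 1 && pk < length(yv)
  # require a genuine fall-off after the peak, not a noisy plateau
  falls <- interior && yv[length(yv)] < 0.8 * yv[pk]
  list(compact = isTRUE(interior && falls), q_peak = qv[pk])
}

#' Sphere radius / radius of gyration relations
#'
#' For a homogeneous sphere `Rg^2 = (3/5) R^2`.
#'
#' @param r Sphere radius.
#' @param rg Radius of gyration.
#' @return The converted quantity.
#' @export
rg_from_radius <- function(r) {
  stopifnot(r > 0)
  sqrt(3 / 5) * r
}

#' @rdname rg_from_radius
#' @export
radius_from_rg <- function(rg) {
  stopifnot(rg > 0)
  rg / sqrt(3 / 5)
}

#' Form factor of a homogeneous sphere
#'
#' `P(Q) = [3 (sin(QR) - QR cos(QR)) / (QR)^3]^2`, normalized to 1 at Q = 0.
#'
#' @param q Momentum transfer.
#' @param radius Sphere radius (reciprocal units of `q`).
#' @return Form factor values.
#' @export
sphere_form_factor <- function(q, radius) {
  x <- q * radius
  p <- ifelse(x < 1e-4, 1 - x^2 / 5,          # series limit, avoids 0/0
              3 * (sin(x) - x * cos(x)) / x^3)
  p^2
}

#' Analytic pair distance distribution of a homogeneous sphere
#'
#' `p(r) = r^2 (1 - 3x/4 + x^3/16)` with `x = r / R`, zero outside
#' `[0, 2R]` (unnormalized).
#'
#' @param r Distances.
#' @param radius Sphere radius.
#' @return Unnormalized `p(r)`.
#' @export
sphere_pddf <- function(r, radius) {
  x <- r / radius
  ifelse(r >= 0 & x <= 2, r^2 * (1 - 0.75 * x + x^3 / 16), 0)
}

#' Debye form factor of a Gaussian chain
#'
#' `P(x) = 2 (exp(-x) - 1 + x) / x^2` with `x = (Q Rg)^2`; used as the
#' flexible-particle reference in compactness tests.
#'
#' @param q Momentum transfer.
#' @param rg Radius of gyration.
#' @return Form factor values.
#' @export
debye_form_factor <- function(q, rg) {
  x <- (q * rg)^2
  ifelse(x < 1e-8, 1 - x / 3, 2 * (exp(-x) - 1 + x) / x^2)
}
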