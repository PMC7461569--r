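#' Enthalpogram container
#'
#' One temperature's titration data: the observed enthalpy of dilution
#' against cumulative surfactant concentration.
#'
#' @param conc Surfactant concentration `C_s`, mol dm^-3; strictly
#'   increasing, positive.
#' @param dh Dilution enthalpy, kJ mol^-1.
#' @param temperature Temperature, K.
#' @param sigma Optional per-point uncertainty, kJ mol^-1.
#' @return An `enthalpogram` object (tibble with attributes).
#' @export
enthalpogram <- function(conc, dh, temperature = NA_real_, sigma = NULL) {
  if (length(conc) != length(dh)) stop("conc and dh lengths differ", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing", call. = FALSE)
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  out <- tibble::tibble(conc = as.numeric(conc), dh = as.numeric(dh))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  structure(out, temperature = as.numeric(temperature),
            class = c("enthalpogram", class(out)))
}

check_sigmoid_params <- function(p) {
  need <- c("h_ia", "h_ib", "h_fa", "h_fb", "cmc", "width", "n")
  if (!all(need %in% names(p))) stop("missing sigmoid parameters", call. = FALSE)
  if (p[["width"]] <= 0) stop("transition width must be positive", call. = FALSE)
  if (p[["n"]] <= 0) stop("exponent n must be positive", call. = FALSE)
  invisible(p)
}

#' Sigmoidal (modified Boltzmann) enthalpogram model
#'
#' Generalized-logistic step between two linear baselines:
#' `dH(C) = Hf(C) + (Hi(C) - Hf(C)) / (1 + exp((C - cmc)/width))^n`
#' with the pre-micellar baseline `Hi(C) = h_ia + h_ib * C` and the
#' post-micellar baseline `Hf(C) = h_fa + h_fb * C`.  Far below the step the
#' model equals the initial baseline; far above, the final baseline.
#'
#' @param conc Concentrations, mol dm^-3.
#' @param params Named vector/list with `h_ia`, `h_ib`, `h_fa`, `h_fb`,
#'   `cmc`, `width`, `n`.
#' @return Model enthalpies, kJ mol^-1.
#' @export
eval_sigmoid <- function(conc, params) {
  p <- check_sigmoid_params(as.list(params))
  hi <- p$h_ia + p$h_ib * conc
  hf <- p$h_fa + p$h_fb * conc
  # (1 + exp(u))^-n computed on the log scale for numerical stability
  u <- (conc - p$cmc) / p$width
  g <- exp(-p$n * log1p(exp(pmin(u, 700))))
  hf + (hi - hf) * g
}

check_double_params <- function(p) {
  need <- c("a1", "b1", "a2", "b2", "a3", "b3",
            "c1", "w1", "n1", "c2", "w2", "n2")
  if (!all(need %in% names(p))) stop("missing double-sigmoid parameters", call. = FALSE)
  if (p[["w1"]] <= 0 || p[["w2"]] <= 0) stop("widths must be positive", call. = FALSE)
  if (p[["n1"]] <= 0 || p[["n2"]] <= 0) stop("exponents must be positive", call. = FALSE)
  if (p[["c1"]] >= p[["c2"]]) stop("step centres must satisfy c1 < c2", call. = FALSE)
  invisible(p)
}

#' Double-sigmoid (bell-shaped) enthalpogram model
#'
#' Two conjoined generalized-logistic steps over a shared piecewise-linear
#' baseline: the first step (centre `c1`) is the micellisation transition,
#' the second (centre `c2`) the micelle shape transformation.  With the three
#' baselines `L1 = a1 + b1 C` (pre-micellar), `L2 = a2 + b2 C` (between the
#' steps) and `L3 = a3 + b3 C` (post-transition):
#' `dH(C) = L3 + (L2 - L3) g2 + (L1 - L2) g1`,
#' each `g = (1 + exp((C - c)/w))^-n`, so the low-concentration limit is
#' `L1`, the plateau between the steps `L2`, and the high-concentration limit
#' `L3`.
#'
#' @param conc Concentrations, mol dm^-3.
#' @param params Named vector/list with `a1`, `b1`, `a2`, `b2`, `a3`, `b3`,
#'   `c1`, `w1`, `n1`, `c2`, `w2`, `n2` (`c1 < c2`).
#' @return Model enthalpies, kJ mol^-1.
#' @export
eval_double_sigmoid <- function(conc, params) {
  p <- check_double_params(as.list(params))
  eval_double_raw(conc, p)
}

# evaluation without the ordering contract, for use inside least-squares
# iterations where the optimizer may transiently cross c1 >= c2
eval_double_raw <- function(conc, p) {
  p <- as.list(p)
  step <- function(c0, w, n) {
    u <- (conc - c0) / w
    exp(-n * log1p(exp(pmin(u, 700))))
  }
  l1 <- p$a1 + p$b1 * conc
  l2 <- p$a2 + p$b2 * conc
  l3 <- p$a3 + p$b3 * conc
  l3 + (l2 - l3) * step(p$c2, p$w2, p$n2) + (l1 - l2) * step(p$c1, p$w1, p$n1)
}

# numerically robust second derivative of a model curve (central differences)
second_deriv <- function(f, x, h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2

#' Critical micelle concentration as the inflection of the fitted model
#'
#' The c.m.c is the zero of the second derivative of the model enthalpy with
#' respect to concentration, located with a bracketing root finder on a
#' finite-difference second derivative.  For a symmetric step (`n = 1`, flat
#' baselines) this is the fitted centre exactly; for skewed steps
#' (`n != 1`) or sloped baselines the inflection shifts away from the centre
#' and the root nearest the centre is returned.
#'
#' @param params Single-sigmoid parameters (see [eval_sigmoid()]).
#' @param span Half-width of the search window in units of `width`.
#' @return Inflection concentration, mol dm^-3.
#' @export
cmc_from_second_derivative <- function(params, span = 20) {
  p <- check_sigmoid_params(as.list(params))
  f <- function(x) eval_sigmoid(x, p)
  inflection_root(f, centre = p$cmc, width = p$width, span = span)
}

inflection_root <- function(f, centre, width, span = 20) {
  h <- width * 1e-3
  d2 <- function(x) second_deriv(f, x, h)
  lo <- centre - span * width
  hi <- centre + span * width
  grid <- seq(lo, hi, length.out = 4001)
  v <- d2(grid)
  # ignore the saturated tails where the curvature underflows to exactly 0;
  # bracket sign changes between consecutive points of non-zero sign
  nz <- which(sign(v) != 0)
  if (length(nz) < 2)
    stop("no sign change of the second derivative in the search window", call. = FALSE)
  flips <- nz[which(sign(v[nz])[-1] * sign(v[nz])[-length(nz)] < 0)]
  pair_hi <- nz[match(flips, nz) + 1L]
  if (length(flips) == 0)
    stop("no sign change of the second derivative in the search window", call. = FALSE)
  roots <- vapply(seq_along(flips), function(i)
    uniroot(d2, c(grid[flips[i]], grid[pair_hi[i]]), tol = 1e-12)$root, numeric(1))
  roots[which.min(abs(roots - centre))]
}

#' Enthalpy of micellisation from the fitted baselines
#'
#' The two linear baselines are evaluated at the inflection concentration and
#' their difference `Hf(C) - Hi(C)` is returned (negative when micellisation
#' is exothermic relative to the monomer state at that concentration).  For a
#' double-sigmoid model the adjacent baseline pair of each step is used,
#' giving the micellisation enthalpy at `c1` and the transition enthalpy at
#' `c2`.
#'
#' @param params Single- or double-sigmoid parameters.
#' @param at Optional inflection concentration(s); defaults to the model
#'   inflection(s) from the second-derivative rule.
#' @return For a single step, a scalar `dH_mic`; for two steps a named vector
#'   `c(dh_mic, dh_trans)`, kJ mol^-1.
#' @export
micellisation_enthalpy <- function(params, at = NULL) {
  p <- as.list(params)
  if (all(c("c1", "c2") %in% names(p))) {
    check_double_params(p)
    if (is.null(at)) at <- double_inflections(p)
    dh1 <- (p$a2 + p$b2 * at[1]) - (p$a1 + p$b1 * at[1])
    dh2 <- (p$a3 + p$b3 * at[2]) - (p$a2 + p$b2 * at[2])
    c(dh_mic = unname(dh1), dh_trans = unname(dh2))
  } else {
    check_sigmoid_params(p)
    if (is.null(at)) at <- cmc_from_second_derivative(p)
    (p$h_fa + p$h_fb * at) - (p$h_ia + p$h_ib * at)
  }
}

#' Inflection concentrations of a double-sigmoid model
#'
#' Applies the second-derivative zero rule separately within each step's
#' bracket (a window of a few widths around each centre), so the two
#' inflections are the c.m.c and the transition concentration `C_trans`.
#'
#' @param params Double-sigmoid parameters.
#' @param span Half-width of each search window in units of the step width.
#' @return Numeric vector `c(cmc, c_trans)`.
#' @export
double_inflections <- function(params, span = 6) {
  p <- check_double_params(as.list(params))
  f <- function(x) eval_double_sigmoid(x, p)
  c(cmc = inflection_root(f, p$c1, p$w1, span),
    c_trans = inflection_root(f, p$c2, p$w2, span))
}
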