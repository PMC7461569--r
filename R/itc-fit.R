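#' Fit a sigmoidal or double-sigmoidal model to an enthalpogram
#'
#' Least-squares fit of the modified Boltzmann model (one step) or of two
#' conjoined steps over a piecewise-linear baseline, by Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}).  Starting values come from the data: baselines
#' from the curve ends, centres from the extrema of a smoothed numerical
#' derivative, widths from the spread of the derivative peak, exponents at 1.
#'
#' @param curve An [enthalpogram()] (or any data frame with `conc` and `dh`,
#'   optionally `sigma`).
#' @param steps 1 for a single sigmoid, 2 for the double sigmoid (bell-shaped
#'   curves with two separable inflections).
#' @param start Optional named list of starting values overriding the
#'   automatic initialisation.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An `itc_fit` object: list with `params` (named estimates), `se`
#'   (standard errors), `vcov`, `sigma` (residual standard deviation),
#'   `residuals`, `steps`, `curve`, and the underlying `nls` fit.
#' @export
fit_enthalpogram <- function(curve, steps = 1L, start = NULL, max_iter = 200L) {
  stopifnot(steps %in% c(1L, 2L))
  conc <- curve$conc
  dh <- curve$dh
  if (steps == 1 && length(conc) < 8)
    stop("at least 8 points are required for a single-sigmoid fit", call. = FALSE)
  if (steps == 2 && length(conc) < 14)
    stop("at least 14 points are required for a double-sigmoid fit", call. = FALSE)
  w <- if (!is.null(curve[["sigma"]])) 1 / curve[["sigma"]]^2 else rep(1, length(conc))

  if (steps == 1) {
    st <- if (is.null(start)) init_single(conc, dh) else start
    fml <- dh ~ eval_sigmoid(conc, c(h_ia = h_ia, h_ib = h_ib, h_fa = h_fa,
                                     h_fb = h_fb, cmc = cmc, width = width, n = n))
    lower <- c(h_ia = -Inf, h_ib = -Inf, h_fa = -Inf, h_fb = -Inf,
               cmc = min(conc), width = diff(range(conc)) * 1e-5, n = 0.05)
    upper <- c(h_ia = Inf, h_ib = Inf, h_fa = Inf, h_fb = Inf,
               cmc = max(conc), width = diff(range(conc)), n = 20)
  } else {
    st <- if (is.null(start)) init_double(conc, dh) else start
    fml <- dh ~ eval_double_raw(conc, list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                                           a3 = a3, b3 = b3, c1 = c1, w1 = w1,
                                           n1 = n1, c2 = c2, w2 = w2, n2 = n2))
    rng <- range(conc)
    lower <- c(a1 = -Inf, b1 = -Inf, a2 = -Inf, b2 = -Inf, a3 = -Inf, b3 = -Inf,
               c1 = rng[1], w1 = diff(rng) * 1e-5, n1 = 0.05,
               c2 = rng[1], w2 = diff(rng) * 1e-5, n2 = 0.05)
    upper <- c(a1 = Inf, b1 = Inf, a2 = Inf, b2 = Inf, a3 = Inf, b3 = Inf,
               c1 = rng[2], w1 = diff(rng), n1 = 20,
               c2 = rng[2], w2 = diff(rng), n2 = 20)
  }

  dat <- data.frame(conc = conc, dh = dh)
  attempt <- function(start_values)
    tryCatch(minpack.lm::nlsLM(fml, data = dat, start = start_values, weights = w,
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(maxiter = max_iter)),
             error = function(e) e)
  # deterministic multi-start: the automatic initialisation, then width
  # rescalings that unstick saturated steps
  widths <- intersect(c("width", "w1", "w2"), names(st))
  variants <- list(st,
                   modifyList(st, setNames(as.list(unlist(st[widths]) * 3), widths)),
                   modifyList(st, setNames(as.list(unlist(st[widths]) / 3), widths)))
  fit <- NULL
  last_err <- NULL
  for (v in variants) {
    res <- attempt(v)
    if (!inherits(res, "error")) { fit <- res; break }
    last_err <- res
  }
  if (is.null(fit))
    stop(sprintf("enthalpogram fit failed to converge: %s",
                 conditionMessage(last_err)), call. = FALSE)

  params <- coef(fit)
  centres <- if (steps == 1) params[["cmc"]] else c(params[["c1"]], params[["c2"]])
  if (any(centres <= min(conc)) || any(centres >= max(conc)))
    stop("fitted transition centre lies outside the data range", call. = FALSE)
  if (steps == 2 && params[["c1"]] >= params[["c2"]])
    stop("double-sigmoid centres collapsed (c1 >= c2)", call. = FALSE)

  sm <- summary(fit)
  structure(list(params = params, se = sm$coefficients[, "Std. Error"],
                 vcov = vcov(fit), sigma = sm$sigma,
                 residuals = as.numeric(residuals(fit)),
                 steps = steps, curve = curve, fit = fit),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  kind <- if (x$steps == 1) "single-sigmoid" else "double-sigmoid"
  cat(sprintf("ITC %s fit (weighted residual sd %.4g)\n", kind, x$sigma))
  est <- cbind(estimate = x$params, std_error = x$se)
  print(round(est, 6))
  invisible(x)
}

# derivative-based initialisation ------------------------------------------

smoothed_derivative <- function(conc, dh) {
  d <- diff(dh) / diff(conc)
  mid <- (conc[-1] + conc[-length(conc)]) / 2
  if (length(d) >= 7) d <- stats::filter(d, rep(1 / 5, 5), sides = 2)
  d[is.na(d)] <- 0
  list(mid = mid, d = as.numeric(d))
}

init_single <- function(conc, dh) {
  k <- max(3L, round(length(conc) / 4))
  pre <- lm(dh ~ conc, data = data.frame(conc = head(conc, k), dh = head(dh, k)))
  post <- lm(dh ~ conc, data = data.frame(conc = tail(conc, k), dh = tail(dh, k)))
  der <- smoothed_derivative(conc, dh)
  peak <- which.max(abs(der$d))
  centre <- der$mid[peak]
  # width from the spread of the derivative peak above half its maximum
  above <- which(abs(der$d) > abs(der$d[peak]) / 2)
  width <- max(diff(range(der$mid[above])) / 4, diff(range(conc)) / 50)
  list(h_ia = unname(coef(pre)[1]), h_ib = unname(coef(pre)[2]),
       h_fa = unname(coef(post)[1]), h_fb = unname(coef(post)[2]),
       cmc = centre, width = width, n = 1)
}

init_double <- function(conc, dh) {
  der <- smoothed_derivative(conc, dh)
  # two strongest derivative extrema, separated by at least a fifth of range
  ord <- order(-abs(der$d))
  p1 <- ord[1]
  min_sep <- diff(range(conc)) / 5
  p2 <- ord[which(abs(der$mid[ord] - der$mid[p1]) > min_sep)[1]]
  if (is.na(p2)) p2 <- ord[2]
  cs <- sort(c(der$mid[p1], der$mid[p2]))
  w0 <- diff(range(conc)) / 40
  # baseline segments that stay clear of both transition regions
  line_fit <- function(mask, fallback_mask) {
    if (sum(mask) < 3) mask <- fallback_mask
    if (sum(mask) < 2) mask <- rep(TRUE, length(conc))
    cf <- coef(lm(dh ~ conc, data = data.frame(conc = conc[mask], dh = dh[mask])))
    cf[is.na(cf)] <- 0
    unname(cf)
  }
  pre <- line_fit(conc < cs[1] - 3 * w0, seq_along(conc) <= 3)
  post <- line_fit(conc > cs[2] + 3 * w0, seq_along(conc) > length(conc) - 3)
  mid <- line_fit(conc > cs[1] + 3 * w0 & conc < cs[2] - 3 * w0,
                  conc > cs[1] & conc < cs[2])
  list(a1 = pre[1], b1 = pre[2], a2 = mid[1], b2 = mid[2],
       a3 = post[1], b3 = post[2],
       c1 = cs[1], w1 = w0, n1 = 1, c2 = cs[2], w2 = w0, n2 = 1)
}

#' Confidence interval for a fitted parameter
#'
#' Wald interval `estimate +- t_{1-a/2, df} * se` from the least-squares fit.
#'
#' @param fit An `itc_fit`.
#' @param param Parameter name (e.g. `"cmc"`, `"c1"`, `"c2"`).
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
confint_param <- function(fit, param, level = 0.95) {
  est <- fit$params[[param]]
  se <- fit$se[[param]]
  df <- length(fit$residuals) - length(fit$params)
  tq <- qt(1 - (1 - level) / 2, df)
  c(lower = est - tq * se, upper = est + tq * se)
}
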