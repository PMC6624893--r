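#' Residual diagnostics of a fit
#'
#' Computes the fit residuals `v_i - v(t_i)`, their standard deviation
#' (denominator n - 1), a two-sided sign test for median 0, and the
#' Anderson-Darling and Cramer-von Mises tests for normality. Least
#' squares implicitly assumes normal residuals, so these tests probe
#' whether SSE was an appropriate loss. The normality tests are the
#' composite variants (mean and SD estimated from the sample), the only
#' defensible choice for residuals of a fitted curve; they require at
#' least 8 residuals and are reported as `NA` (with a notice) below
#' that.
#'
#' @param fit A `bp_fit` (or [bp_params()]) fitted to `data`.
#' @param data The fitted [growth_dataset()].
#' @return An object of class `residual_report`: list with `residuals`,
#'   `sd`, `sign_test_p`, `anderson_darling_p`, `cramer_von_mises_p`.
#' @examples
#' tumor <- load_dataset("tumor")
#' pars <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
#' residual_report(pars, tumor)
#' @export
residual_report <- function(fit, data) {
  params <- if (inherits(fit, "bp_fit")) fit$params else fit
  stopifnot(inherits(params, "bp_params"), inherits(data, "growth_dataset"))
  r <- data$volumes - solve_curve(params, data$times)
  n <- length(r)
  nonzero <- r[r != 0]
  sign_p <- if (n >= 3L && length(nonzero) > 0L) {
    binom.test(sum(nonzero > 0), length(nonzero))$p.value
  } else if (n >= 3L) {
    1 # all residuals exactly zero: perfectly balanced
  } else {
    NA_real_
  }
  if (n >= 8L && sd(r) > 0) {
    ad_p <- nortest::ad.test(r)$p.value
    cvm_p <- suppressWarnings(nortest::cvm.test(r)$p.value)
  } else {
    if (n < 8L) message("fewer than 8 residuals: normality tests skipped")
    ad_p <- cvm_p <- NA_real_
  }
  structure(
    list(residuals = as.numeric(r), sd = sd(r), sign_test_p = sign_p,
         anderson_darling_p = ad_p, cramer_von_mises_p = cvm_p),
    class = "residual_report"
  )
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> n = %d, residual SD = %.4g mm^3\n",
              length(x$residuals), x$sd))
  cat(sprintf("  sign test (median 0): p = %.3g\n", x$sign_test_p))
  cat(sprintf("  normality: Anderson-Darling p = %.3g, Cramer-von Mises p = %.3g\n",
              x$anderson_darling_p, x$cramer_von_mises_p))
  invisible(x)
}

#' Cubic-spline interpolation of a growth dataset
#'
#' Natural cubic spline through all observations (exact at the knots,
#' zero second derivative at the boundary). The spline provides a
#' model-free interpolation of the data and, via its derivative, a
#' numeric differentiation of the series.
#'
#' @param data A [growth_dataset()] with at least 3 observations.
#' @param method Spline boundary handling: `"natural"` (default) or
#'   `"fmm"` (the not-a-knot-like Forsythe-Malcolm-Moler end condition).
#' @return An interpolating function `f(t, deriv = 0)`.
#' @examples
#' tumor <- load_dataset("tumor")
#' s <- spline_interpolate(tumor)
#' s(50)
#' @export
spline_interpolate <- function(data, method = c("natural", "fmm")) {
  stopifnot(inherits(data, "growth_dataset"))
  method <- match.arg(method)
  if (length(data) < 3L) {
    stop("spline interpolation needs at least 3 observations", call. = FALSE)
  }
  if (anyDuplicated(data$times)) {
    stop("duplicate observation times", call. = FALSE)
  }
  splinefun(data$times, data$volumes, method = method)
}

#' Relative growth rate from the spline interpolation
#'
#' Numeric differentiation of the data: evaluates `s'(t) / s(t)` with
#' `s` the cubic-spline interpolant, in 1/day. Where the spline value is
#' non-positive (possible between knots for wiggly data) the rate is
#' flagged as `NA` with a warning.
#'
#' @param data A [growth_dataset()].
#' @param times Evaluation times (days).
#' @param method Spline variant, see [spline_interpolate()].
#' @return Numeric vector of rates (per day).
#' @export
spline_rgr <- function(data, times, method = "natural") {
  s <- spline_interpolate(data, method = method)
  v <- s(times)
  rate <- s(times, deriv = 1) / v
  bad <- v <= 0
  if (any(bad)) {
    warning(sprintf("spline non-positive at %d requested time(s); rate flagged NA",
                    sum(bad)))
    rate[bad] <- NA_real_
  }
  rate
}

#' Relative-growth-rate envelope over near-optimal models
#'
#' For every near-optimal exponent pair of the landscape (threshold as
#' in [near_optimal_region()]), evaluates the relative growth rate of
#' its best-fit curve along `times` and returns the pointwise minimum
#' and maximum, together with the best-fit model's own rate. The band
#' visualizes how much the growth-rate history is constrained by the
#' data: models fitting almost equally well can imply different
#' metabolism histories.
#'
#' @param landscape A `bp_landscape`.
#' @param threshold Relative SSE excess defining near-optimality.
#' @param times Evaluation times (days); each curve is anchored at
#'   `times[1]`, so start the mesh at the fitted dataset's first
#'   observation time.
#' @return Data frame with columns `time`, `lower`, `upper`, `best`
#'   (rates per day).
#' @export
rgr_envelope <- function(landscape, threshold, times) {
  stopifnot(inherits(landscape, "bp_landscape"))
  reg <- near_optimal_region(landscape, threshold)
  res <- landscape$results
  key <- paste(reg$a, reg$b)
  sel <- res[paste(res$a, res$b) %in% key, , drop = FALSE]
  rates <- sapply(seq_len(nrow(sel)), function(i) {
    params <- bp_params(sel$a[i], sel$b[i], p = sel$p[i], q = sel$q[i],
                        v0 = sel$v0[i])
    relative_growth_rate(params, times, on_failure = "na")
  })
  rates <- matrix(rates, nrow = length(times))
  best <- best_pair(landscape)
  data.frame(
    time = times,
    lower = apply(rates, 1L, min, na.rm = TRUE),
    upper = apply(rates, 1L, max, na.rm = TRUE),
    best = relative_growth_rate(best$fit$params, times, on_failure = "na")
  )
}

# finite-difference Jacobian of the model curve w.r.t. (ln p, ln q, ln v0)
.curve_jacobian <- function(params, times, t0 = times[1L], h = 1e-6) {
  lp <- log(c(params$p, params$q, params$v0))
  J <- matrix(NA_real_, nrow = length(times), ncol = 3L)
  for (j in 1:3) {
    up <- lp
    dn <- lp
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    vu <- solve_curve(bp_params(params$a, params$b, p = exp(up[1L]),
                                q = exp(up[2L]), v0 = exp(up[3L])),
                      times, t0 = t0, on_failure = "na")
    vd <- solve_curve(bp_params(params$a, params$b, p = exp(dn[1L]),
                                q = exp(dn[2L]), v0 = exp(dn[3L])),
                      times, t0 = t0, on_failure = "na")
    J[, j] <- (vu - vd) / (2 * h)
  }
  J
}

#' Single-observation prediction band of a fitted curve
#'
#' Delta-method/t band for one new observation: at each requested time
#' `curve +/- t_{df} * s * sqrt(1 + leverage)`, with `s^2` the residual
#' variance (SSE / (n - 3), three free parameters), and the leverage
#' `g' (J'J)^{-1} g` computed from the finite-difference Jacobian of the
#' curve with respect to the log-parameters. If the Jacobian
#' cross-product is singular the leverage term is dropped and the band
#' is flagged via the attribute `leverage_dropped`.
#'
#' @param fit A `bp_fit` fitted to `data` (ideally polished).
#' @param data The fitted [growth_dataset()].
#' @param confidence Band confidence level (default 0.95).
#' @param times Evaluation times (default: the observation times).
#' @return Data frame with columns `time`, `fit`, `lower`, `upper`.
#' @examples
#' tumor <- load_dataset("tumor")
#' pars <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
#' fit <- polish_fit(c(1.62, 2.44), tumor, pars)
#' band <- prediction_band(fit, tumor)
#' all(tumor$volumes >= band$lower & tumor$volumes <= band$upper)
#' @export
prediction_band <- function(fit, data, confidence = 0.95, times = NULL) {
  stopifnot(inherits(fit, "bp_fit"), inherits(data, "growth_dataset"),
            confidence > 0, confidence < 1)
  if (is.null(times)) times <- data$times
  n <- length(data)
  df_resid <- n - 3L
  if (df_resid < 1L) stop("need more than 3 observations", call. = FALSE)
  s2 <- fit$sse / df_resid
  t0 <- min(data$times[1L], times[1L])
  J <- .curve_jacobian(fit$params, data$times, t0 = t0)
  JtJ <- crossprod(J)
  Ji <- tryCatch(solve(JtJ), error = function(e) NULL)
  G <- .curve_jacobian(fit$params, times, t0 = t0)
  leverage_dropped <- FALSE
  if (is.null(Ji) || anyNA(J) || anyNA(G)) {
    lev <- rep(0, length(times))
    leverage_dropped <- TRUE
    warning("singular or invalid Jacobian; leverage term dropped from the band")
  } else {
    lev <- rowSums((G %*% Ji) * G)
    lev[lev < 0] <- 0
  }
  v <- solve_curve(fit$params, times, t0 = t0)
  half <- qt(1 - (1 - confidence) / 2, df_resid) * sqrt(s2 * (1 + lev))
  out <- data.frame(time = times, fit = as.numeric(v),
                    lower = as.numeric(v - half),
                    upper = as.numeric(v + half))
  attr(out, "leverage_dropped") <- leverage_dropped
  out
}
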