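#' Exponent pair identifying one Bertalanffy-Puetter model
#'
#' The pair (a, b) with `0 <= a < b` selects one member of the
#' Bertalanffy-Puetter family `dv/dt = p*v^a - q*v^b`. Named growth
#' models are special pairs: exponential (0, 1), von Bertalanffy
#' (2/3, 1), Verhulst/logistic (1, 2). The diagonal `a = b`
#' (Gompertz-type limit) is excluded; a minimal separation
#' `b - a >= 1e-6` is enforced so that power-of-ratio formulas stay
#' well defined.
#'
#' @param a,b Non-negative exponents with `a < b`.
#' @return An object of class `exponent_pair`.
#' @examples
#' exponent_pair(1, 2)      # Verhulst
#' exponent_pair(2 / 3, 1)  # von Bertalanffy
#' @export
exponent_pair <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || !is.finite(b) || a < 0) {
    stop("exponents must be finite with a >= 0", call. = FALSE)
  }
  if (b - a < 1e-6) {
    stop("need a < b (b - a >= 1e-6); the diagonal a = b is excluded",
         call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "exponent_pair")
}

#' @export
print.exponent_pair <- function(x, ...) {
  cat(sprintf("<exponent_pair> (a = %g, b = %g)\n", x$a, x$b))
  invisible(x)
}

.as_pair <- function(pair) {
  if (inherits(pair, "exponent_pair")) return(pair)
  if (is.numeric(pair) && length(pair) == 2L) {
    return(exponent_pair(pair[1L], pair[2L]))
  }
  stop("'pair' must be an exponent_pair or a numeric length-2 vector",
       call. = FALSE)
}

#' Full Bertalanffy-Puetter parameter set
#'
#' Bundles an exponent pair with the three free parameters of its model:
#' growth coefficient `p` (mm^3^(1-a)/day), decay coefficient `q`
#' (mm^3^(1-b)/day) and the volume `v0` (mm^3) at the first observation
#' time. All three are strictly positive in the fitted model class
#' (positivity yields bounded growth curves); `q` can be extremely small
#' (down to ~1e-34 for large `b`), which doubles handle natively.
#'
#' @param a,b Exponents (or pass an `exponent_pair` as `a`).
#' @param p,q,v0 Positive model parameters.
#' @return An object of class `bp_params` with fields `a, b, p, q, v0`.
#' @examples
#' bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
#' @export
bp_params <- function(a, b = NULL, p, q, v0) {
  if (inherits(a, "exponent_pair")) {
    pair <- a
  } else {
    pair <- exponent_pair(a, b)
  }
  stopifnot(is.numeric(p), is.numeric(q), is.numeric(v0),
            length(p) == 1L, length(q) == 1L, length(v0) == 1L)
  if (!is.finite(p) || !is.finite(q) || !is.finite(v0) ||
      p <= 0 || q <= 0 || v0 <= 0) {
    stop("p, q and v0 must be finite and strictly positive", call. = FALSE)
  }
  structure(list(a = pair$a, b = pair$b, p = as.numeric(p),
                 q = as.numeric(q), v0 = as.numeric(v0)),
            class = "bp_params")
}

#' @export
print.bp_params <- function(x, ...) {
  cat(sprintf("<bp_params> (a = %g, b = %g): p = %.6g, q = %.6g, v0 = %.6g\n",
              x$a, x$b, x$p, x$q, x$v0))
  invisible(x)
}

#' Growth-rate right-hand side of the Bertalanffy-Puetter ODE
#'
#' Evaluates `dv/dt = p * v^a - q * v^b` at the given volume(s).
#'
#' @param v Volume(s) in mm^3, strictly positive.
#' @param params A [bp_params()] set.
#' @return Growth rate(s) in mm^3/day.
#' @examples
#' pars <- bp_params(1, 2, p = 0.5, q = 0.2, v0 = 1)
#' bp_rhs(1, pars)  # 0.3
#' @export
bp_rhs <- function(v, params) {
  stopifnot(inherits(params, "bp_params"))
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("'v' must be finite and strictly positive", call. = FALSE)
  }
  params$p * v^params$a - params$q * v^params$b
}

#' Solve a Bertalanffy-Puetter model curve
#'
#' Integrates `dv/dt = p*v^a - q*v^b` with `v(times[1]) = v0` and returns
#' the volume at each requested time. The curve is anchored at the first
#' requested time, matching the fitting convention that `v0` is the
#' volume at the first observation. Integration is performed in
#' log-volume (`u = ln v`) with an adaptive Dormand-Prince 4(5) scheme,
#' which preserves positivity and remains stable when `b` is large and
#' `q` tiny.
#'
#' @param params A [bp_params()] set.
#' @param times Requested times (days), sorted ascending.
#' @param t0 Anchor time at which `v(t0) = v0`; defaults to `times[1]`.
#'   Set it to the dataset's first observation time when evaluating a
#'   fitted curve on a different time mesh.
#' @param rtol,atol Relative/absolute integration tolerances (log space).
#' @param max_steps Step-count cap before the integration is declared
#'   failed.
#' @param on_failure `"error"` (default) raises a diagnostic error on
#'   integration failure; `"na"` returns all-`NA` with attribute
#'   `failed = TRUE`.
#' @return Numeric vector of volumes (mm^3) at `times`.
#' @examples
#' pars <- bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 100)
#' solve_curve(pars, c(0, 25, 50, 100))
#' @export
solve_curve <- function(params, times, t0 = NULL, rtol = 1e-8, atol = 1e-10,
                        max_steps = 10000L, on_failure = c("error", "na")) {
  stopifnot(inherits(params, "bp_params"), is.numeric(times),
            length(times) >= 1L)
  on_failure <- match.arg(on_failure)
  if (is.unsorted(times)) {
    stop("'times' must be sorted ascending", call. = FALSE)
  }
  tt <- as.numeric(times)
  prepended <- FALSE
  if (!is.null(t0)) {
    if (t0 > tt[1L]) {
      stop("'t0' must not exceed the first requested time", call. = FALSE)
    }
    if (t0 < tt[1L]) {
      tt <- c(t0, tt)
      prepended <- TRUE
    }
  }
  v <- .bp_solve_cpp(params$a, params$b, params$p, params$q, params$v0,
                     tt, rtol, atol, as.integer(max_steps))
  failed <- isTRUE(attr(v, "failed"))
  v <- as.numeric(if (prepended) v[-1L] else v)
  if (failed) attr(v, "failed") <- TRUE
  if (isTRUE(attr(v, "failed")) && on_failure == "error") {
    stop(sprintf(paste0("curve integration failed for (a=%g, b=%g, p=%g, ",
                        "q=%g, v0=%g): overflow or step budget exhausted"),
                 params$a, params$b, params$p, params$q, params$v0),
         call. = FALSE)
  }
  v
}

#' Asymptotic (limiting) volume of a model curve
#'
#' For positive p, q the curve is bounded and approaches the equilibrium
#' of the ODE, `(p/q)^(1/(b-a))`, as t grows; this is the carrying
#' capacity. Computed in log space; if it exceeds the double range,
#' `Inf` is returned with a warning (effectively unbounded growth on any
#' relevant horizon, typical for near-diagonal pairs).
#'
#' @param params A [bp_params()] set.
#' @return Asymptotic volume in mm^3.
#' @examples
#' asymptotic_volume(bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 50))  # 1000
#' @export
asymptotic_volume <- function(params) {
  stopifnot(inherits(params, "bp_params"))
  lv <- (log(params$p) - log(params$q)) / (params$b - params$a)
  if (lv > log(.Machine$double.xmax)) {
    warning("asymptotic volume exceeds double range; returning Inf")
    return(Inf)
  }
  exp(lv)
}

#' Volume at the inflection point of a model curve
#'
#' The growth rate `p*v^a - q*v^b` is maximal at
#' `v = (a*p / (b*q))^(1/(b-a))`, the volume where the curve's second
#' derivative vanishes. Requires `a > 0` (for `a = 0` the rate is
#' maximal at `v -> 0` and no interior inflection exists).
#'
#' @param params A [bp_params()] set with `a > 0`.
#' @return Inflection volume in mm^3.
#' @examples
#' inflection_volume(bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 50))  # 500
#' @export
inflection_volume <- function(params) {
  stopifnot(inherits(params, "bp_params"))
  if (params$a <= 0) {
    stop("inflection volume requires a > 0", call. = FALSE)
  }
  lv <- (log(params$a * params$p) - log(params$b * params$q)) /
    (params$b - params$a)
  if (lv > log(.Machine$double.xmax)) {
    warning("inflection volume exceeds double range; returning Inf")
    return(Inf)
  }
  exp(lv)
}

#' Relative growth rate along a model curve
#'
#' Evaluates `v'/v = p*v^(a-1) - q*v^(b-1)` along the solution curve at
#' the requested times, in units of 1/day (multiply by 100 for
#' percent/day). The relative growth rate is the metabolism-linked
#' per-capita growth speed.
#'
#' @inheritParams solve_curve
#' @return Numeric vector of rates (per day) at `times`.
#' @examples
#' pars <- bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 100)
#' relative_growth_rate(pars, c(0, 50, 100))
#' @export
relative_growth_rate <- function(params, times, t0 = NULL, rtol = 1e-8,
                                 atol = 1e-10, max_steps = 10000L,
                                 on_failure = c("error", "na")) {
  v <- solve_curve(params, times, t0 = t0, rtol = rtol, atol = atol,
                   max_steps = max_steps, on_failure = on_failure)
  params$p * v^(params$a - 1) - params$q * v^(params$b - 1)
}
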