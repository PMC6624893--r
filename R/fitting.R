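#' Annealing configuration
#'
#' Controls the multiplicative simulated-annealing scheme used to
#' minimize SSE over (p, q, v0) for one exponent pair. Defaults mirror
#' the reference procedure: 50,000 steps for a cold start at the first
#' pair of each grid row, 10,000 steps for warm starts along increasing
#' b, and a restart from the best-seen parameters every 1,000 steps with
#' adaptive cooling.
#'
#' @param steps_cold_start Annealing steps for a cold start (default
#'   50,000).
#' @param steps_warm_start Annealing steps when starting from a previous
#'   fit (default 10,000).
#' @param restart_interval Steps between restarts from the best-seen
#'   parameters (default 1,000); cooling is applied at each restart.
#' @param perturbation_scale Width sigma of the log-normal multiplicative
#'   proposal `exp(sigma * Z)` (default 0.05).
#' @param initial_acceptance Target initial probability of accepting an
#'   uphill move (default 0.3); calibrates the starting temperature from
#'   probe proposals.
#' @param seed Optional integer seed; when set, fits are bit-reproducible.
#' @param rtol,atol,max_steps Curve-integration controls, as in
#'   [solve_curve()]. The default step cap is tighter than
#'   [solve_curve()]'s so that infeasible proposals (which the annealer
#'   simply rejects) fail fast.
#' @param fast_factor Integer >= 1 dividing both step budgets; useful for
#'   coarse exploratory sweeps where full budgets are unnecessary.
#' @return An object of class `anneal_config`.
#' @examples
#' anneal_config()                  # full budgets
#' anneal_config(fast_factor = 10)  # 5,000 / 1,000 steps
#' @export
anneal_config <- function(steps_cold_start = 50000L,
                          steps_warm_start = 10000L,
                          restart_interval = 1000L,
                          perturbation_scale = 0.05,
                          initial_acceptance = 0.3,
                          seed = NULL,
                          rtol = 1e-8, atol = 1e-10, max_steps = 2000L,
                          fast_factor = 1L) {
  stopifnot(steps_cold_start >= 0, steps_warm_start >= 0,
            restart_interval > 0, perturbation_scale > 0,
            initial_acceptance > 0, initial_acceptance < 1,
            fast_factor >= 1)
  structure(
    list(steps_cold_start = as.integer(round(steps_cold_start / fast_factor)),
         steps_warm_start = as.integer(round(steps_warm_start / fast_factor)),
         restart_interval = as.integer(restart_interval),
         perturbation_scale = perturbation_scale,
         initial_acceptance = initial_acceptance,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         rtol = rtol, atol = atol, max_steps = as.integer(max_steps)),
    class = "anneal_config"
  )
}

.new_fit_result <- function(params, sse, n_points, polished, anneal_steps,
                            seed, converged) {
  structure(
    list(params = params, sse = sse, n_points = as.integer(n_points),
         polished = isTRUE(polished), anneal_steps = as.integer(anneal_steps),
         seed = seed, converged = isTRUE(converged)),
    class = "bp_fit"
  )
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("<bp_fit> (a = %g, b = %g)\n", x$params$a, x$params$b))
  cat(sprintf("  p = %.6g, q = %.6g, v0 = %.6g\n",
              x$params$p, x$params$q, x$params$v0))
  cat(sprintf("  SSE = %.5g over %d points (%s, %d annealing steps)\n",
              x$sse, x$n_points,
              if (x$polished) "polished" else "annealing only",
              x$anneal_steps))
  invisible(x)
}

#' Sum of squared errors of a model curve against data
#'
#' Computes `SSE = sum_i (v_i - v(t_i))^2` where `v(t)` is the model
#' curve anchored at the first observation time. A failed curve
#' integration yields `Inf` (the annealer then rejects the candidate).
#'
#' @param params A [bp_params()] set.
#' @param data A [growth_dataset()].
#' @param rtol,atol,max_steps Integration controls as in [solve_curve()].
#' @return SSE in mm^6 (`Inf` if the curve cannot be integrated).
#' @examples
#' tumor <- load_dataset("tumor")
#' pars <- bp_params(1.62, 2.44, p = 5.02e-4, q = 5.55e-7, v0 = 318.5)
#' sse_of(pars, tumor)
#' @export
sse_of <- function(params, data, rtol = 1e-8, atol = 1e-10,
                   max_steps = 10000L) {
  stopifnot(inherits(params, "bp_params"), inherits(data, "growth_dataset"))
  .bp_sse_cpp(params$a, params$b, params$p, params$q, params$v0,
              data$times, data$volumes, rtol, atol, as.integer(max_steps))
}

#' Simulated-annealing fit of one exponent pair
#'
#' Minimizes SSE over (p, q, v0) for the fixed exponent pair by a
#' multiplicative simulated-annealing scheme: each step multiplies every
#' parameter by a positive log-normal factor close to 1 (which preserves
#' positivity and is scale-free across the many orders of magnitude that
#' q spans), accepts downhill moves always and uphill moves with
#' Metropolis probability, restarts from the best-seen parameters every
#' `restart_interval` steps, and cools the temperature adaptively based
#' on the recent uphill-acceptance rate.
#'
#' Without a `start`, the chain begins at `p = q = 1` and `v0 = v1` (the
#' first observed volume) and uses the cold-start step budget; with a
#' `start` (e.g. the previous grid point's optimum) the warm-start
#' budget applies.
#'
#' @param pair An [exponent_pair()] (or numeric length-2 vector).
#' @param data A [growth_dataset()].
#' @param config An [anneal_config()].
#' @param start Optional [bp_params()] warm-start (its exponents are
#'   replaced by `pair`).
#' @param steps Optional explicit step budget overriding the config.
#' @return A `bp_fit` result (best-seen parameters and SSE;
#'   `converged = FALSE` if every candidate curve failed to integrate).
#' @examples
#' tumor <- load_dataset("tumor")
#' fit <- anneal_fit(c(1, 2), tumor,
#'                   anneal_config(fast_factor = 50, seed = 1))
#' fit$sse
#' @export
anneal_fit <- function(pair, data, config = anneal_config(), start = NULL,
                       steps = NULL) {
  pair <- .as_pair(pair)
  stopifnot(inherits(data, "growth_dataset"),
            inherits(config, "anneal_config"))
  if (is.null(start)) {
    start_vec <- c(p = 1, q = 1, v0 = data$volumes[1L])
    n_steps <- if (is.null(steps)) config$steps_cold_start else steps
  } else {
    stopifnot(inherits(start, "bp_params"))
    start_vec <- c(p = start$p, q = start$q, v0 = start$v0)
    n_steps <- if (is.null(steps)) config$steps_warm_start else steps
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .bp_anneal_cpp(pair$a, pair$b, data$times, data$volumes,
                        as.numeric(start_vec), as.integer(n_steps),
                        config$restart_interval, config$perturbation_scale,
                        config$initial_acceptance, config$rtol, config$atol,
                        config$max_steps)
  params <- bp_params(pair, p = res$p, q = res$q, v0 = res$v0)
  .new_fit_result(params, res$sse, length(data), polished = FALSE,
                  anneal_steps = n_steps, seed = config$seed,
                  converged = res$converged)
}

#' Deterministic least-squares polish of a fit
#'
#' Refines a candidate (typically the annealer's output) by
#' Levenberg-Marquardt least squares on the log-parameters
#' (ln p, ln q, ln v0), which keeps the parameters positive and
#' conditions the tiny-q regimes. The loss is exactly the SSE of
#' [sse_of()]. If the optimizer fails or does not improve, the start is
#' returned unchanged with `polished = FALSE`.
#'
#' @param pair An [exponent_pair()] (or numeric length-2 vector).
#' @param data A [growth_dataset()].
#' @param start A [bp_params()] or `bp_fit` to refine.
#' @param rtol,atol,max_steps Integration controls as in [solve_curve()].
#' @return A `bp_fit` with `sse` no larger than the start's.
#' @examples
#' tumor <- load_dataset("tumor")
#' rough <- bp_params(1.62, 2.44, p = 6e-4, q = 6e-7, v0 = 300)
#' polish_fit(c(1.62, 2.44), tumor, rough)$sse
#' @export
polish_fit <- function(pair, data, start, rtol = 1e-8, atol = 1e-10,
                       max_steps = 10000L) {
  pair <- .as_pair(pair)
  stopifnot(inherits(data, "growth_dataset"))
  if (inherits(start, "bp_fit")) start <- start$params
  stopifnot(inherits(start, "bp_params"))
  start <- bp_params(pair, p = start$p, q = start$q, v0 = start$v0)
  sse_start <- sse_of(start, data, rtol, atol, max_steps)

  resid_fn <- function(lp) {
    v <- .bp_solve_cpp(pair$a, pair$b, exp(lp[1L]), exp(lp[2L]), exp(lp[3L]),
                       data$times, rtol, atol, as.integer(max_steps))
    r <- data$volumes - v
    r[!is.finite(r)] <- 1e12
    r
  }
  lm_res <- tryCatch(
    minpack.lm::nls.lm(par = log(c(start$p, start$q, start$v0)),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (!is.null(lm_res) && all(is.finite(lm_res$par))) {
    cand <- tryCatch(
      bp_params(pair, p = exp(lm_res$par[1L]), q = exp(lm_res$par[2L]),
                v0 = exp(lm_res$par[3L])),
      error = function(e) NULL
    )
    if (!is.null(cand)) {
      sse_cand <- sse_of(cand, data, rtol, atol, max_steps)
      if (is.finite(sse_cand) && sse_cand <= sse_start) {
        return(.new_fit_result(cand, sse_cand, length(data), polished = TRUE,
                               anneal_steps = 0L, seed = NULL,
                               converged = TRUE))
      }
    }
  }
  .new_fit_result(start, sse_start, length(data), polished = FALSE,
                  anneal_steps = 0L, seed = NULL,
                  converged = is.finite(sse_start))
}

# Deterministic data-driven starting values for one exponent pair.
# Each start anchors v0 at the first observation, guesses the carrying
# capacity K as a multiple of the largest observed volume, and sets p so
# that the model's initial relative growth rate matches the first
# observed inter-point rate; q then follows from K = (p/q)^(1/(b-a)).
# These are the classic initializations of bounded-growth regression and
# give the local polish a footing in the relevant basin even when the
# stochastic search has not found it.
.heuristic_starts <- function(pair, data, k_factors = c(1.1, 1.5, 3, 10)) {
  v <- data$volumes
  t <- data$times
  v1 <- v[1L]
  r1 <- max((v[2L] - v[1L]) / ((t[2L] - t[1L]) * v[1L]), 1e-4)
  out <- list()
  for (kf in k_factors) {
    K <- kf * max(v)
    denom <- 1 - (v1 / K)^(pair$b - pair$a)
    if (denom <= 0) next
    p <- r1 * v1^(1 - pair$a) / denom
    q <- p / K^(pair$b - pair$a)
    cand <- tryCatch(bp_params(pair, p = p, q = q, v0 = v1),
                     error = function(e) NULL)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Fit one exponent pair: annealing, polish, and multistart safeguard
#'
#' Runs [anneal_fit()] and then [polish_fit()] from its optimum. In
#' addition, a small set of deterministic data-driven starting values
#' (carrying-capacity and initial-slope heuristics) is polished, and the
#' overall best candidate by SSE is returned. The safeguard costs a few
#' hundred curve evaluations -- negligible next to the annealing budget
#' -- and makes the fit robust for exponent pairs far from the diagonal,
#' where a cold stochastic search can stall on the flat-curve plateau of
#' the SSE surface.
#'
#' @inheritParams anneal_fit
#' @param multistart Logical; also polish the deterministic heuristic
#'   starts (default `TRUE`).
#' @return A `bp_fit` whose `sse` is the smallest among all candidates.
#' @examples
#' tumor <- load_dataset("tumor")
#' fit <- fit_pair(c(1, 2), tumor, anneal_config(fast_factor = 50, seed = 1))
#' fit
#' @export
fit_pair <- function(pair, data, config = anneal_config(), start = NULL,
                     steps = NULL, multistart = TRUE) {
  pair <- .as_pair(pair)
  best <- anneal_fit(pair, data, config, start = start, steps = steps)
  if (best$converged) {
    pol <- polish_fit(pair, data, best$params,
                      rtol = config$rtol, atol = config$atol,
                      max_steps = config$max_steps)
    if (pol$sse <= best$sse) {
      pol$anneal_steps <- best$anneal_steps
      pol$seed <- best$seed
      best <- pol
    }
  }
  if (multistart) {
    for (st in .heuristic_starts(pair, data)) {
      cand <- polish_fit(pair, data, st,
                         rtol = config$rtol, atol = config$atol,
                         max_steps = config$max_steps)
      if (cand$converged && (!best$converged || cand$sse < best$sse)) {
        cand$anneal_steps <- best$anneal_steps
        cand$seed <- best$seed
        best <- cand
      }
    }
  }
  best
}
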