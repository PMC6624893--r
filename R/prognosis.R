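#' Fit an initial data segment and assess its extrapolation
#'
#' Truncates the dataset at `cutoff` days, runs a full grid sweep (with
#' boundary extension) on the segment, and evaluates the segment's best
#' model curve over the complete dataset without refitting. This is the
#' core of the prognosis experiment: a model that fits the first part of
#' the series well need not predict its continuation.
#'
#' @param data The full [growth_dataset()].
#' @param cutoff Segment cutoff in days; the segment must retain at
#'   least 4 observations (the model class has 5 free parameters
#'   overall, so shorter segments are refused).
#' @param grid A [grid_spec()] for the segment sweep.
#' @param config An [anneal_config()].
#' @param extend Extend the grid while the optimum sits on its boundary
#'   (default `TRUE`; segment optima often have very large b).
#' @param ... Further arguments passed to [extend_if_boundary()] (e.g.
#'   `increment`, `a_cap`, `b_cap`).
#' @return A list with elements `landscape` (the segment's
#'   `bp_landscape`) and `report` (a `bp_prognosis`, see
#'   [prognosis_report()]).
#' @export
fit_segment <- function(data, cutoff, grid = grid_spec(),
                        config = anneal_config(), extend = TRUE, ...) {
  stopifnot(inherits(data, "growth_dataset"))
  seg <- truncate_dataset(data, cutoff)
  if (length(seg) < 4L) {
    stop(sprintf("segment up to %g days retains only %d observations; >= 4 required",
                 cutoff, length(seg)), call. = FALSE)
  }
  land <- sweep_grid(grid, seg, config)
  if (extend) {
    land <- extend_if_boundary(land, seg, config, ...)
  }
  best <- best_pair(land)
  fit <- polish_fit(best$pair, seg, best$fit$params)
  report <- prognosis_report(fit, data, cutoff)
  list(landscape = land, report = report)
}

#' Build a prognosis report for a segment fit
#'
#' Packages a fit produced on an initial data segment together with its
#' extrapolation over the full dataset: the segment SSE, the
#' all-data SSE of the same (unrefitted) curve, and the per-point
#' prediction residuals.
#'
#' @param fit A `bp_fit` produced on the segment (observations with
#'   `time <= cutoff`).
#' @param full_data The complete [growth_dataset()].
#' @param cutoff The segment cutoff in days.
#' @return An object of class `bp_prognosis` with fields `cutoff`,
#'   `best` (the fit), `sse_segment`, `sse_all`, `times`, `observed`,
#'   `predicted`, `residuals`.
#' @export
prognosis_report <- function(fit, full_data, cutoff) {
  stopifnot(inherits(fit, "bp_fit"), inherits(full_data, "growth_dataset"))
  pred <- solve_curve(fit$params, full_data$times, on_failure = "na")
  resid <- full_data$volumes - pred
  structure(
    list(cutoff = cutoff, best = fit, sse_segment = fit$sse,
         sse_all = extrapolation_sse(fit, full_data),
         times = full_data$times, observed = full_data$volumes,
         predicted = as.numeric(pred), residuals = as.numeric(resid)),
    class = "bp_prognosis"
  )
}

#' @export
print.bp_prognosis <- function(x, ...) {
  cat(sprintf("<bp_prognosis> segment t <= %g days, pair (a = %g, b = %g)\n",
              x$cutoff, x$best$params$a, x$best$params$b))
  cat(sprintf("  SSE(segment) = %.5g, SSE(all) = %.5g\n",
              x$sse_segment, x$sse_all))
  invisible(x)
}

#' Extrapolation SSE of a segment fit over the full series
#'
#' Evaluates the SSE of an already-fitted curve over all observations of
#' the full dataset (no refitting). For a fit produced on a subset this
#' is never smaller than the segment SSE.
#'
#' @param fit A `bp_fit` (or [bp_params()]).
#' @param full_data The complete [growth_dataset()].
#' @return SSE in mm^6 (`Inf` if the curve cannot be integrated over the
#'   extended horizon; a diagnostic warning is then given).
#' @export
extrapolation_sse <- function(fit, full_data) {
  params <- if (inherits(fit, "bp_fit")) fit$params else fit
  stopifnot(inherits(params, "bp_params"),
            inherits(full_data, "growth_dataset"))
  sse <- sse_of(params, full_data)
  if (!is.finite(sse)) {
    warning("curve integration failed over the full horizon; SSE is Inf")
  }
  sse
}

#' Feasible prognosis horizon of segment fits
#'
#' For each report, finds the longest time beyond the segment cutoff for
#' which the predicted volumes stay within `tolerance` relative error of
#' the observations at every intermediate observed point. The summary is
#' the median horizon across segments. A horizon of 0 means the first
#' post-cutoff observation is already missed; `NA` means no observation
#' lies beyond the cutoff.
#'
#' @param reports A list of `bp_prognosis` reports (a single report is
#'   also accepted).
#' @param tolerance Relative volume-error tolerance (default 0.15).
#' @return A list with `horizons` (days, one per report, named by
#'   cutoff) and `median` (days).
#' @export
horizon_assessment <- function(reports, tolerance = 0.15) {
  if (inherits(reports, "bp_prognosis")) reports <- list(reports)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "bp_prognosis")),
            tolerance > 0)
  horizons <- vapply(reports, function(r) {
    beyond <- which(r$times > r$cutoff)
    if (length(beyond) == 0L) return(NA_real_)
    rel_err <- abs(r$residuals[beyond]) / r$observed[beyond]
    bad <- which(!(rel_err < tolerance))
    if (length(bad) == 0L) {
      return(r$times[beyond[length(beyond)]] - r$cutoff)
    }
    if (bad[1L] == 1L) return(0)
    r$times[beyond[bad[1L] - 1L]] - r$cutoff
  }, numeric(1))
  names(horizons) <- vapply(reports, function(r) sprintf("%g", r$cutoff),
                            character(1))
  list(horizons = horizons, median = median(horizons, na.rm = TRUE))
}

#' Tabulate prognosis reports
#'
#' One row per segment with the fitted exponents, parameters, segment
#' SSE and all-data extrapolation SSE.
#'
#' @param reports List of `bp_prognosis` reports.
#' @param path Optional CSV output path.
#' @return Data frame with columns
#'   `cutoff,a,b,v0,p,q,sse_segment,sse_all`.
#' @export
prognosis_table <- function(reports, path = NULL) {
  if (inherits(reports, "bp_prognosis")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(cutoff = r$cutoff, a = r$best$params$a, b = r$best$params$b,
               v0 = r$best$params$v0, p = r$best$params$p,
               q = r$best$params$q, sse_segment = r$sse_segment,
               sse_all = r$sse_all)
  }))
  if (!is.null(path)) {
    out <- df
    for (col in c("v0", "p", "q", "sse_segment", "sse_all")) {
      out[[col]] <- .fmt_num(df[[col]])
    }
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  df
}
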