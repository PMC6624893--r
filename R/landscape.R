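#' Exponent-grid specification
#'
#' Defines the rectangular grid of exponent pairs `a = m * spacing`,
#' `b = a + n * spacing` (integers `m >= 0`, `n >= 1`) searched by
#' [sweep_grid()]. The default region `0 <= a <= 2.1`,
#' `a < b <= 3.1` with spacing 0.01 covers the named growth models
#' (exponential (0, 1), von Bertalanffy (2/3, 1), Verhulst (1, 2), the
#' generalized-Bertalanffy line b = 1 and the Richards line a = 1). An
#' optional `region_mask(a, b)` predicate can carve a non-rectangular
#' search region out of the rectangle.
#'
#' @param spacing Grid step (default 0.01).
#' @param a_min,a_max Inclusive bounds for the first exponent.
#' @param b_max Inclusive upper bound for the second exponent (the lower
#'   bound for b is always `a + spacing`; the diagonal is excluded).
#' @param region_mask Optional vectorized predicate `function(a, b)`
#'   returning `TRUE` for pairs to keep.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(spacing = 0.1, a_max = 2.1, b_max = 3.1)
#' @export
grid_spec <- function(spacing = 0.01, a_min = 0, a_max = 2.1, b_max = 3.1,
                      region_mask = NULL) {
  stopifnot(spacing > 0, a_min >= 0, a_max >= a_min, b_max > a_min)
  structure(
    list(spacing = spacing, a_min = a_min, a_max = a_max, b_max = b_max,
         region_mask = region_mask),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> spacing %g, a in [%g, %g], b in (a, %g], %d pairs\n",
              x$spacing, x$a_min, x$a_max, x$b_max, nrow(grid_pairs(x))))
  invisible(x)
}

#' Enumerate the exponent pairs of a grid
#'
#' @param grid A [grid_spec()].
#' @return A data frame with columns `a`, `b`, ordered as the sweep
#'   visits them (outer loop over a, inner loop over increasing b).
#' @export
grid_pairs <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  s <- grid$spacing
  ms <- seq.int(round(grid$a_min / s), round(grid$a_max / s))
  n_max <- round(grid$b_max / s)
  out <- do.call(rbind, lapply(ms, function(m) {
    if (m + 1L > n_max) return(NULL)
    data.frame(a = m * s, b = seq.int(m + 1L, n_max) * s)
  }))
  if (is.null(out) || nrow(out) == 0L) {
    stop("grid contains no exponent pairs", call. = FALSE)
  }
  if (!is.null(grid$region_mask)) {
    keep <- grid$region_mask(out$a, out$b)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0L) stop("region mask removed all pairs", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

.new_landscape <- function(results, grid, data_label, secured = TRUE) {
  structure(
    list(results = results, grid = grid, data_label = data_label,
         secured = secured),
    class = "bp_landscape"
  )
}

#' @export
print.bp_landscape <- function(x, ...) {
  bp <- best_pair(x)
  cat(sprintf("<bp_landscape> %d exponent pairs fitted to '%s'\n",
              nrow(x$results), x$data_label))
  cat(sprintf("  minimum SSE %.5g at (a = %g, b = %g)%s\n",
              bp$fit$sse, bp$pair$a, bp$pair$b,
              if (x$secured) "" else "  [optimality not secured]"))
  invisible(x)
}

# fit one row of the grid: cold start (full budget + heuristic safeguard)
# at the first b, then warm starts with the reduced budget along b
.sweep_row <- function(a, bs, data, config, polish_each, start = NULL) {
  rows <- vector("list", length(bs))
  prev <- start
  for (i in seq_along(bs)) {
    pair <- exponent_pair(a, bs[i])
    fit <- if (is.null(prev)) {
      fit_pair(pair, data, config, multistart = TRUE)
    } else if (polish_each) {
      fit_pair(pair, data, config, start = prev, multistart = FALSE)
    } else {
      anneal_fit(pair, data, config, start = prev)
    }
    prev <- fit$params
    rows[[i]] <- data.frame(a = pair$a, b = pair$b, v0 = fit$params$v0,
                            p = fit$params$p, q = fit$params$q,
                            sse = fit$sse, polished = fit$polished,
                            converged = fit$converged)
  }
  do.call(rbind, rows)
}

#' Sweep the exponent grid and map the SSE landscape
#'
#' Visits every grid pair with an outer loop over `a` and an inner loop
#' over increasing `b`. The first pair of each row, `(a, a + spacing)`,
#' is fitted cold with the full annealing budget (plus the deterministic
#' multistart safeguard of [fit_pair()]); each subsequent pair along the
#' row is warm-started from the previous pair's optimized parameters
#' with the reduced warm budget. This inner-loop warm starting exploits
#' the continuity of `SSE_opt(a, b)` along the b-direction.
#'
#' @param grid A [grid_spec()].
#' @param data A [growth_dataset()].
#' @param config An [anneal_config()]. If `config$seed` is set, the
#'   whole sweep is seeded once (per-pair fits then draw from one
#'   stream), making the sweep reproducible.
#' @param polish_each Polish every grid fit by Levenberg-Marquardt
#'   (default `TRUE`); with `FALSE` only annealing is used along rows,
#'   mirroring the cheapest possible sweep.
#' @param retry_frayed One-shot refit (5x warm budget) of entries that
#'   fail the neighbor-median smoothness screen of
#'   [landscape_smoothness()] (default `FALSE`).
#' @return A `bp_landscape`: fitted results (columns
#'   `a,b,v0,p,q,sse,polished,converged`), the grid, and provenance.
#' @examples
#' tumor <- load_dataset("tumor")
#' grid <- grid_spec(spacing = 0.5, a_max = 1.5, b_max = 2.5)
#' ls <- sweep_grid(grid, tumor, anneal_config(fast_factor = 50, seed = 1))
#' ls
#' @export
sweep_grid <- function(grid, data, config = anneal_config(),
                       polish_each = TRUE, retry_frayed = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(data, "growth_dataset"),
            inherits(config, "anneal_config"))
  pairs <- grid_pairs(grid)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL # one stream for the whole sweep
  res <- do.call(rbind, lapply(split(pairs, pairs$a), function(df) {
    .sweep_row(df$a[1L], df$b, data, cfg, polish_each)
  }))
  rownames(res) <- NULL
  res <- res[order(res$a, res$b), , drop = FALSE]
  land <- .new_landscape(res, grid, data$label)
  if (retry_frayed) {
    land <- .retry_frayed(land, data, cfg)
  }
  land
}

# refit smoothness violators once with a 5x warm budget, keeping
# improvements only
.retry_frayed <- function(landscape, data, config) {
  viol <- landscape_smoothness(landscape)
  viol <- viol[!viol$ok, , drop = FALSE]
  if (nrow(viol) == 0L) return(landscape)
  res <- landscape$results
  for (i in seq_len(nrow(viol))) {
    j <- which(res$a == viol$a[i] & res$b == viol$b[i])
    start <- bp_params(res$a[j], res$b[j], p = res$p[j], q = res$q[j],
                       v0 = res$v0[j])
    fit <- fit_pair(c(res$a[j], res$b[j]), data, config, start = start,
                    steps = 5L * config$steps_warm_start)
    if (fit$sse < res$sse[j]) {
      res[j, c("v0", "p", "q", "sse", "polished")] <-
        list(fit$params$v0, fit$params$p, fit$params$q, fit$sse,
             fit$polished)
    }
  }
  landscape$results <- res
  landscape
}

#' Best-fitting exponent pair of a landscape
#'
#' @param landscape A `bp_landscape`.
#' @return A list with elements `pair` ([exponent_pair()]) and `fit`
#'   (`bp_fit`). Ties in SSE are broken lexicographically (smallest a,
#'   then smallest b).
#' @export
best_pair <- function(landscape) {
  stopifnot(inherits(landscape, "bp_landscape"))
  res <- landscape$results
  if (nrow(res) == 0L) stop("empty landscape", call. = FALSE)
  j <- order(res$sse, res$a, res$b)[1L]
  params <- bp_params(res$a[j], res$b[j], p = res$p[j], q = res$q[j],
                      v0 = res$v0[j])
  fit <- .new_fit_result(params, res$sse[j], NA_integer_,
                         polished = res$polished[j], anneal_steps = 0L,
                         seed = NULL, converged = res$converged[j])
  list(pair = exponent_pair(res$a[j], res$b[j]), fit = fit)
}

#' Near-optimal exponent-pair region
#'
#' An exponent pair is near-optimal at relative threshold `threshold` if
#' its `SSE_opt(a, b)` is at most `(1 + threshold)` times the minimal
#' SSE over the landscape. The region always contains the argmin; the
#' region shrinks as the threshold shrinks (nesting). The region's size
#' measures how sharply the data identify a growth model.
#'
#' @param landscape A `bp_landscape`.
#' @param threshold Relative SSE excess (e.g. 0.01 for 1%).
#' @return Data frame of near-optimal pairs (`a`, `b`, `sse`).
#' @export
near_optimal_region <- function(landscape, threshold) {
  stopifnot(inherits(landscape, "bp_landscape"), threshold >= 0)
  res <- landscape$results
  if (nrow(res) == 0L) stop("empty landscape", call. = FALSE)
  sse_min <- min(res$sse)
  keep <- res$sse <= (1 + threshold) * sse_min
  out <- res[keep, c("a", "b", "sse")]
  rownames(out) <- NULL
  out
}

#' Extend the grid while the optimum sits on its boundary
#'
#' If the best-fitting pair lies on the grid's upper boundary
#' (`b = b_max`) or right boundary (`a = a_max`), the searched rectangle
#' is enlarged by `increment` in the touched direction(s) and the new
#' pairs are fitted (warm-started from the nearest already-fitted
#' entries), repeating until the optimum is interior or the hard caps
#' are hit. If a cap is reached with the optimum still on the boundary,
#' the returned landscape carries `secured = FALSE` ("optimality not
#' secured").
#'
#' @param landscape A `bp_landscape` from [sweep_grid()].
#' @param data The [growth_dataset()] the landscape was fitted to.
#' @param config An [anneal_config()].
#' @param increment Grid-range increment per extension step (default
#'   0.5).
#' @param a_cap,b_cap Hard caps on the extended ranges (defaults 4
#'   and 12).
#' @param polish_each Passed on to the row fits as in [sweep_grid()].
#' @return The extended `bp_landscape`.
#' @export
extend_if_boundary <- function(landscape, data, config = anneal_config(),
                               increment = 0.5, a_cap = 4, b_cap = 12,
                               polish_each = TRUE) {
  stopifnot(inherits(landscape, "bp_landscape"),
            inherits(data, "growth_dataset"))
  cfg <- config
  cfg$seed <- NULL
  grid <- landscape$grid
  s <- grid$spacing
  res <- landscape$results
  repeat {
    j <- order(res$sse, res$a, res$b)[1L]
    on_b <- res$b[j] >= grid$b_max - s / 2
    on_a <- res$a[j] >= grid$a_max - s / 2
    if (!on_b && !on_a) {
      return(.new_landscape(res, grid, landscape$data_label, secured = TRUE))
    }
    at_cap <- (!on_b || grid$b_max >= b_cap) && (!on_a || grid$a_max >= a_cap)
    if (at_cap) {
      warning("extension cap reached with the optimum on the boundary; ",
              "optimality not secured")
      return(.new_landscape(res, grid, landscape$data_label, secured = FALSE))
    }
    if (on_b && grid$b_max < b_cap) {
      new_b_max <- min(grid$b_max + increment, b_cap)
      # extend every existing row upward in b, warm from the row's top entry
      for (a in unique(res$a)) {
        row <- res[res$a == a, , drop = FALSE]
        top <- row[which.max(row$b), ]
        lo <- round((grid$b_max + s) / s)
        hi <- round(new_b_max / s)
        if (lo > hi) next
        bs <- seq.int(lo, hi) * s
        bs <- bs[bs > a + s / 2]
        if (length(bs) == 0L) next
        start <- bp_params(top$a, top$b, p = top$p, q = top$q, v0 = top$v0)
        res <- rbind(res, .sweep_row(a, bs, data, cfg, polish_each,
                                     start = start))
      }
      grid$b_max <- new_b_max
    }
    if (on_a && grid$a_max < a_cap) {
      new_a_max <- min(grid$a_max + increment, a_cap)
      lo_a <- round((grid$a_max + s) / s)
      hi_a <- round(new_a_max / s)
      as <- if (lo_a > hi_a) numeric() else seq.int(lo_a, hi_a) * s
      for (a in as) {
        m <- round(a / s) + 1L
        n_max <- round(grid$b_max / s)
        if (m > n_max) next
        bs <- seq.int(m, n_max) * s
        res <- rbind(res, .sweep_row(a, bs, data, cfg, polish_each))
      }
      grid$a_max <- new_a_max
    }
    res <- res[order(res$a, res$b), , drop = FALSE]
    rownames(res) <- NULL
  }
}

#' Neighbor-median smoothness screen of a landscape
#'
#' Over the well-conditioned zone `a, b <= zone_max`, each grid entry's
#' SSE is compared with the median SSE of its (up to 8) grid neighbors;
#' entries deviating by 50% or more are flagged. A frayed (flagged)
#' entry usually means the stochastic fit stalled and should be retried
#' with a larger budget (see `retry_frayed` in [sweep_grid()]).
#'
#' @param landscape A `bp_landscape`.
#' @param zone_max Upper exponent bound of the screened zone (default 3).
#' @param max_rel Maximal tolerated relative deviation from the neighbor
#'   median (default 0.5).
#' @return Data frame with columns `a`, `b`, `sse`, `median_neighbor`,
#'   `ok`.
#' @export
landscape_smoothness <- function(landscape, zone_max = 3, max_rel = 0.5) {
  stopifnot(inherits(landscape, "bp_landscape"))
  res <- landscape$results
  s <- landscape$grid$spacing
  zone <- res[res$a <= zone_max & res$b <= zone_max, , drop = FALSE]
  if (nrow(zone) == 0L) {
    return(data.frame(a = numeric(), b = numeric(), sse = numeric(),
                      median_neighbor = numeric(), ok = logical()))
  }
  key <- function(a, b) paste(round(a / s), round(b / s))
  sse_by_key <- setNames(res$sse, key(res$a, res$b))
  off <- expand.grid(da = c(-s, 0, s), db = c(-s, 0, s))
  off <- off[!(off$da == 0 & off$db == 0), ]
  med <- vapply(seq_len(nrow(zone)), function(i) {
    nb <- sse_by_key[key(zone$a[i] + off$da, zone$b[i] + off$db)]
    nb <- nb[!is.na(nb)]
    if (length(nb) == 0L) NA_real_ else median(nb)
  }, numeric(1))
  ok <- is.na(med) | abs(zone$sse - med) < max_rel * med
  data.frame(a = zone$a, b = zone$b, sse = zone$sse, median_neighbor = med,
             ok = ok)
}

#' Write / read a landscape results table
#'
#' The CSV has the header `a,b,v0,p,q,sse` with one row per grid pair,
#' in full-precision scientific notation (round-trips at >= 15
#' significant digits, preserving q values down to ~1e-34).
#'
#' @param landscape A `bp_landscape`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "bp_landscape"))
  res <- landscape$results
  df <- data.frame(a = .fmt_num(res$a), b = .fmt_num(res$b),
                   v0 = .fmt_num(res$v0), p = .fmt_num(res$p),
                   q = .fmt_num(res$q), sse = .fmt_num(res$sse))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param grid The [grid_spec()] the table was produced with (the CSV
#'   stores only the fitted entries).
#' @param data_label Provenance label to attach.
#' @return `read_landscape()` returns a `bp_landscape`.
#' @export
read_landscape <- function(path, grid, data_label = basename(path)) {
  stopifnot(inherits(grid, "grid_spec"))
  df <- read.csv(path)
  need <- c("a", "b", "v0", "p", "q", "sse")
  if (!all(need %in% names(df))) {
    stop("landscape CSV must have columns a,b,v0,p,q,sse", call. = FALSE)
  }
  df$polished <- TRUE
  df$converged <- is.finite(df$sse)
  .new_landscape(df[c(need, "polished", "converged")], grid, data_label)
}

#' Export near-optimal regions for plotting
#'
#' Writes a CSV of grid pairs with the smallest threshold (from
#' `thresholds`) at which each pair is near-optimal; pairs outside the
#' largest threshold are omitted.
#'
#' @param landscape A `bp_landscape`.
#' @param thresholds Increasing relative thresholds (default 1%, 5%,
#'   10%).
#' @param path Output CSV path (columns `a,b,threshold`).
#' @return The exported data frame, invisibly.
#' @export
export_regions <- function(landscape, thresholds = c(0.01, 0.05, 0.10),
                           path) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0))
  sse_min <- min(landscape$results$sse)
  out <- NULL
  for (th in rev(thresholds)) { # largest first, overwrite with smaller
    reg <- near_optimal_region(landscape, th)
    reg$threshold <- th
    if (is.null(out)) {
      out <- reg
    } else {
      idx <- match(paste(reg$a, reg$b), paste(out$a, out$b))
      out$threshold[idx[!is.na(idx)]] <- th
    }
  }
  out <- out[order(out$a, out$b), c("a", "b", "threshold")]
  rownames(out) <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
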