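#' Longitudinal size-at-age dataset
#'
#' Container for ordered (time, volume) observations. Times are in days,
#' strictly increasing with `t[1] >= 0`; volumes are in mm^3 and strictly
#' positive. At least two observations are required and missing values
#' are refused.
#'
#' @param times Numeric vector of observation times (days).
#' @param volumes Numeric vector of volumes (mm^3), same length as `times`.
#' @param label Free-text provenance label.
#' @return An object of class `growth_dataset`: a list with elements
#'   `times`, `volumes`, `label`.
#' @examples
#' d <- growth_dataset(c(0, 10, 20), c(100, 180, 240), label = "toy")
#' d
#' @export
growth_dataset <- function(times, volumes, label = "") {
  if (!is.numeric(times) || !is.numeric(volumes)) {
    stop("'times' and 'volumes' must be numeric vectors", call. = FALSE)
  }
  if (length(times) != length(volumes)) {
    stop("'times' and 'volumes' must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a growth dataset needs at least 2 observations", call. = FALSE)
  }
  if (anyNA(times) || anyNA(volumes)) {
    stop("missing values are not allowed in a growth dataset", call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("the first observation time must be >= 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (any(volumes <= 0)) {
    stop("all volumes must be positive", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), volumes = as.numeric(volumes),
         label = as.character(label)[1L]),
    class = "growth_dataset"
  )
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("<growth_dataset> %s\n", if (nzchar(x$label)) x$label else "(unlabeled)"))
  cat(sprintf("  %d observations, t = %g..%g days, v = %g..%g mm^3\n",
              length(x$times), min(x$times), max(x$times),
              min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' @export
length.growth_dataset <- function(x) length(x$times)

#' @export
as.data.frame.growth_dataset <- function(x, ...) {
  data.frame(time = x$times, volume = x$volumes)
}

# 14 size-at-age observations (days, mm^3) of an untreated human breast
# cancer xenograft (GI-101A cells in nude mice), monitored over 114 days.
.tumor_gi101a <- function() {
  growth_dataset(
    times   = c(0, 9, 20, 32, 43, 54, 65, 76, 82, 87, 93, 98, 107, 114),
    volumes = c(225, 300, 582, 650, 680, 930, 1225, 1464, 1911, 2184,
                2570, 2721, 2948, 3503),
    label = "tumor"
  )
}

#' Load a growth dataset from CSV (or the built-in tumor fixture)
#'
#' Reads a two-column CSV with header `time,volume` (days, mm^3). The
#' keyword `"tumor"` (or `"paper"`, an alias) returns the built-in
#' 14-point size-at-age series of an untreated breast-cancer xenograft
#' observed over 114 days, used in all examples.
#'
#' @param path Path to a CSV file, or `"tumor"` / `"paper"` for the
#'   built-in fixture.
#' @return A [growth_dataset()].
#' @examples
#' tumor <- load_dataset("tumor")
#' length(tumor)
#' @export
load_dataset <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (path %in% c("tumor", "paper")) {
    return(.tumor_gi101a())
  }
  if (!file.exists(path)) {
    stop(sprintf("dataset file not found: '%s'", path), call. = FALSE)
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("could not parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  need <- c("time", "volume")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' must have columns 'time' and 'volume'", path),
         call. = FALSE)
  }
  growth_dataset(df$time, df$volume, label = basename(path))
}

#' Write a growth dataset to CSV
#'
#' @param data A [growth_dataset()].
#' @param path Output CSV path; columns `time,volume`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "growth_dataset"))
  df <- data.frame(time = .fmt_num(data$times), volume = .fmt_num(data$volumes))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal formatting (round-trips doubles)
.fmt_num <- function(x) sprintf("%.17g", x)

#' Generate a synthetic growth dataset from a known model curve
#'
#' Samples the exact Bertalanffy-Puetter curve defined by `params` at the
#' requested times and adds independent Gaussian noise of standard
#' deviation `noise_sd` (mm^3). Values pushed non-positive by noise are
#' truncated to a small positive floor; a warning is issued if more than
#' 10% of points required truncation.
#'
#' @param params A [bp_params()] parameter set.
#' @param times Observation times (days), strictly increasing.
#' @param noise_sd Noise standard deviation in mm^3 (`>= 0`).
#' @param seed Optional integer seed for reproducibility.
#' @param label Dataset label.
#' @return A [growth_dataset()] whose attribute `"truth"` stores `params`.
#' @examples
#' pars <- bp_params(1, 2, p = 0.1, q = 1e-4, v0 = 100)
#' d <- generate_synthetic(pars, times = seq(0, 100, by = 10),
#'                         noise_sd = 20, seed = 1)
#' @export
generate_synthetic <- function(params, times, noise_sd, seed = NULL,
                               label = "synthetic") {
  stopifnot(inherits(params, "bp_params"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  v <- solve_curve(params, times)
  obs <- v + rnorm(length(times), sd = noise_sd)
  floor_v <- 1e-6 * max(v)
  n_trunc <- sum(obs < floor_v)
  if (n_trunc > 0.1 * length(obs)) {
    warning(sprintf("%d of %d synthetic volumes truncated to stay positive",
                    n_trunc, length(obs)))
  }
  obs <- pmax(obs, floor_v)
  out <- growth_dataset(times, obs, label = label)
  attr(out, "truth") <- params
  out
}

#' Restrict a dataset to an initial segment
#'
#' Keeps observations with `time <= cutoff` days.
#'
#' @param data A [growth_dataset()].
#' @param cutoff Cutoff time in days.
#' @return A [growth_dataset()] with the retained observations.
#' @export
truncate_dataset <- function(data, cutoff) {
  stopifnot(inherits(data, "growth_dataset"))
  keep <- data$times <= cutoff
  if (sum(keep) < 2L) {
    stop("fewer than 2 observations before the cutoff", call. = FALSE)
  }
  growth_dataset(data$times[keep], data$volumes[keep],
                 label = sprintf("%s[t<=%g]", data$label, cutoff))
}
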