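#' Geometry constants for aggregate calculations
#'
#' The aggregate-stability statistic rests on two measured constants: the
#' single-cell diameter (10 µm by default) and the random packing density of
#' cells inside a spherical aggregate (0.64, the random close-packing
#' fraction for spheres). `horizon_days` is the exponent used when projecting
#' the cell number of an aggregate forward from its baseline measurement
#' (default 3 days).
#'
#' @param cell_diameter single-cell diameter, µm (> 0).
#' @param packing_density fraction of aggregate volume occupied by cells,
#'   in (0, 1].
#' @param horizon_days days of growth assumed in the forward projection.
#' @return A `geometry_constants` list; `cell_volume` (µm³) is precomputed.
#' @export
geometry_constants <- function(cell_diameter = 10, packing_density = 0.64,
                               horizon_days = 3) {
  stopifnot(cell_diameter > 0, packing_density > 0, packing_density <= 1,
            horizon_days > 0)
  structure(list(cell_diameter = cell_diameter,
                 packing_density = packing_density,
                 horizon_days = horizon_days,
                 cell_volume = sphere_volume(cell_diameter / 2)),
            class = "geometry_constants")
}

#' Sphere volume and its inverse
#'
#' `sphere_volume(r)` is (4/3) pi r^3; `sphere_diameter(V)` returns the
#' diameter of the sphere of volume `V`. The two compose to the identity.
#' For the default 10 µm cell, `sphere_volume(5)` is 523.6 µm³, the
#' single-cell volume constant.
#'
#' @param radius sphere radius, µm (>= 0).
#' @param volume sphere volume, µm³ (>= 0).
#' @return Volume in µm³, or diameter in µm.
#' @export
sphere_volume <- function(radius) {
  if (any(radius < 0)) stop("radius must be >= 0")
  (4 / 3) * pi * radius^3
}

#' @rdname sphere_volume
#' @export
sphere_diameter <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0")
  2 * (3 * volume / (4 * pi))^(1 / 3)
}

#' Cells per aggregate from its volume
#'
#' Divides the aggregate volume by the single-cell volume and multiplies by
#' the packing density: `N1 = (V1 / Vc) * rho`. Fractional counts are kept —
#' the quantity is a continuous ratio, not an integer census.
#'
#' @param V1 aggregate volume, µm³ (>= 0).
#' @param geom a [geometry_constants()].
#' @return Estimated number of cells in the aggregate.
#' @export
cells_per_aggregate <- function(V1, geom = geometry_constants()) {
  if (any(V1 < 0)) stop("volume must be >= 0")
  (V1 / geom$cell_volume) * geom$packing_density
}

#' Project an aggregate's cell number forward in time
#'
#' Exponential growth at the specific rate `K` measured from daily counts:
#' `N = N1 * exp(K * horizon_days)`.
#'
#' @param N1 baseline cell number (>= 0).
#' @param K specific growth rate, 1/day.
#' @param geom a [geometry_constants()]; supplies `horizon_days`.
#' @return Predicted cell number.
#' @export
predict_future_cells <- function(N1, K, geom = geometry_constants()) {
  if (any(N1 < 0)) stop("cell number must be >= 0")
  N1 * exp(K * geom$horizon_days)
}

#' Aggregate volume implied by a cell number
#'
#' Inverse of [cells_per_aggregate()]: `V = N * Vc / rho`. Use
#' [sphere_diameter()] on the result for the implied diameter.
#'
#' @param N3P cell number (>= 0).
#' @param geom a [geometry_constants()].
#' @return Volume in µm³.
#' @export
predicted_volume <- function(N3P, geom = geometry_constants()) {
  if (any(N3P < 0)) stop("cell number must be >= 0")
  N3P * geom$cell_volume / geom$packing_density
}

#' Aggregate percent error
#'
#' The stability statistic: observed minus proliferation-predicted aggregate
#' volume, relative to observed, `(V3 - V3P) / V3`. Positive values mean the
#' observed aggregates are larger than cell proliferation alone can explain
#' (fusion); negative values mean they are smaller (fragmentation or
#' instability). Returned as a fraction (0.5 = 50%).
#'
#' @param V3 observed aggregate volume, µm³ (> 0).
#' @param V3P predicted aggregate volume, µm³.
#' @return Dimensionless fraction.
#' @export
aggregate_pct_error <- function(V3, V3P) {
  if (any(V3 <= 0)) stop("observed volume V3 must be > 0")
  (V3 - V3P) / V3
}

#' Normalize qPCR Ct values against a housekeeping gene
#'
#' Delta-Ct expression level: `1000 / 2^(ct_target - ct_housekeeping)`.
#' Equal Ct gives 1000; each extra target cycle halves the value, so larger
#' numbers mean higher expression.
#'
#' @param ct_target,ct_housekeeping finite Ct values (cycles).
#' @return Expression level in arbitrary units.
#' @export
qpcr_normalize <- function(ct_target, ct_housekeeping) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_housekeeping)))
    stop("Ct values must be finite")
  1000 / 2^(ct_target - ct_housekeeping)
}

#' Daily time series for one bioreactor run
#'
#' Holds the raw daily measurements of a single reactor: replicate cell
#' counts (cells/ml, typically triplicate), aggregate diameter samples
#' (µm, typically >= 30 per day once aggregates have formed), and optional
#' viability. Days must be strictly increasing; counts and diameters must be
#' positive.
#'
#' @param run_id run identifier.
#' @param days integer vector of culture days (e.g. 0:4).
#' @param counts list, one numeric vector of replicate counts per day
#'   (`NULL` entries allowed for unmeasured days).
#' @param diameters list, one numeric vector of diameters per day (`NULL`
#'   allowed; day 0 usually has none, the culture being single cells).
#' @param viability optional numeric vector of per-day percent viability.
#' @return A `reactor_series` object.
#' @export
reactor_series <- function(run_id, days, counts, diameters = NULL,
                           viability = NULL) {
  days <- as.integer(days)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  counts <- .per_day_list(counts, length(days), "counts")
  diameters <- .per_day_list(diameters, length(days), "diameters")
  for (i in seq_along(days)) {
    if (!is.null(counts[[i]]) && any(counts[[i]] <= 0))
      stop(sprintf("run %s day %d: nonpositive cell count", run_id, days[i]))
    if (!is.null(diameters[[i]]) && any(diameters[[i]] <= 0))
      stop(sprintf("run %s day %d: nonpositive diameter", run_id, days[i]))
  }
  structure(list(run_id = as.character(run_id), days = days,
                 counts = counts, diameters = diameters,
                 viability = viability),
            class = "reactor_series")
}

.per_day_list <- function(x, n_days, what) {
  if (is.null(x)) return(vector("list", n_days))
  if (!is.list(x)) x <- list(x)
  if (length(x) != n_days)
    stop(sprintf("'%s' must have one entry per day", what))
  x
}

#' @export
print.reactor_series <- function(x, ...) {
  nd <- vapply(x$diameters, length, 0L)
  cat(sprintf("Reactor %s: days %s; counts on %d days; diameters on %d days (n = %s)\n",
              x$run_id, paste(range(x$days), collapse = "-"),
              sum(vapply(x$counts, length, 0L) > 0), sum(nd > 0),
              paste(nd[nd > 0], collapse = ",")))
  invisible(x)
}

#' Exponential growth rate from daily counts
#'
#' Least-squares fit of log mean count against day: the slope is the
#' specific growth rate K (1/day) and `doubling_time = ln 2 / K` (reported as
#' `NA` for non-growing cultures, K <= 0). Replicates are averaged per day
#' before taking logs, mirroring daily-averaged count analysis.
#'
#' @param series a [reactor_series()].
#' @return A `growth_estimate` list: `K`, `doubling_time`, `r2_fit`.
#' @export
fit_growth_rate <- function(series) {
  means <- vapply(series$counts, function(v)
    if (length(v)) mean(v) else NA_real_, 0)
  keep <- is.finite(means)
  if (sum(keep) < 2) stop("need counts on at least two days")
  if (any(means[keep] <= 0)) stop("counts must be positive")
  day <- series$days[keep]
  ly <- log(means[keep])
  fit <- stats::lm(ly ~ day)
  K <- unname(stats::coef(fit)[2])
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(K = K,
                 doubling_time = if (K > 0) log(2) / K else NA_real_,
                 r2_fit = r2),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Growth: K = %.4f /day, doubling time = %s days (R2 = %.3f)\n",
              x$K, if (is.na(x$doubling_time)) "NA"
                   else sprintf("%.3f", x$doubling_time), x$r2_fit))
  invisible(x)
}

#' Per-day diameter statistics and growth slope
#'
#' Arithmetic mean and sample (n-1) standard deviation of the measured
#' aggregate diameters for each day with data, plus the least-squares slope
#' of mean diameter against day (µm/day). Days with a single measurement
#' get `NA` SD.
#'
#' @param series a [reactor_series()].
#' @return List with `per_day` (data.frame `day`, `n`, `mean`, `sd`) and
#'   `slope` (µm/day; `NA` with fewer than two measured days).
#' @export
diameter_stats <- function(series) {
  has <- vapply(series$diameters, length, 0L) > 0
  if (!any(has)) stop("no diameter measurements")
  day <- series$days[has]
  m <- vapply(series$diameters[has], mean, 0)
  s <- vapply(series$diameters[has], function(v)
    if (length(v) >= 2) stats::sd(v) else NA_real_, 0)
  n <- vapply(series$diameters[has], length, 0L)
  slope <- if (length(day) >= 2)
    unname(stats::coef(stats::lm(m ~ day))[2]) else NA_real_
  list(per_day = data.frame(day = day, n = n, mean = m, sd = s),
       slope = slope)
}

#' Aggregate stability from a reactor time series
#'
#' Chains the geometry equations: the mean diameter on `baseline_day` gives
#' the baseline aggregate volume `V1` and cell number `N1`; the growth rate
#' fitted from daily counts projects the cell number forward over
#' `horizon_days` to `N3P` and the predicted volume `V3P`; the observed mean
#' diameter on `compare_day` gives `V3`; the percent error is
#' `(V3 - V3P)/V3`. By default the comparison day is the baseline day plus
#' the projection horizon, so a series generated by noise-free exponential
#' growth without fusion has exactly zero percent error. Set `compare_day`
#' explicitly to compare against a different measurement day (the projection
#' exponent stays `horizon_days`).
#'
#' @param series a [reactor_series()].
#' @param geom a [geometry_constants()].
#' @param baseline_day day whose mean diameter seeds the prediction
#'   (default 1, the first day aggregates are measurable).
#' @param compare_day day whose observed mean diameter is compared with the
#'   prediction; default `baseline_day + geom$horizon_days`.
#' @param growth optional precomputed [fit_growth_rate()] result.
#' @return An `aggregate_stability` list: `V1`, `N1`, `N3P`, `V3P`, `V3`,
#'   `pct_error` (fraction), `K`, `diameter_sd` (on the comparison day),
#'   `diameter_slope` (µm/day).
#' @export
stability_from_series <- function(series, geom = geometry_constants(),
                                  baseline_day = 1, compare_day = NULL,
                                  growth = NULL) {
  compare_day <- compare_day %||% (baseline_day + geom$horizon_days)
  ds <- diameter_stats(series)
  d1 <- ds$per_day$mean[ds$per_day$day == baseline_day]
  d3 <- ds$per_day$mean[ds$per_day$day == compare_day]
  if (length(d1) == 0)
    stop(sprintf("no diameters measured on baseline day %d", baseline_day))
  if (length(d3) == 0)
    stop(sprintf("no diameters measured on comparison day %d", compare_day))
  growth <- growth %||% fit_growth_rate(series)
  V1 <- sphere_volume(d1 / 2)
  N1 <- cells_per_aggregate(V1, geom)
  N3P <- predict_future_cells(N1, growth$K, geom)
  V3P <- predicted_volume(N3P, geom)
  V3 <- sphere_volume(d3 / 2)
  sd3 <- ds$per_day$sd[ds$per_day$day == compare_day]
  structure(list(V1 = V1, N1 = N1, N3P = N3P, V3P = V3P, V3 = V3,
                 pct_error = aggregate_pct_error(V3, V3P),
                 K = growth$K, diameter_sd = sd3,
                 diameter_slope = ds$slope),
            class = "aggregate_stability")
}

#' @export
print.aggregate_stability <- function(x, ...) {
  cat(sprintf(
    "Aggregate stability: %% error = %+.1f%% (V3 = %.3g, predicted %.3g um^3; K = %.3f /day)\n",
    100 * x$pct_error, x$V3, x$V3P, x$K))
  invisible(x)
}

#' Assemble the per-run response table from reactor series
#'
#' Computes the kinetics- and geometry-derived responses for every run:
#' growth rate and doubling time, final cell concentration, mean aggregate
#' diameter and its SD on the stability comparison day, diameter growth
#' slope, the aggregate percent error, and mean final-day viability when
#' recorded.
#'
#' @param series_list list of [reactor_series()].
#' @param geom a [geometry_constants()].
#' @param baseline_day,compare_day passed to [stability_from_series()].
#' @return A data.frame keyed by `run_id` with one column per response.
#' @export
series_responses <- function(series_list, geom = geometry_constants(),
                             baseline_day = 1, compare_day = NULL) {
  rows <- lapply(series_list, function(s) {
    g <- fit_growth_rate(s)
    st <- stability_from_series(s, geom, baseline_day, compare_day,
                                growth = g)
    last <- length(s$days)
    data.frame(
      run_id = s$run_id,
      growth_rate = g$K,
      doubling_time = g$doubling_time,
      cell_concentration = mean(s$counts[[last]]),
      diameter = sphere_diameter(st$V3),
      diameter_sd = st$diameter_sd,
      diameter_slope = st$diameter_slope,
      pct_error = st$pct_error,
      viability = if (is.null(s$viability)) NA_real_
                  else s$viability[last],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
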