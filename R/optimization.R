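#' Desirability criterion for one response
#'
#' Encodes a goal for a predicted response in the Derringer–Suich
#' piecewise-linear form (unit exponents). For `"maximize"`, desirability is
#' 0 at or below `low` and 1 at or above `high`; for `"minimize"` the ramp
#' is reversed; `"target"` rises from `low` to `target` and falls to `high`;
#' `"range"` is 1 inside the limits and 0 outside.
#'
#' @param response name of the fitted response the criterion applies to.
#' @param goal one of `"maximize"`, `"minimize"`, `"target"`, `"range"`.
#' @param low,high criterion limits, `low < high`.
#' @param target target value (required for `"target"`, inside the limits).
#' @param weight relative weight in the overall desirability (> 0).
#' @return A `criterion` object.
#' @export
criterion <- function(response, goal = c("maximize", "minimize", "target",
                                         "range"),
                      low, high, target = NULL, weight = 1) {
  goal <- match.arg(goal)
  stopifnot(is.finite(low) || is.finite(high), weight > 0)
  if (is.finite(low) && is.finite(high) && low >= high)
    stop("criterion limits must satisfy low < high")
  if (goal == "target") {
    if (is.null(target)) stop("'target' goal requires a target value")
    if (target <= low || target >= high)
      stop("target must lie strictly inside the limits")
  }
  structure(list(response = response, goal = goal, low = low, high = high,
                 target = target, weight = weight), class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("Criterion: %s %s in [%g, %g]%s, weight %g\n", x$goal,
              x$response, x$low, x$high,
              if (!is.null(x$target)) sprintf(", target %g", x$target) else "",
              x$weight))
  invisible(x)
}

#' Per-response desirability
#'
#' @param y predicted response value(s).
#' @param crit a [criterion()].
#' @return Desirability in \[0, 1\], vectorized over `y`.
#' @export
desirability <- function(y, crit) {
  ramp_up <- function(y, a, b) pmin(1, pmax(0, (y - a) / (b - a)))
  switch(crit$goal,
    maximize = ramp_up(y, crit$low, crit$high),
    minimize = 1 - ramp_up(y, crit$low, crit$high),
    target = pmin(ramp_up(y, crit$low, crit$target),
                  1 - ramp_up(y, crit$target, crit$high)),
    range = as.numeric(y >= crit$low & y <= crit$high))
}

#' Overall desirability
#'
#' Weighted geometric mean of the per-criterion desirabilities: zero as soon
#' as any criterion is fully violated, 1 only when all are fully met.
#'
#' @param ds vector of per-criterion desirabilities in \[0, 1\].
#' @param weights positive weights (default equal).
#' @return Scalar overall desirability D in \[0, 1\].
#' @export
overall_desirability <- function(ds, weights = rep(1, length(ds))) {
  stopifnot(length(ds) == length(weights), all(weights > 0))
  if (any(ds < 0 | ds > 1)) stop("desirabilities must lie in [0, 1]")
  if (any(ds == 0)) return(0)
  exp(sum(weights * log(ds)) / sum(weights))
}

#' Process capability index
#'
#' `Cpk = min((USL - mu)/(3 sigma), (mu - LSL)/(3 sigma))` over the finite
#' specification limits: the distance from the predicted mean to the nearest
#' limit in units of three predicted standard deviations. Cpk near 1 means
#' the 6-sigma natural tolerance just fits between the limits.
#'
#' @param pred_mean,pred_sd predicted mean and SD (`pred_sd > 0`).
#' @param lower_spec,upper_spec specification limits; at least one finite.
#' @return Cpk (numeric scalar).
#' @export
cpk <- function(pred_mean, pred_sd, lower_spec = -Inf, upper_spec = Inf) {
  stopifnot(pred_sd > 0)
  if (!is.finite(lower_spec) && !is.finite(upper_spec))
    stop("at least one specification limit must be finite")
  min((upper_spec - pred_mean) / (3 * pred_sd),
      (pred_mean - lower_spec) / (3 * pred_sd))
}

#' Probability of failing the specification limits
#'
#' Probability that the response falls outside `[lower, upper]` under a
#' normal predictive distribution, in percent. The default is the exact
#' normal-CDF value; `method = "mc"` estimates it by Monte Carlo (useful as
#' a cross-check and for non-rectangular extensions).
#'
#' @param pred_mean,pred_sd predictive mean and SD (`pred_sd > 0`).
#' @param lower,upper specification limits (may be infinite).
#' @param method `"closed"` or `"mc"`.
#' @param n_draws Monte-Carlo sample size.
#' @param seed Monte-Carlo seed.
#' @return Failure probability in percent, 0-100.
#' @export
probability_of_failure <- function(pred_mean, pred_sd, lower = -Inf,
                                   upper = Inf,
                                   method = c("closed", "mc"),
                                   n_draws = 1e5, seed = 0) {
  stopifnot(pred_sd > 0)
  method <- match.arg(method)
  if (method == "closed") {
    p <- stats::pnorm(lower, pred_mean, pred_sd) +
      stats::pnorm(upper, pred_mean, pred_sd, lower.tail = FALSE)
  } else {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    z <- stats::rnorm(n_draws, pred_mean, pred_sd)
    p <- mean(z < lower | z > upper)
  }
  100 * p
}

## criterion limits on the modeling scale; one-sided goals keep only the
## limiting side; the neglog transform is decreasing, so limits swap
.spec_limits_model_scale <- function(cr, transform) {
  lo <- if (cr$goal == "minimize") -Inf else cr$low
  hi <- if (cr$goal == "maximize") Inf else cr$high
  if (transform == "identity") return(c(lo, hi))
  tlo <- if (is.finite(hi)) apply_transform(hi, transform) else -Inf
  thi <- if (is.finite(lo)) apply_transform(lo, transform) else Inf
  c(tlo, thi)
}

## desirability of the model predictions at coded point x
.desirability_at <- function(x, fits, criteria) {
  ds <- vapply(criteria, function(cr) {
    mu <- predict(fits[[cr$response]], x, scale = "response")$fit
    desirability(mu, cr)
  }, 0)
  overall_desirability(ds, vapply(criteria, `[[`, 0, "weight"))
}

#' Multi-response setpoint optimization
#'
#' Maximizes the overall desirability of the fitted response predictions
#' over the coded factor box by multi-start Nelder–Mead (candidates are
#' clamped to the box before evaluation, so the search cannot leave the
#' design space). Deterministic for a given seed; the reported solution is
#' at least as desirable as every start point. The result carries, per
#' criterion, the predicted mean and prediction SD at the setpoint, Cpk
#' against the criterion limits, and the closed-form probability of failure.
#'
#' @param fits a `doe_fit` from [fit_response_models()], or a named list of
#'   `fitted_model`s.
#' @param criteria list of [criterion()] objects; every referenced response
#'   must have a fitted model.
#' @param bounds length-2 numeric, the coded search box (default
#'   `c(-1, 1)`).
#' @param n_starts number of random starts (default 20; the center point is
#'   always included as a start).
#' @param seed RNG seed for the starts.
#' @return A `setpoint_result`: `coded`, `actual` (when the design's factor
#'   set is available), `desirability`, per-criterion table `criteria`
#'   (predicted mean, sd, desirability, cpk, failure %), and
#'   `factor_contributions`.
#' @export
optimize_setpoint <- function(fits, criteria, bounds = c(-1, 1),
                              n_starts = 20, seed = 0) {
  models <- if (inherits(fits, "doe_fit")) fits$models else fits
  factors <- if (inherits(fits, "doe_fit")) design_factors(fits$design)
             else NULL
  for (cr in criteria)
    if (!cr$response %in% names(models))
      stop("criterion references unfitted response: ", cr$response)
  k <- length(models[[criteria[[1]]$response]]$model$factors)
  clamp <- function(x) pmin(bounds[2], pmax(bounds[1], x))
  obj <- function(x) -.desirability_at(clamp(x), models, criteria)

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  starts <- rbind(rep(0, k),
                  matrix(stats::runif(n_starts * k, bounds[1], bounds[2]),
                         ncol = k))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    x0 <- starts[s, ]
    res <- if (k == 1)
      stats::optim(x0, obj, method = "Brent",
                   lower = bounds[1], upper = bounds[2])
    else
      suppressWarnings(stats::optim(x0, obj, method = "Nelder-Mead",
                                    control = list(maxit = 2000,
                                                   reltol = 1e-10)))
    v0 <- obj(x0)
    cand <- if (res$value <= v0) list(par = clamp(res$par),
                                      value = res$value)
            else list(par = clamp(x0), value = v0)
    if (is.null(best) || cand$value < best$value - 1e-12) best <- cand
  }
  x <- best$par
  names(x) <- models[[criteria[[1]]$response]]$model$factors

  crit_tab <- do.call(rbind, lapply(criteria, function(cr) {
    fit <- models[[cr$response]]
    pr <- predict(fit, x, interval = "prediction")
    mu <- pr$fit; sdv <- pr$se
    lim <- .spec_limits_model_scale(cr, fit$transform)
    mu_resp <- predict(fit, x, scale = "response")$fit
    has_sd <- is.finite(sdv) && sdv > 0
    data.frame(response = cr$response, goal = cr$goal,
               predicted = mu_resp, pred_sd = sdv,
               desirability = desirability(mu_resp, cr),
               cpk = if (has_sd) cpk(mu, sdv, lim[1], lim[2]) else NA_real_,
               failure_pct = if (has_sd)
                 probability_of_failure(mu, sdv, lim[1], lim[2])
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    coded = x,
    actual = if (!is.null(factors)) drop(coded_to_actual(x, factors)),
    desirability = -best$value,
    criteria = crit_tab,
    factor_contributions = factor_contributions(models[names(models) %in%
      vapply(criteria, `[[`, "", "response")], x)),
    class = "setpoint_result")
}

#' @export
print.setpoint_result <- function(x, ...) {
  cat(sprintf("Setpoint: overall desirability D = %.3f\n", x$desirability))
  cat("  coded: ", paste(sprintf("%s = %+.3f", names(x$coded), x$coded),
                         collapse = ", "), "\n")
  if (!is.null(x$actual))
    cat("  actual:", paste(sprintf("%s = %.4g", names(x$actual), x$actual),
                           collapse = ", "), "\n")
  print(cbind(x$criteria[1:4],
              round(x$criteria[c("desirability", "cpk", "failure_pct")], 3)),
        row.names = FALSE)
  invisible(x)
}

#' Factor contributions at a setpoint
#'
#' For each factor and response, the span of the predicted response as that
#' factor sweeps the coded range with the others held at the setpoint,
#' normalized so contributions sum to 100% within a response. This is a
#' span-normalized sensitivity reconstruction: with interactions present, a
#' factor's contribution depends on where its partners sit.
#'
#' @param models named list of `fitted_model`s (or a `doe_fit`).
#' @param setpoint coded settings vector.
#' @param bounds coded sweep range.
#' @param n_points sweep grid resolution.
#' @return Matrix of percents, factors x responses, columns summing to 100
#'   (or 0 for a flat response).
#' @export
factor_contributions <- function(models, setpoint, bounds = c(-1, 1),
                                 n_points = 21) {
  if (inherits(models, "doe_fit")) models <- models$models
  fnames <- models[[1]]$model$factors
  grid <- seq(bounds[1], bounds[2], length.out = n_points)
  out <- matrix(0, length(fnames), length(models),
                dimnames = list(fnames, names(models)))
  for (r in seq_along(models)) {
    spans <- vapply(seq_along(fnames), function(j) {
      X <- matrix(rep(setpoint, each = n_points), nrow = n_points)
      X[, j] <- grid
      mu <- predict(models[[r]], X)$fit
      diff(range(mu))
    }, 0)
    ## flat responses (spans at numerical noise) contribute nothing
    base <- abs(predict(models[[r]], matrix(setpoint, nrow = 1))$fit)
    spans[spans < 1e-9 * max(1, base)] <- 0
    tot <- sum(spans)
    out[, r] <- if (tot > 0) 100 * spans / tot else 0
  }
  out
}

#' Setpoint sensitivity profile for one factor
#'
#' Sweeps a single factor across the coded range with the others held at the
#' setpoint and reports the predicted response with its prediction interval.
#' The band widens toward the design-space edges (leverage). When a
#' criterion is supplied, each grid point also gets the probability (normal
#' predictive distribution, closed form, optionally Monte Carlo) that a new
#' observation meets the criterion limits — the acceptable operating window
#' is where that probability stays high.
#'
#' @param fit a `fitted_model`.
#' @param setpoint coded settings vector.
#' @param factor name of the factor to sweep.
#' @param n_points grid resolution (default 21).
#' @param level prediction-interval coverage.
#' @param criterion optional [criterion()] for the pass-probability column.
#' @param n_mc if > 0, use Monte Carlo with this many draws for the pass
#'   probability.
#' @param seed Monte-Carlo seed.
#' @return data.frame: `x` (coded level), `fit`, `lwr`, `upr`, and
#'   `pass_prob` when a criterion is given.
#' @export
setpoint_profile <- function(fit, setpoint, factor, n_points = 21,
                             level = 0.95, criterion = NULL, n_mc = 0,
                             seed = 0) {
  fnames <- fit$model$factors
  j <- match(factor, fnames)
  if (is.na(j)) stop("unknown factor: ", factor)
  grid <- seq(-1, 1, length.out = n_points)
  X <- matrix(rep(setpoint, each = n_points), nrow = n_points)
  X[, j] <- grid
  pr <- predict(fit, X, interval = "prediction", level = level)
  out <- data.frame(x = grid, fit = pr$fit, se = pr$se,
                    lwr = pr$lwr, upr = pr$upr)
  if (!is.null(criterion)) {
    lim <- .spec_limits_model_scale(criterion, fit$transform)
    lo <- lim[1]; hi <- lim[2]
    if (n_mc > 0) {
      old <- .save_seed(); on.exit(.restore_seed(old))
      set.seed(as.integer(seed))
      out$pass_prob <- vapply(seq_len(n_points), function(i) {
        z <- stats::rnorm(n_mc, pr$fit[i], pr$se[i])
        mean(z >= lo & z <= hi)
      }, 0)
    } else {
      out$pass_prob <- stats::pnorm(hi, pr$fit, pr$se) -
        stats::pnorm(lo, pr$fit, pr$se)
    }
  }
  out
}
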