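#' Response transforms
#'
#' `apply_transform` maps a response vector onto the modeling scale;
#' `invert_transform` maps model-scale values back. Supported tags:
#' `"identity"`, and `"neglog"` for percentage responses
#' (`y -> -log10(y/100 + eps)`), used to normalize left-skewed flow-cytometry
#' marker frequencies that pile up near 100%. The small offset `eps` guards
#' exact-zero observations.
#'
#' @param y numeric response vector (percent scale for `"neglog"`).
#' @param transform `"identity"` or `"neglog"`.
#' @param eps offset inside the log (default 1e-6).
#' @return Transformed (or back-transformed) numeric vector.
#' @export
apply_transform <- function(y, transform = c("identity", "neglog"),
                            eps = 1e-6) {
  transform <- match.arg(transform)
  if (transform == "identity") return(y)
  arg <- y / 100 + eps
  bad <- which(is.finite(arg) & arg <= 0)
  if (length(bad))
    stop("neglog transform undefined for nonpositive values at rows: ",
         paste(bad, collapse = ", "))
  -log10(arg)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(y, transform = c("identity", "neglog"),
                             eps = 1e-6) {
  transform <- match.arg(transform)
  if (transform == "identity") return(y)
  (10^(-y) - eps) * 100
}

#' Normalize responses to center-point replicates across batches
#'
#' Campaigns run in several batches drift between batches (reagent lots,
#' instrument day effects). The replicated center points, present in every
#' batch, estimate that drift: each response within a batch is rescaled by
#' `grand center-point mean / batch center-point mean`, so batch-level
#' multiplicative offsets cancel while the grand center-point mean is
#' preserved. The operation is idempotent.
#'
#' @param responses data.frame keyed by `run_id` with numeric response
#'   columns.
#' @param design a `design_table` with filled `batch` and `is_center`
#'   columns.
#' @return The rescaled response table (same shape).
#' @export
normalize_to_center_points <- function(responses, design) {
  if (anyNA(design$batch)) stop("design has unassigned batches")
  idx <- match(responses$run_id, design$run_id)
  if (anyNA(idx)) stop("responses contain run_ids absent from the design")
  batch <- design$batch[idx]
  center <- design$is_center[idx]
  for (b in unique(design$batch))
    if (!any(center & batch == b))
      stop("batch ", b, " has no center point: cannot normalize")
  num <- setdiff(names(responses)[vapply(responses, is.numeric, TRUE)],
                 "run_id")
  for (col in num) {
    y <- responses[[col]]
    if (all(is.na(y))) next
    grand <- mean(y[center])
    if (!is.finite(grand)) stop("non-finite center-point mean for ", col)
    for (b in unique(batch)) {
      bm <- mean(y[center & batch == b])
      if (!is.finite(bm) || bm == 0)
        stop(sprintf("center-point mean of '%s' in batch %s is %s",
                     col, b, if (is.finite(bm)) "zero" else "not finite"))
      y[batch == b] <- y[batch == b] * (grand / bm)
    }
    responses[[col]] <- y
  }
  responses
}

#' Multiple linear regression on a model matrix
#'
#' Ordinary least squares of a response on the coded model matrix, with the
#' summaries used throughout DoE practice: coefficients with 95% t-based
#' confidence intervals, the corrected R2 (`1 - SSres/SStot` about the mean;
#' defined as 0 when the response is constant), residual variance, hat
#' values and the unscaled coefficient covariance needed for prediction
#' intervals. Coefficients are in coded units, so their magnitudes are
#' directly comparable across factors.
#'
#' @param X model matrix from [build_model_matrix()] (full column rank,
#'   `nrow(X) >= ncol(X)`).
#' @param y numeric response vector.
#' @param response optional response name carried in the result.
#' @param model optional [model_spec()] carried for later prediction.
#' @param transform transform tag the response was fitted under.
#' @param level confidence level for the coefficient intervals.
#' @return A `fitted_model` list: `coef`, `se`, `ci`, `r2`, `sigma2`,
#'   `df_res`, `cov_unscaled`, `hat`, `residuals`, `fitted`, plus metric
#'   slots (`q2`, `validity`, `reproducibility`) filled by
#'   [fit_response_models()].
#' @export
fit_mlr <- function(X, y, response = "y", model = NULL,
                    transform = "identity", level = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) stop("fewer runs than model parameters")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (anyNA(y)) stop("response '", response, "' contains missing values")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient model matrix: collinear or repeated terms")
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  n <- nrow(X); p <- ncol(X)
  df_res <- n - p
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  sigma2 <- if (df_res > 0) ss_res / df_res else NA_real_
  Ru <- qr.R(qx)
  cov_unscaled <- chol2inv(Ru)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  se <- if (is.na(sigma2)) rep(NA_real_, p) else sqrt(sigma2 * diag(cov_unscaled))
  tcrit <- if (df_res > 0) stats::qt(1 - (1 - level) / 2, df_res) else NA_real_
  ci <- cbind(lower = coef - tcrit * se, upper = coef + tcrit * se)
  Q <- qr.Q(qx)
  hat <- rowSums(Q^2)
  structure(list(response = response, terms = colnames(X), coef = coef,
                 se = se, ci = ci, level = level, r2 = r2, sigma2 = sigma2,
                 df_res = df_res, ss_res = ss_res, ss_tot = ss_tot,
                 cov_unscaled = cov_unscaled, hat = hat, residuals = res,
                 fitted = fitted, y = y, X = X, model = model,
                 transform = transform,
                 q2 = NA_real_, validity = NA_real_, p_lof = NA_real_,
                 reproducibility = NA_real_),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Response '%s' (%s scale): R2 = %.3f, Q2 = %.3f, validity = %.3f, reproducibility = %.3f\n",
              x$response, x$transform, x$r2, x$q2, x$validity,
              x$reproducibility))
  tab <- data.frame(coef = x$coef, se = x$se,
                    lower = x$ci[, 1], upper = x$ci[, 2])
  print(round(tab, 4))
  invisible(x)
}

#' Leave-one-out prediction precision (Q2)
#'
#' PRESS computed by the hat-matrix shortcut (`e_i / (1 - h_ii)` summed in
#' squares), algebraically identical to refitting with each run left out;
#' `Q2 = 1 - PRESS/SStot`. Q2 can be negative — the model then predicts new
#' runs worse than the response mean — and is reported as computed. Runs
#' with leverage numerically at 1 make leave-one-out prediction undefined
#' and yield `-Inf`.
#'
#' @param X model matrix, `nrow(X) > ncol(X)`.
#' @param y response vector.
#' @return Q2 (numeric scalar) with the PRESS value as attribute `"press"`.
#' @export
q2_press <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("Q2 requires more runs than parameters")
  fit <- fit_mlr(X, y)
  one_minus_h <- 1 - fit$hat
  if (any(one_minus_h < 1e-10)) {
    press <- Inf
  } else {
    press <- sum((fit$residuals / one_minus_h)^2)
  }
  q2 <- if (fit$ss_tot > 0) 1 - press / fit$ss_tot else 0
  structure(q2, press = press)
}

#' Model validity from the lack-of-fit test
#'
#' Partitions the residual sum of squares into pure error (within replicate
#' groups, typically the center points) and lack of fit, forms the F test,
#' and maps the p-value through the conventional DoE score
#' `validity = 1 + 0.57647 * log10(p_lof)`, capped at 1. The scaling makes
#' `p_lof = 0.05` correspond exactly to the customary 0.25 acceptance floor:
#' values above 0.25 indicate no detectable lack of fit at the 5% level.
#'
#' @param fit a `fitted_model` from [fit_mlr()], or a model matrix (with `y`
#'   supplied).
#' @param groups replicate grouping: a factor/vector over runs, or a logical
#'   vector marking one replicated group (e.g. `design$is_center`). Groups
#'   with fewer than 2 members contribute no pure error.
#' @param y response vector when `fit` is a matrix.
#' @return List: `validity`, `p_lof`, `f`, `df_lof`, `df_pe`, `ss_lof`,
#'   `ss_pe`. `validity` is `NA` when no replicate group or no lack-of-fit
#'   degrees of freedom exist.
#' @export
model_validity <- function(fit, groups, y = NULL) {
  if (!inherits(fit, "fitted_model")) fit <- fit_mlr(as.matrix(fit), y)
  g <- .replicate_groups(groups, length(fit$y))
  pe <- .pure_error(fit$y, g)
  if (pe$df == 0)
    return(list(validity = NA_real_, p_lof = NA_real_, f = NA_real_,
                df_lof = NA_real_, df_pe = 0, ss_lof = NA_real_, ss_pe = 0))
  ss_lof <- fit$ss_res - pe$ss
  df_lof <- fit$df_res - pe$df
  if (df_lof <= 0)
    return(list(validity = NA_real_, p_lof = NA_real_, f = NA_real_,
                df_lof = df_lof, df_pe = pe$df, ss_lof = ss_lof,
                ss_pe = pe$ss))
  ss_lof <- max(ss_lof, 0)
  f <- (ss_lof / df_lof) / (pe$ss / pe$df)
  p <- stats::pf(f, df_lof, pe$df, lower.tail = FALSE)
  list(validity = validity_score(p), p_lof = p, f = f,
       df_lof = df_lof, df_pe = pe$df, ss_lof = ss_lof, ss_pe = pe$ss)
}

#' @rdname model_validity
#' @param p_lof lack-of-fit p-value(s).
#' @export
validity_score <- function(p_lof) {
  pmin(1, 1 + 0.57647 * log10(pmax(p_lof, .Machine$double.xmin)))
}

.replicate_groups <- function(groups, n) {
  if (is.logical(groups)) {
    g <- rep(NA_character_, n)
    g[groups] <- "replicate"
    g
  } else as.character(groups)
}

.pure_error <- function(y, g) {
  ss <- 0; df <- 0
  for (lev in unique(stats::na.omit(g))) {
    yy <- y[!is.na(g) & g == lev]
    if (length(yy) >= 2) {
      ss <- ss + sum((yy - mean(yy))^2)
      df <- df + length(yy) - 1
    }
  }
  list(ss = ss, df = df)
}

#' Replicate reproducibility
#'
#' `1 - (pooled within-replicate variance) / (total response variance)`:
#' 1 when replicates are identical, 0 when replicate scatter is as large as
#' the response's total scatter. Values above 0.5 are conventionally read as
#' acceptable replicate control.
#'
#' @param y response vector over all runs.
#' @param groups replicate grouping as in [model_validity()].
#' @return Numeric score <= 1 (`NA` without replicates or with constant
#'   response).
#' @export
reproducibility <- function(y, groups) {
  g <- .replicate_groups(groups, length(y))
  pe <- .pure_error(y, g)
  tot <- stats::var(y)
  if (pe$df == 0 || !is.finite(tot) || tot == 0) return(NA_real_)
  1 - (pe$ss / pe$df) / tot
}

#' Fit interaction models for every response of a campaign
#'
#' Runs the full per-response pipeline: optional center-point batch
#' normalization, the response transform, the least-squares interaction fit,
#' and the four quality metrics (R2, Q2, lack-of-fit validity using the
#' center-point replicates, reproducibility).
#'
#' @param design a `design_table` (batches assigned when `normalize = TRUE`).
#' @param responses data.frame keyed by `run_id` with numeric responses.
#' @param model a [model_spec()]; default full two-factor interaction model.
#' @param transforms named character vector mapping response names to
#'   transform tags (unnamed responses use `"identity"`), e.g.
#'   `c(OCT4_flow = "neglog")`.
#' @param normalize apply [normalize_to_center_points()] first (default
#'   `TRUE`).
#' @return A `doe_fit`: list of `fitted_model`s (one per response) plus the
#'   design, model and normalized response table.
#' @export
fit_response_models <- function(design, responses,
                                model = model_spec(design_factors(design)),
                                transforms = NULL, normalize = TRUE) {
  if (normalize) responses <- normalize_to_center_points(responses, design)
  responses <- responses[match(design$run_id, responses$run_id), ,
                         drop = FALSE]
  X <- build_model_matrix(design, model)
  groups <- design$is_center
  cols <- setdiff(names(responses)[vapply(responses, is.numeric, TRUE)],
                  "run_id")
  fits <- list()
  for (col in cols) {
    if (all(is.na(responses[[col]]))) next
    tr <- if (!is.null(transforms) && col %in% names(transforms))
      transforms[[col]] else "identity"
    y <- apply_transform(responses[[col]], tr)
    fit <- fit_mlr(X, y, response = col, model = model, transform = tr)
    fit$q2 <- if (nrow(X) > ncol(X)) as.numeric(q2_press(X, y)) else NA_real_
    v <- model_validity(fit, groups)
    fit$validity <- v$validity
    fit$p_lof <- v$p_lof
    fit$reproducibility <- reproducibility(y, groups)
    fits[[col]] <- fit
  }
  structure(list(models = fits, design = design, model = model,
                 responses = responses),
            class = "doe_fit")
}

#' @export
print.doe_fit <- function(x, ...) {
  cat(sprintf("DoE fit: %d responses, %d runs, p = %d\n",
              length(x$models), nrow(x$design), n_parameters(x$model)))
  print(round_df(metric_table(x), 3))
  invisible(x)
}

#' Model-quality metric table
#' @param fit a `doe_fit` from [fit_response_models()].
#' @return data.frame with one row per response and columns `r2`, `q2`,
#'   `validity`, `reproducibility`.
#' @export
metric_table <- function(fit) {
  data.frame(
    response = names(fit$models),
    r2 = vapply(fit$models, `[[`, 0, "r2"),
    q2 = vapply(fit$models, `[[`, 0, "q2"),
    validity = vapply(fit$models, `[[`, 0, "validity"),
    reproducibility = vapply(fit$models, `[[`, 0, "reproducibility"),
    row.names = NULL)
}

#' Predict a fitted response at coded settings
#'
#' @param object a `fitted_model` (must carry its [model_spec()]).
#' @param x coded settings: vector of length n_factors or a matrix.
#' @param interval `"none"`, `"confidence"` (mean response) or
#'   `"prediction"` (new observation).
#' @param level interval coverage.
#' @param scale `"model"` (the fitted, possibly transformed scale) or
#'   `"response"` (back-transformed).
#' @param ... unused.
#' @return data.frame with `fit`, `se` (model scale) and interval bounds.
#' @export
predict.fitted_model <- function(object, x,
                                 interval = c("none", "confidence",
                                              "prediction"),
                                 level = 0.95,
                                 scale = c("model", "response"), ...) {
  interval <- match.arg(interval)
  scale <- match.arg(scale)
  if (is.null(object$model))
    stop("fitted_model carries no model_spec; refit via fit_response_models()")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  colnames(x) <- object$model$factors
  F <- build_model_matrix(x, object$model)
  mu <- drop(F %*% object$coef)
  lev <- rowSums((F %*% object$cov_unscaled) * F)
  se_fit <- sqrt(object$sigma2 * lev)
  se <- switch(interval, none = se_fit, confidence = se_fit,
               prediction = sqrt(object$sigma2 * (1 + lev)))
  out <- data.frame(fit = mu, se = se)
  if (interval != "none") {
    tcrit <- stats::qt(1 - (1 - level) / 2, object$df_res)
    out$lwr <- mu - tcrit * se
    out$upr <- mu + tcrit * se
  }
  if (scale == "response" && object$transform != "identity") {
    out$fit <- invert_transform(out$fit, object$transform)
    if (interval != "none") {
      lo <- invert_transform(out$upr, object$transform)
      hi <- invert_transform(out$lwr, object$transform)
      out$lwr <- pmin(lo, hi); out$upr <- pmax(lo, hi)
    }
  }
  out
}

#' Pearson correlation matrix across responses
#'
#' Pairwise Pearson correlations between response columns with two-sided
#' t-test p-values, as used to relate aggregate size to the other culture
#' responses. Both matrices are symmetric with unit (r) / zero (p) diagonal.
#'
#' @param responses data.frame keyed by `run_id` with numeric responses.
#' @param pairs optional character vector restricting to these columns.
#' @return A `response_correlation` list of matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(responses, pairs = NULL) {
  cols <- setdiff(names(responses)[vapply(responses, is.numeric, TRUE)],
                  "run_id")
  if (!is.null(pairs)) cols <- intersect(cols, pairs)
  m <- as.matrix(responses[, cols, drop = FALSE])
  k <- length(cols)
  r <- diag(1, k); p <- matrix(0, k, k); n <- matrix(nrow(m), k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(cols, cols)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(m[, i], m[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) {
      r[i, j] <- r[j, i] <- NA_real_; p[i, j] <- p[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n), class = "response_correlation")
}

#' @export
print.response_correlation <- function(x, ...) {
  cat("Response correlations (Pearson r):\n")
  print(round(x$r, 3))
  invisible(x)
}
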