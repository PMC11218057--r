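# Shared fixtures and independent oracles, built in code.

two_factors <- function() factor_set(c("A", "B"), c(0, 0), c(1, 1))

five_factors <- function() default_factors()

# exhaustive D-optimal oracle: best log det(X'X) over all n-run designs
# drawn from the candidate rows with repetition allowed (replicated runs are
# legitimate designs); enumeration, independent of the exchange search
exhaustive_logdet <- function(candidates, model, n_runs) {
  F <- build_model_matrix(candidates, model)
  best <- -Inf
  multisets <- function(start, left, rows) {
    if (left == 0) {
      d <- determinant(crossprod(F[rows, , drop = FALSE]), logarithm = TRUE)
      if (d$sign > 0 && d$modulus > best) best <<- as.numeric(d$modulus)
      return(invisible())
    }
    for (i in start:nrow(F)) multisets(i, left - 1, c(rows, i))
  }
  multisets(1, n_runs, integer(0))
  best
}

# explicit leave-one-out PRESS by refitting (oracle for the hat shortcut)
loo_press <- function(X, y) {
  sum(vapply(seq_len(nrow(X)), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    (y[i] - sum(X[i, ] * b))^2
  }, 0))
}

# noise-free reactor series following the exponential forward model:
# counts N0 e^{Kt}, all aggregates identical, volume growing as e^{K dt}
forward_series <- function(K = 0.5, d1 = 65, N0 = 1.1e5, days = 0:4,
                           n_diam = 30) {
  v1 <- sphere_volume(d1 / 2)
  reactor_series(
    "fwd", days,
    counts = lapply(days, function(t) rep(N0 * exp(K * t), 3)),
    diameters = lapply(days, function(t) {
      if (t < 1) NULL
      else rep(sphere_diameter(v1 * exp(K * (t - 1))), n_diam)
    }))
}

# tiny fitted model on a known linear truth over k factors
linear_fit <- function(coef, factors = two_factors(), n = 12, seed = 1,
                       sd = 0) {
  model <- model_spec(factors)
  set.seed(seed)
  X <- matrix(runif(n * nrow(factors), -1, 1), ncol = nrow(factors),
              dimnames = list(NULL, factors$name))
  F <- build_model_matrix(X, model)
  stopifnot(all(names(coef) %in% colnames(F)))
  beta <- structure(numeric(ncol(F)), names = colnames(F))
  beta[names(coef)] <- coef
  y <- drop(F %*% beta) + rnorm(n, 0, sd)
  fit_mlr(F, y, model = model)
}
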