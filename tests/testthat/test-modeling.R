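test_that("model matrix has the expected structure", {
  f <- two_factors()
  m <- model_spec(f)
  corners <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  colnames(corners) <- f$name
  F <- build_model_matrix(corners, m)
  expect_equal(dim(F), c(4, 4))
  expect_equal(unname(crossprod(F)), diag(4) * 4)
  ctr <- build_model_matrix(matrix(0, 1, 2, dimnames = list(NULL, f$name)), m)
  expect_equal(as.numeric(ctr), c(1, 0, 0, 0))
  expect_equal(n_parameters(model_spec(five_factors())), 1 + 5 + 10)
})

test_that("transforms behave and invert", {
  y <- c(0.3, 50, 99)
  expect_identical(apply_transform(y, "identity"), y)
  expect_equal(apply_transform(100, "neglog", eps = 0), 0)
  expect_equal(apply_transform(10, "neglog", eps = 0), 1, tolerance = 1e-12)
  expect_equal(invert_transform(apply_transform(y, "neglog"), "neglog"), y,
               tolerance = 1e-9)
  expect_error(apply_transform(-5, "neglog"), "nonpositive")
})

test_that("center-point normalization rescales batches and is idempotent", {
  f <- two_factors()
  coded <- rbind(c(-1, -1), c(1, 1), c(0, 0), c(-1, 1), c(1, -1), c(0, 0))
  d <- design_table(coded, f)
  d$batch <- c("B1", "B1", "B1", "B2", "B2", "B2")
  resp <- data.frame(run_id = d$run_id, y = c(10, 20, 12, 30, 40, 24))
  out <- normalize_to_center_points(resp, d)
  # batch B2's center sits at 2x batch B1's: B2 values are scaled down
  grand <- mean(c(12, 24))
  expect_equal(out$y, c(10, 20, 12, 30, 40, 24) *
                 rep(c(grand / 12, grand / 24), each = 3))
  # center grand mean preserved, batch center means equalized
  expect_equal(mean(out$y[c(3, 6)]), grand)
  expect_equal(out$y[3], out$y[6])
  # idempotent
  expect_equal(normalize_to_center_points(out, d)$y, out$y, tolerance = 1e-12)
  # identical centers leave everything untouched
  resp2 <- data.frame(run_id = d$run_id, y = c(1, 2, 5, 3, 4, 5))
  expect_equal(normalize_to_center_points(resp2, d)$y, resp2$y)
  # degenerate cases are explicit errors
  resp3 <- data.frame(run_id = d$run_id, y = c(1, 2, 0, 3, 4, 5))
  expect_error(normalize_to_center_points(resp3, d), "zero")
  d2 <- d; d2$batch[c(3, 6)] <- "B1"; d2$is_center[6] <- FALSE
  d2$batch[6] <- "B2"
  expect_error(normalize_to_center_points(resp, d2), "no center point")
})

test_that("least squares recovers exact truths and handles degeneracies", {
  fit <- linear_fit(c("(Intercept)" = 2, A = 1.5, "A:B" = -0.7))
  expect_lt(max(abs(fit$coef - c(2, 1.5, 0, -0.7))), 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # orthogonal 2^2 design: coefficients are the +/- contrasts / 4
  f <- two_factors()
  corners <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  colnames(corners) <- f$name
  F <- build_model_matrix(corners, model_spec(f))
  y <- c(3, 5, 7, 13)
  fit2 <- fit_mlr(F, y)
  expect_equal(unname(fit2$coef),
               as.numeric(crossprod(F, y) / 4), tolerance = 1e-12)
  # constant response: R2 defined as 0
  Fn <- build_model_matrix(rbind(corners, corners), model_spec(f))
  expect_equal(fit_mlr(Fn, rep(4, 8))$r2, 0)
  # rank deficiency is an explicit error
  expect_error(fit_mlr(cbind(Fn, Fn[, 2]), rep(4, 8)), "rank")
})

test_that("hat-matrix PRESS equals explicit leave-one-out refits", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(6:15, 1); p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    q2 <- q2_press(X, y)
    expect_equal(attr(q2, "press"), loo_press(X, y), tolerance = 1e-9)
    expect_lte(as.numeric(q2), fit_mlr(X, y)$r2 + 1e-12)
  }
})

test_that("Q2 is near 1 for noiseless truth and negative for pure noise", {
  fit <- linear_fit(c("(Intercept)" = 1, A = 2, B = -1), n = 15)
  expect_gt(as.numeric(q2_press(fit$X, fit$y)), 1 - 1e-9)
  set.seed(3)
  q2s <- replicate(500, {
    X <- cbind(1, matrix(rnorm(8 * 3), 8))
    as.numeric(q2_press(X, rnorm(8)))
  })
  expect_lt(median(q2s), 0)
})

test_that("validity maps the lack-of-fit p-value onto the conventional scale", {
  expect_equal(validity_score(1), 1)
  expect_equal(validity_score(0.05), 0.25, tolerance = 1e-3)
  # a correctly specified model shows no systematic lack of fit
  f <- two_factors()
  coded <- rbind(candidate_set(f, 2), c(0, 0), c(0, 0), c(0, 0))
  colnames(coded) <- f$name
  F <- build_model_matrix(coded, model_spec(f))
  groups <- c(rep(NA, 4), rep("ctr", 3))
  set.seed(21)
  vals <- replicate(200, {
    y <- drop(F %*% c(1, 0.5, -0.5, 0.2)) + rnorm(7, 0, 0.3)
    model_validity(F, groups, y = y)$validity
  })
  expect_gt(median(vals), 0.25)
  # no replicates: undefined
  expect_true(is.na(model_validity(F, rep(NA, 7),
                                   y = rnorm(7))$validity))
})

test_that("reproducibility is the 1 - replicate/total variance ratio", {
  groups <- c(NA, NA, NA, "c", "c", "c")
  y_perfect <- c(1, 5, 9, 4, 4, 4)
  expect_equal(reproducibility(y_perfect, groups), 1)
  y <- c(1, 5, 9, 3, 4, 5)
  expect_equal(reproducibility(y, groups),
               1 - var(c(3, 4, 5)) / var(y), tolerance = 1e-12)
  # replicate variance equal to total variance scores 0
  y0 <- c(4, 4, 4, 1, 4, 7)
  expect_equal(reproducibility(y0, groups), 1 - var(c(1, 4, 7)) / var(y0))
})

test_that("correlation matrix is symmetric, exact on degenerate pairs, affine-invariant", {
  set.seed(5)
  resp <- data.frame(run_id = sprintf("R%02d", 1:19),
                     a = rnorm(19))
  resp$b <- -resp$a
  resp$c <- rnorm(19)
  cm <- correlation_matrix(resp)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  resp2 <- resp
  resp2$a <- 100 - 3 * resp$a   # affine rescale flips sign only
  cm2 <- correlation_matrix(resp2)
  expect_equal(abs(cm2$r), abs(cm$r), tolerance = 1e-12)
  expect_equal(cm2$p, cm$p, tolerance = 1e-9)
})

test_that("correlation estimate is calibrated at the campaign sample size", {
  rho <- 0.8; n <- 19
  set.seed(8)
  rhat <- replicate(2000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  })
  expect_lt(abs(mean(rhat) - rho), 0.03)
  # and the package path agrees with cor() on one draw
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cm <- correlation_matrix(data.frame(run_id = seq_len(n), x = x, y = y))
  expect_equal(cm$r["x", "y"], cor(x, y), tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], cor.test(x, y)$p.value, tolerance = 1e-12)
})
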