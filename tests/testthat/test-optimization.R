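test_that("piecewise-linear desirability hits its anchors", {
  up <- criterion("y", "maximize", low = 0, high = 10)
  expect_equal(desirability(10, up), 1)
  expect_equal(desirability(12, up), 1)
  expect_equal(desirability(0, up), 0)
  expect_equal(desirability(5, up), 0.5)
  dn <- criterion("y", "minimize", low = 1, high = 3)
  expect_equal(desirability(c(0.5, 2, 4), dn), c(1, 0.5, 0))
  tg <- criterion("y", "target", low = 0, high = 4, target = 1)
  expect_equal(desirability(c(0, 0.5, 1, 2.5, 4), tg), c(0, 0.5, 1, 0.5, 0))
  rg <- criterion("y", "range", low = 0, high = 1)
  expect_equal(desirability(c(-0.1, 0.5, 1.1), rg), c(0, 1, 0))
})

test_that("overall desirability is the weighted geometric mean", {
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  expect_equal(overall_desirability(c(0.9, 0, 1)), 0)
  expect_equal(overall_desirability(c(0.25, 1)), 0.5)
  expect_equal(overall_desirability(c(0.25, 1), weights = c(2, 1)),
               0.25^(2 / 3), tolerance = 1e-12)
  expect_error(overall_desirability(c(1.2, 0.5)), "0, 1")
})

test_that("Cpk measures distance to the nearest limit in 3-sigma units", {
  expect_equal(cpk(0, 1, -3, 3), 1)
  expect_equal(cpk(10, 1, upper_spec = 12.7), 0.9)
  expect_equal(cpk(0, 2, -3, 3), 0.5)
  # affine invariance: shift and scale mean, sd and limits together
  set.seed(2)
  for (i in 1:20) {
    mu <- rnorm(1); s <- runif(1, 0.5, 2)
    lo <- mu - runif(1, 1, 5) * s; hi <- mu + runif(1, 1, 5) * s
    a <- rnorm(1); b <- runif(1, 0.1, 3)
    expect_equal(cpk(a + b * mu, b * s, a + b * lo, a + b * hi),
                 cpk(mu, s, lo, hi), tolerance = 1e-9)
  }
  expect_error(cpk(0, 1), "finite")
})

test_that("failure probability: closed form matches Monte Carlo and anchors", {
  p6 <- probability_of_failure(0, 1, -3, 3)
  expect_equal(p6, 100 * 2 * pnorm(-3), tolerance = 1e-9)  # 0.27%
  expect_equal(probability_of_failure(5, 2), 0)
  n <- 1e5
  pmc <- probability_of_failure(0, 1, -1.5, 2, method = "mc", n_draws = n,
                                seed = 4)
  pcl <- probability_of_failure(0, 1, -1.5, 2)
  se <- 100 * sqrt(pcl / 100 * (1 - pcl / 100) / n)
  expect_lt(abs(pmc - pcl), 3 * se)
})

test_that("setpoint search honors monotone, symmetric and oracle cases", {
  # rising linear response: optimum at the +1 bound of the active factor
  fit <- linear_fit(c("(Intercept)" = 5, A = 2), sd = 0)
  crit <- list(criterion("y", "maximize", low = 4, high = 8))
  sp <- optimize_setpoint(list(y = fit), crit, seed = 1)
  expect_equal(unname(sp$coded["A"]), 1, tolerance = 1e-6)
  expect_equal(sp$desirability, desirability(7, crit[[1]]), tolerance = 1e-6)
  # conflicting symmetric goals meet at the symmetry point
  f_up <- linear_fit(c("(Intercept)" = 0, A = 1), sd = 0)
  crit2 <- list(criterion("up", "target", low = -2, high = 2, target = 1),
                criterion("dn", "target", low = -2, high = 2, target = -1))
  sp2 <- optimize_setpoint(list(up = f_up, dn = f_up), crit2, seed = 1)
  expect_lt(abs(sp2$coded["A"]), 1e-4)
  # interior optimum against a dense grid-search oracle
  fitA <- linear_fit(c("(Intercept)" = 0, A = 1, B = 0.4, "A:B" = 0.3),
                     sd = 0)
  crit3 <- list(criterion("y", "target", low = -1, high = 1, target = 0.2))
  sp3 <- optimize_setpoint(list(y = fitA), crit3, seed = 2)
  g <- as.matrix(expand.grid(A = seq(-1, 1, 0.05), B = seq(-1, 1, 0.05)))
  Dg <- apply(g, 1, function(x) {
    desirability(predict(fitA, x)$fit, crit3[[1]])
  })
  expect_gte(sp3$desirability, max(Dg) - 0.01)
  expect_error(optimize_setpoint(list(y = fitA),
                                 list(criterion("z", "maximize", 0, 1))),
               "unfitted")
})

test_that("factor contributions reflect spans and interaction partners", {
  only_a <- linear_fit(c("(Intercept)" = 1, A = 2), sd = 0)
  fc <- factor_contributions(list(y = only_a), c(A = 0, B = 0))
  expect_equal(unname(fc[, "y"]), c(100, 0), tolerance = 1e-6)
  both <- linear_fit(c("(Intercept)" = 1, A = 2, B = -2), sd = 0)
  fc2 <- factor_contributions(list(y = both), c(A = 0, B = 0))
  expect_equal(unname(fc2[, "y"]), c(50, 50), tolerance = 1e-6)
  inter <- linear_fit(c("(Intercept)" = 0, "A:B" = 1), sd = 0)
  fc_ctr <- factor_contributions(list(y = inter), c(A = 0, B = 0))
  expect_equal(sum(fc_ctr[, "y"]), 0)   # flat at the center
  fc_off <- factor_contributions(list(y = inter), c(A = 0.8, B = 0.8))
  expect_gt(min(fc_off[, "y"]), 0)      # active once the partner is off-center
})

test_that("setpoint profiles follow the model and widen toward the edges", {
  fit <- linear_fit(c("(Intercept)" = 1, A = 2), n = 20, sd = 0.1, seed = 4)
  pr <- setpoint_profile(fit, c(A = 0, B = 0), "A", n_points = 11)
  slope <- coef(lm(fit ~ x, data = pr))[2]
  expect_equal(unname(slope), unname(fit$coef["A"]), tolerance = 1e-6)
  halfwidth <- (pr$upr - pr$lwr) / 2
  expect_gt(halfwidth[1], halfwidth[6])        # edge wider than center
  expect_gt(halfwidth[11], halfwidth[6])
  inter <- linear_fit(c("(Intercept)" = 0, "A:B" = 1.5), n = 20, sd = 0.05,
                      seed = 6)
  flat <- setpoint_profile(inter, c(A = 0, B = 0), "A", n_points = 7)
  expect_lt(diff(range(flat$fit)), 0.2)
  crit <- criterion("y", "maximize", low = 0, high = 2)
  withp <- setpoint_profile(fit, c(A = 0, B = 0), "A", n_points = 7,
                            criterion = crit, n_mc = 20000, seed = 1)
  closed <- setpoint_profile(fit, c(A = 0, B = 0), "A", n_points = 7,
                             criterion = crit)
  expect_lt(max(abs(withp$pass_prob - closed$pass_prob)), 0.02)
})
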