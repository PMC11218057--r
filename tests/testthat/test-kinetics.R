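test_that("sphere volume matches the closed form and inverts cleanly", {
  expect_equal(sphere_volume(5), 523.5988, tolerance = 1e-6)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(50), 1000 * sphere_volume(5), tolerance = 1e-12)
  expect_error(sphere_volume(-1), ">= 0")
  r <- c(0.1, 5, 50, 123.4)
  expect_equal(sphere_diameter(sphere_volume(r)), 2 * r, tolerance = 1e-9)
})

test_that("cell number per aggregate follows the packing-density rule", {
  expect_equal(cells_per_aggregate(sphere_volume(50)), 640, tolerance = 1e-9)
  expect_equal(cells_per_aggregate(0), 0)
  g1 <- geometry_constants(packing_density = 1)
  expect_equal(cells_per_aggregate(g1$cell_volume, g1), 1)
  # inverse round-trip through the predicted volume
  N <- c(1, 10, 640, 1e4)
  expect_equal(cells_per_aggregate(predicted_volume(N)), N, tolerance = 1e-12)
  expect_equal(predicted_volume(640), sphere_volume(50), tolerance = 1e-9)
})

test_that("forward cell projection is exponential in the horizon", {
  expect_equal(predict_future_cells(250, 0), 250)
  expect_equal(predict_future_cells(100, log(2)), 800, tolerance = 1e-12)
  expect_equal(predict_future_cells(100, -log(2)), 12.5, tolerance = 1e-12)
  g <- geometry_constants(horizon_days = 2)
  expect_equal(predict_future_cells(100, log(2), g), 400, tolerance = 1e-12)
})

test_that("aggregate percent error is the relative volume discrepancy", {
  expect_equal(aggregate_pct_error(100, 100), 0)
  expect_equal(aggregate_pct_error(2, 1), 0.5)      # one fusion per pair
  expect_equal(aggregate_pct_error(0.5, 1), -1)     # fragmentation
  expect_error(aggregate_pct_error(0, 1), "> 0")
})

test_that("growth fit recovers exact exponentials and obeys doubling identity", {
  s <- forward_series(K = 0.5)
  g <- fit_growth_rate(s)
  expect_equal(g$K, 0.5, tolerance = 1e-12)
  expect_equal(g$r2_fit, 1, tolerance = 1e-9)
  expect_equal(log(2) / 0.4, 1.7329, tolerance = 1e-4)
  for (K in c(0.05, 0.3, 0.69, 1.2)) {
    g <- fit_growth_rate(forward_series(K = K))
    expect_equal(g$doubling_time * g$K, log(2), tolerance = 1e-9)
  }
  one_day <- reactor_series("x", 0, counts = list(c(1e5, 1e5, 1e5)))
  expect_error(fit_growth_rate(one_day), "two days")
  expect_error(reactor_series("x", 0:1, counts = list(1e5, -2)),
               "nonpositive")
})

test_that("noisy growth-rate estimates are unbiased to within 2%", {
  K <- 0.5; cv <- 0.1
  s <- sqrt(log(1 + cv^2))
  set.seed(42)
  Khat <- replicate(1000, {
    days <- 0:4
    counts <- lapply(days, function(t)
      rlnorm(3, log(1e5) + K * t - s^2 / 2, s))
    fit_growth_rate(reactor_series("n", days, counts))$K
  })
  expect_lt(abs(mean(Khat) - K) / K, 0.02)
})

test_that("diameter statistics: means, sample SD, linear slope", {
  s <- reactor_series("d", 1:3, counts = list(1, 2, 4),
                      diameters = list(rep(100, 30), rep(110, 30),
                                       rep(120, 30)))
  ds <- diameter_stats(s)
  expect_equal(ds$per_day$mean, c(100, 110, 120))
  expect_equal(ds$per_day$sd, c(0, 0, 0))
  expect_equal(ds$slope, 10, tolerance = 1e-9)
  s2 <- reactor_series("d", 1:2, counts = list(1, 2),
                       diameters = list(c(90, 110), 105))
  ds2 <- diameter_stats(s2)
  expect_equal(ds2$per_day$mean, c(100, 105))
  expect_true(is.na(ds2$per_day$sd[2]))
  expect_equal(ds2$per_day$sd[1], sd(c(90, 110)))
})

test_that("stability chain is self-consistent on the noise-free forward model", {
  for (K in c(0.2, 0.5, 0.8)) {
    st <- stability_from_series(forward_series(K = K))
    expect_lt(abs(st$pct_error), 1e-9)
  }
  # volume doubling beyond growth (pairwise fusion) gives +0.5
  s <- forward_series(K = 0.5)
  v4 <- sphere_volume(s$diameters[[5]][1] / 2) * 2
  s$diameters[[5]] <- rep(sphere_diameter(v4), 30)
  expect_equal(stability_from_series(s)$pct_error, 0.5, tolerance = 1e-9)
  # missing comparison-day diameters is an explicit error
  s$diameters[5] <- list(NULL)
  expect_error(stability_from_series(s), "comparison day")
})

test_that("qPCR delta-Ct normalization halves per cycle", {
  expect_equal(qpcr_normalize(20, 20), 1000)
  expect_equal(qpcr_normalize(21, 20), 500)
  expect_equal(qpcr_normalize(19, 20), 2000)
  expect_error(qpcr_normalize(NA, 20), "finite")
})
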