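zero_noise_truth <- function(...) {
  sim_truth(count_cv = 0, diameter_sdlog = 0, marker_sd = 0,
            batch_sdlog = 0, fusion_base = 0, frag_rate = 0, ...)
}

test_that("reactor simulation is bit-identical under the same seed", {
  tr <- sim_truth()
  x <- c(DS = 0.5, HS = -1, PVA = 0, PA = 1, PEG = -0.5)
  s1 <- simulate_reactor(x, tr, seed = 123)
  s2 <- simulate_reactor(x, tr, seed = 123)
  expect_identical(s1, s2)
  s3 <- simulate_reactor(x, tr, seed = 124)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("noise-free growth follows the exponential diameter law", {
  tr <- zero_noise_truth()
  s <- simulate_reactor(rep(0.3, 5), tr, seed = 1)
  K <- tr$K0 + sum(0.3 * c(-0.03, 0.02, 0.03, 0.04, 0.05)) +
    0.09 * (0.02 + 0.03)
  d1 <- mean(s$diameters[[2]])
  for (t in 2:4) {
    dt <- mean(s$diameters[[t + 1]])
    expect_equal(dt, d1 * exp(K * (t - 1) / 3), tolerance = 1e-9)
  }
  # counts are exactly N0 e^{Kt}
  expect_equal(mean(s$counts[[5]]), tr$N0 * exp(4 * K), tolerance = 1e-9)
})

test_that("without fusion or noise the stability statistic vanishes", {
  tr <- zero_noise_truth()
  for (x in list(rep(0, 5), rep(1, 5), rep(-0.5, 5))) {
    s <- simulate_reactor(x, tr, seed = 7)
    expect_lt(abs(stability_from_series(s, tr$geom)$pct_error), 1e-6)
  }
})

test_that("percent error rises with fusion and falls with fragmentation", {
  pe <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(lam) {
    tr <- sim_truth(count_cv = 0, diameter_sdlog = 0, marker_sd = 0,
                    batch_sdlog = 0, fusion_base = lam, frag_rate = 0,
                    fusion_beta = numeric(0), n_aggregates = 4000,
                    n_measure = 4000)
    mean(vapply(1:3, function(s)
      stability_from_series(simulate_reactor(rep(0, 5), tr, seed = s),
                            tr$geom)$pct_error, 0))
  }, 0)
  expect_true(all(diff(pe) > 0))
  expect_lt(abs(pe[1]), 1e-6)
  tr_frag <- sim_truth(count_cv = 0, diameter_sdlog = 0, marker_sd = 0,
                       batch_sdlog = 0, fusion_base = 0, frag_rate = 0.3,
                       n_aggregates = 2000, n_measure = 2000)
  pef <- stability_from_series(simulate_reactor(rep(0, 5), tr_frag,
                                                seed = 2), tr_frag$geom)
  expect_lt(pef$pct_error, 0)
})

test_that("fusion conserves volume and drops the count by one per event", {
  set.seed(31)
  vol <- rlnorm(100, log(1e5), 0.3)
  merged <- aggdoe:::.fusion_step(vol, lam = 0.2)
  expect_lt(length(merged), length(vol))
  expect_equal(sum(merged), sum(vol), tolerance = 1e-9)
  split <- aggdoe:::.fragmentation_step(vol, lam = 0.2)
  expect_gt(length(split), length(vol))
  expect_equal(sum(split), sum(vol), tolerance = 1e-9)
})

test_that("campaign responses carry the truth's coefficient structure", {
  des <- default_campaign_design(seed = 0)
  tr_low <- zero_noise_truth(
    response_truth = local({
      rt <- default_response_truth()
      for (nm in names(rt)) rt[[nm]]$noise_sd <- 0
      rt
    }))
  camp <- simulate_campaign(des, tr_low, seed = 5)
  fits <- fit_response_models(des, camp$responses, normalize = FALSE)
  # zero noise: linear-scale truths are recovered
  b <- tr_low$response_truth$NANOG_qpcr$beta
  expect_lt(max(abs(fits$models$NANOG_qpcr$coef[names(b)] - b)), 1e-6)
  bK <- tr_low$beta_K
  expect_lt(max(abs(fits$models$growth_rate$coef[names(bK)] - bK)), 1e-6)
})

test_that("center-point normalization removes simulated batch drift", {
  des <- default_campaign_design(seed = 0)
  tr <- sim_truth(batch_sdlog = 0.2)
  worse <- 0
  for (s in 1:10) {
    camp <- simulate_campaign(des, tr, seed = s)
    ctr <- camp$design$is_center
    batch <- camp$design$batch
    y <- camp$responses$NANOG_qpcr
    norm <- normalize_to_center_points(camp$responses, camp$design)
    spread <- function(v) abs(diff(tapply(v[ctr], batch[ctr], mean)))
    if (spread(norm$NANOG_qpcr) > spread(y)) worse <- worse + 1
  }
  expect_equal(worse, 0)  # batch center gap closes every time
})

test_that("parameter recovery holds at default noise", {
  des <- default_campaign_design(seed = 0)
  rate <- recovery_rate(des, sim_truth(), n_seeds = 60, seed = 100)
  expect_gte(as.numeric(rate), 0.9)
})

test_that("fixtures reproduce bit-identically and match the study shape", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture("campaign19", seed = 2, dir = d1)
  p2 <- make_fixture("campaign19", seed = 2, dir = d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  des <- read_design(p1["design"], default_factors())
  expect_equal(nrow(des), 19)
  expect_equal(sum(des$is_center), 3)
  expect_equal(sort(unique(des$batch)), c("B1", "B2"))
})

test_that("the clean scenario supports high-quality fits end to end", {
  dir <- withr::local_tempdir()
  p <- make_fixture("clean", seed = 1, dir = dir)
  des <- read_design(p["design"], default_factors())
  resp <- read_responses(p["responses"])
  fits <- fit_response_models(des, resp,
                              transforms = c(OCT4_flow = "neglog",
                                             TRA160_flow = "neglog"))
  expect_gt(min(metric_table(fits)$r2), 0.9)
})
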