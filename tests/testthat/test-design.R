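test_that("candidate set is the full factorial grid of coded levels", {
  f1 <- factor_set("A", 0, 1)
  expect_equal(as.numeric(candidate_set(f1, 3)), c(-1, 0, 1))
  expect_equal(nrow(candidate_set(five_factors(), 3)), 3^5)
  g <- candidate_set(two_factors(), 2)
  expect_equal(nrow(g), 4)
  expect_setequal(apply(g, 1, paste, collapse = ","),
                  c("-1,-1", "-1,1", "1,-1", "1,1"))
  expect_error(candidate_set(two_factors(), 1), "levels")
})

test_that("coded and actual settings round-trip exactly", {
  f <- factor_set(c("HS", "PEG", "PVA"), c(0, 0.5, 0), c(0.2, 10, 1),
                  spacing = c("linear", "log", "linear"))
  set.seed(7)
  coded <- matrix(runif(30, -1, 1), ncol = 3)
  back <- actual_to_coded(coded_to_actual(coded, f), f)
  expect_lt(max(abs(back - coded)), 1e-12)
})

test_that("coordinate exchange finds the enumeration optimum on small instances", {
  f <- two_factors()
  cand <- candidate_set(f, 3)
  for (m in list(model_spec(f), model_spec(f, interactions = FALSE))) {
    for (n_runs in 4:5) {
      d <- d_optimal_design(f, m, n_runs = n_runs, seed = 2)
      expect_equal(attr(d, "log_det"),
                   exhaustive_logdet(cand, m, n_runs), tolerance = 1e-9)
    }
  }
  # the 4-run main+interaction optimum is the 2^2 factorial corners
  d <- d_optimal_design(f, model_spec(f), n_runs = 4, seed = 0)
  expect_true(all(abs(coded_matrix(d)) == 1))
})

test_that("design search is deterministic, errors when under-parameterized", {
  f <- five_factors()
  d1 <- d_optimal_design(f, n_runs = 16, seed = 3)
  d2 <- d_optimal_design(f, n_runs = 16, seed = 3)
  expect_identical(coded_matrix(d1), coded_matrix(d2))
  expect_error(d_optimal_design(f, n_runs = 10, seed = 0), "singular")
})

test_that("log det is permutation-invariant and center points never hurt it", {
  f <- two_factors()
  m <- model_spec(f)
  d <- d_optimal_design(f, m, n_runs = 5, seed = 1)
  F <- build_model_matrix(d, m)
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(nrow(F))
    expect_equal(determinant(crossprod(F[perm, ]))$modulus,
                 determinant(crossprod(F))$modulus, tolerance = 1e-12)
  }
  d3 <- add_center_points(d, 1)
  expect_gte(attr(d3, "log_det"), attr(d, "log_det") - 1e-12)
})

test_that("G-efficiency is 100% for the 2^2 factorial and degrades off-optimum", {
  f <- two_factors()
  m <- model_spec(f)
  full <- design_table(rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)), f)
  expect_equal(g_efficiency(full, m), 100, tolerance = 1e-9)
  # replacing a corner with an interior point lowers worst-case efficiency
  worse <- design_table(rbind(c(-1, -1), c(-1, 1), c(1, -1), c(0.5, 0.5)), f)
  expect_lt(g_efficiency(worse, m), 100)
  dup <- design_table(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)), f)
  expect_error(g_efficiency(dup, m), "singular")
})

test_that("center points append at the factor midpoints, flagged", {
  f <- five_factors()
  d <- d_optimal_design(f, n_runs = 16, seed = 0)
  expect_identical(nrow(add_center_points(d, 0)), nrow(d))
  d19 <- add_center_points(d, 3)
  expect_equal(nrow(d19), 19)
  expect_equal(sum(d19$is_center), 3)
  mid <- (f$low + f$high) / 2
  ctr <- actual_matrix(d19)[d19$is_center, , drop = FALSE]
  expect_equal(unname(ctr), matrix(mid, 3, 5, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("batch assignment spreads center points and is deterministic", {
  f <- five_factors()
  d <- add_center_points(d_optimal_design(f, n_runs = 16, seed = 0), 3)
  b <- assign_batches(d, 2, seed = 5)
  expect_false(anyNA(b$batch))
  for (bt in unique(b$batch)) expect_gte(sum(b$is_center & b$batch == bt), 1)
  expect_identical(assign_batches(d, 2, seed = 5)$batch, b$batch)
  one <- assign_batches(d, 1)
  expect_equal(unique(one$batch), "B1")
  d2 <- add_center_points(d_optimal_design(f, n_runs = 16, seed = 0), 2)
  expect_error(assign_batches(d2, 3), "center point")
})
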