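test_that("mse matches its worked examples", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_error(mse(1:3, 1:4), "lengths differ")
})

test_that("Fisher transform identities hold", {
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  rs <- seq(-0.999999, 0.999999, length.out = 101)
  expect_equal(fisher_z_inv(fisher_z(rs)), rs, tolerance = 1e-12)
  # odd symmetry: opposite correlations average to zero
  expect_equal(fisher_z_inv(mean(fisher_z(c(0.5, -0.5)))), 0)
})

test_that("evaluation aggregates per-participant correlations via Fisher z", {
  set.seed(20)
  truth <- rm_raw(matrix(rnorm(30), 10, 3))
  perfect <- structure(list(predicted = truth$values, item_ids = truth$item_ids,
                            participant_ids = truth$participant_ids,
                            condition = list(predictor = "slim"),
                            fallbacks = 0L),
                       class = "prediction_set")
  rep1 <- evaluate(perfect, truth)
  expect_equal(unname(rep1$per_participant_r), rep(1, 3))
  expect_equal(rep1$mse, 0)
  expect_gt(rep1$group_r, 0.999)
  # group r stays between the per-participant extremes
  noisy <- perfect
  noisy$predicted <- truth$values + matrix(rnorm(30, sd = 0.8), 10, 3)
  rep2 <- evaluate(noisy, truth)
  expect_gte(rep2$group_r, min(rep2$per_participant_r) - 1e-12)
  expect_lte(rep2$group_r, max(rep2$per_participant_r) + 1e-12)
  # constant predictions are excluded from the Fisher mean, not fatal
  flat <- perfect
  flat$predicted[, 2] <- 0
  rep3 <- evaluate(flat, truth)
  expect_identical(rep3$excluded, "P02")
  expect_true(is.na(rep3$per_participant_r["P02"]))
  expect_gt(rep3$group_r, 0.999)
})

test_that("paired t-test reproduces the textbook formulas", {
  res <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$sd_diff, 1)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_identical(res$dof, 2L)
  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_equal(same$p_two_tailed, 1)
  a <- c(0.3, 0.1, 0.7, 0.2); b <- c(0.2, 0.4, 0.1, 0.3)
  expect_equal(paired_ttest(a, b)$t, -paired_ttest(b, a)$t)
  expect_equal(paired_ttest(a, b)$p_two_tailed,
               paired_ttest(b, a)$p_two_tailed)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "undefined")
})

test_that("paired t-test agrees with the reference implementation", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    x1 <- rnorm(n); x2 <- rnorm(n, sd = runif(1, 0.5, 2))
    mine <- paired_ttest(x1, x2)
    ref <- t.test(x1, x2, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-9)
  }
})

test_that("permutation test conventions and degeneracy guards", {
  set.seed(22)
  # perfectly consistent cohort: observed transfer beats every permutation
  syn <- small_cohort(seed = 5, consistency = 1, gender_strength = 0,
                      noise_sd = 0)
  gen <- generate_cohort(syn)
  r <- prepare_ratings(gen$ratings)
  face <- bind_items(r$face_male, r$face_female, "face")
  W <- fit_slim(face, 1, 0.1)
  raw <- permutation_test(W, r$art, B = 199, seed = 3, convention = "raw")
  expect_identical(raw$p_value, 0)
  add1 <- permutation_test(W, r$art, B = 199, seed = 3,
                           convention = "add_one")
  expect_equal(add1$p_value, 1 / 200)
  expect_length(add1$null_distribution, 199)
  expect_identical(raw$null_distribution, add1$null_distribution)
  expect_warning(permutation_test(W, r$art, B = 50, seed = 1), "coarse")
  W0 <- W; W0$values[] <- 0
  expect_error(permutation_test(W0, r$art, B = 200, seed = 1), "degenerate")
})

test_that("permutation null distribution is seed-stable in distribution", {
  syn <- small_cohort(seed = 9, consistency = 0.5)
  gen <- generate_cohort(syn)
  r <- prepare_ratings(gen$ratings)
  W <- fit_slim(r$scene, 1, 0.1)
  n1 <- permutation_test(W, r$art, B = 300, seed = 41)$null_distribution
  n2 <- permutation_test(W, r$art, B = 300, seed = 42)$null_distribution
  se <- sqrt(var(n1) / 300 + var(n2) / 300)
  expect_lt(abs(mean(n1) - mean(n2)), 4 * se)
})
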