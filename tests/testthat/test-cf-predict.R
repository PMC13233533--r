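test_that("neighborhood prediction evaluates the CF formula by hand", {
  # peers with opposite similarities and equal centered ratings cancel out
  ratings <- rm_raw(rbind(c(0, 1, 1), c(0, -1, -1)))   # column means 0
  sim <- sim_from(rbind(c(1, 0.5, -0.5), c(0.5, 1, 0), c(-0.5, 0, 1)))
  pred <- predict_neighborhood(sim, ratings, items = "i01")
  expect_equal(unname(pred$predicted["i01", "P01"]), 0)
  # a single unit-similarity peer copies the peer's centered rating
  r2 <- rm_raw(rbind(c(0, 2), c(0, -2)))
  s2 <- sim_from(rbind(c(1, 1), c(1, 1)))
  p2 <- predict_neighborhood(s2, r2, items = "i01")
  expect_equal(unname(p2$predicted["i01", "P01"]), 2)
  # all-zero similarities fall back to the participant's own mean
  r3 <- rm_raw(rbind(c(3, 1), c(5, -1)))               # rbar_u = 4
  s3 <- sim_from(rbind(c(1, 0), c(0, 1)))
  p3 <- predict_neighborhood(s3, r3, items = "i01")
  expect_equal(unname(p3$predicted["i01", "P01"]), 4)
  expect_gt(p3$fallbacks, 0)
})

test_that("uniform positive similarities reduce to the plain peer average", {
  set.seed(9)
  v <- matrix(rnorm(24), 6, 4)
  v <- sweep(v, 2, colMeans(v))          # centered, so rbar terms drop
  sim <- sim_from(matrix(0.7, 4, 4) + diag(0.3, 4))
  pred <- predict_neighborhood(sim, rm_raw(v))
  for (u in 1:4)
    expect_equal(unname(pred$predicted[, u]),
                 unname(rowMeans(v[, -u])), tolerance = 1e-12)
})

test_that("the SLIM objective matches its algebraic expansion", {
  a <- c(1, -1)
  A <- cbind(a, a)
  for (w in c(0, 0.3, 1)) for (beta in c(0, 2)) for (lam in c(0, 0.5)) {
    W <- rbind(c(0, w), c(0, 0))
    expect_equal(slim_objective(A, W, beta, lam),
                 1 + (1 - w)^2 + beta / 2 * w^2 + lam * w)
  }
  set.seed(10)
  A2 <- matrix(rnorm(20), 5, 4)
  expect_equal(slim_objective(A2, matrix(0, 4, 4), 1, 1), 0.5 * sum(A2^2))
  W2 <- matrix(runif(16), 4, 4); diag(W2) <- 0
  expect_gte(slim_objective(A2, W2, 0.7, 0.2), 0)
  expect_error(slim_objective(A2, W2, -1, 0), "nonnegative")
})

test_that("SLIM fit recovers the duplicated-column closed form", {
  a <- c(1, -1)
  A <- cbind(a, a)
  for (beta in c(0, 0.5, 3)) for (lam in c(0, 0.5, 1.9)) {
    W <- fit_slim(A, beta, lam)
    expect_equal(W$values[2, 1], (2 - lam) / (2 + beta), tolerance = 1e-6)
    expect_equal(W$values[1, 2], (2 - lam) / (2 + beta), tolerance = 1e-6)
  }
  expect_equal(fit_slim(A, 0, 2)$values[2, 1], 0)   # lasso hits the boundary
  expect_equal(max(fit_slim(A, 0, 1e12)$values), 0) # l1 domination
})

test_that("SLIM fit matches nonnegative least squares in the 2-column limit", {
  set.seed(12)
  for (rep in 1:5) {
    A <- matrix(rnorm(16), 8, 2)
    W <- fit_slim(A, 0, 0)
    w12 <- max(0, sum(A[, 1] * A[, 2]) / sum(A[, 1]^2))
    w21 <- max(0, sum(A[, 1] * A[, 2]) / sum(A[, 2]^2))
    expect_equal(W$values[1, 2], w12, tolerance = 1e-6)
    expect_equal(W$values[2, 1], w21, tolerance = 1e-6)
  }
})

test_that("fitted weights always satisfy the SLIM constraints", {
  set.seed(13)
  for (rep in 1:10) {
    inst <- random_slim_instance(rep + 100)
    W <- fit_slim(inst$A, sample(c(0, 0.1, 1, 10), 1),
                  sample(c(0, 0.1, 1, 10), 1))
    expect_gte(min(W$values), 0)
    expect_identical(max(abs(diag(W$values))), 0)
  }
})

test_that("the l1 norm of the fit is non-increasing in lambda", {
  set.seed(14)
  A <- matrix(rnorm(10 * 5), 10, 5)
  for (beta in c(0.1, 10)) {
    norms <- vapply(10^seq(-3, 2), function(lam)
      sum(fit_slim(A, beta, lam)$values), numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("SLIM predictions aggregate peers through the weight columns", {
  set.seed(15)
  v <- matrix(rnorm(15), 5, 3)
  rm <- rm_raw(v)
  # single unit weight copies the designated peer
  W <- weights_from(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  pred <- predict_slim(W, rm)
  expect_equal(pred$predicted[, "P01"], v[, 2], ignore_attr = TRUE)
  # equal weights summing to one average the peers
  W2 <- weights_from(rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.5, 0, 0)))
  expect_equal(predict_slim(W2, rm)$predicted[, "P01"],
               rowMeans(v[, 2:3]), ignore_attr = TRUE)
})

test_that("fit + predict reproduces a duplicated column on held-out items", {
  set.seed(16)
  base <- rnorm(12)
  other <- rnorm(12)
  A <- cbind(base, base, other)
  colnames(A) <- c("P01", "P02", "P03")
  train <- A[1:8, ]
  W <- fit_slim(train, 0, 0)
  full <- rm_raw(A)
  pred <- predict_slim(W, full, items = sprintf("i%02d", 9:12))
  expect_equal(unname(pred$predicted[, "P01"]), base[9:12], tolerance = 1e-6)
})

test_that("grid search selects and refits; tiny penalties win a perfect fit", {
  set.seed(17)
  A <- rm_raw(matrix(rnorm(20 * 4), 20, 4))
  gs1 <- grid_search(A, beta_grid = 2, lam_grid = 0.5, repeats = 2, seed = 1)
  expect_identical(nrow(gs1$score_table), 1L)
  expect_equal(c(gs1$best_beta, gs1$best_lam), c(2, 0.5))
  expect_s3_class(gs1$weights, "slim_weights")
  # duplicated-column cohort with no noise: regularization can only hurt
  lams <- vapply(1:5, function(s) {
    set.seed(s + 40)
    b <- matrix(rnorm(24 * 2), 24, 2)
    Adup <- rm_raw(cbind(b, b))
    grid_search(Adup, beta_grid = 10^c(-4, 0), lam_grid = 10^seq(-3, 2),
                repeats = 3, seed = s)$best_lam
  }, numeric(1))
  expect_true(all(lams <= 0.1))
})

test_that("grid search honors the selection seed deterministically", {
  set.seed(18)
  A <- rm_raw(matrix(rnorm(16 * 4), 16, 4))
  g1 <- grid_search(A, 10^c(-2, 2), 10^c(-3, -1), repeats = 3, seed = 7)
  g2 <- grid_search(A, 10^c(-2, 2), 10^c(-3, -1), repeats = 3, seed = 7)
  expect_identical(g1$score_table, g2$score_table)
  expect_identical(g1$weights$values, g2$weights$values)
})
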