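test_that("pairwise similarity reproduces hand-computed correlations", {
  expect_equal(pairwise_similarity(rm_raw(cbind(1:3, c(2, 4, 6))))$values[2, 1], 1)
  expect_equal(pairwise_similarity(rm_raw(cbind(1:3, 3:1)))$values[2, 1], -1)
  expect_equal(pairwise_similarity(rm_raw(cbind(1:4, c(1, 3, 2, 4))))$values[2, 1],
               0.8)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(2)
  sm <- pairwise_similarity(rm_raw(matrix(rnorm(60), 12, 5)))
  expect_equal(sm$values, t(sm$values), tolerance = 1e-12)
  expect_identical(unname(diag(sm$values)), rep(1, 5))
  expect_true(all(abs(sm$values) <= 1 + 1e-12))
})

test_that("similarity is invariant under per-participant affine rescaling", {
  set.seed(3)
  v <- matrix(rnorm(80), 20, 4)
  a <- pairwise_similarity(rm_raw(v))$values
  v2 <- sweep(sweep(v, 2, c(2, 0.5, 7, 1.3), "*"), 2, c(-3, 10, 0, 2), "+")
  b <- pairwise_similarity(rm_raw(v2))$values
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("pairwise-complete handling and overlap errors", {
  v <- matrix(rnorm(30), 10, 3)
  v[1:8, 2] <- NA   # only 2 shared items with everyone
  expect_error(pairwise_similarity(rm_raw(v)), "share only")
  v2 <- matrix(rnorm(30), 10, 3)
  v2[1:3, 2] <- NA
  sm <- pairwise_similarity(rm_raw(v2))
  expect_equal(sm$values[2, 1], cor(v2[4:10, 1], v2[4:10, 2]))
})

test_that("lower triangle vectorization is row-major and sized n(n-1)/2", {
  m <- matrix(0, 3, 3)
  m[lower.tri(m)] <- c(21, 31, 32)  # column-major fill: (2,1),(3,1),(3,2)
  m <- m + t(m); diag(m) <- 1
  expect_equal(lower_triangle(sim_from(m)), c(21, 31, 32))
  expect_length(lower_triangle(sim_from(diag(37))), 666)
  expect_equal(lower_triangle(sim_from(matrix(c(1, 5, 5, 1), 2))), 5)
})

test_that("inter-domain matrix correlates similarity structures", {
  set.seed(5)
  sm <- pairwise_similarity(rm_raw(matrix(rnorm(200), 20, 10)))
  sms <- list(sm, sm, sm, sm)
  idm <- inter_domain_matrix(sms)
  expect_identical(dim(idm$values), c(4L, 4L))
  expect_true(all(abs(idm$values - 1) < 1e-12))
  sm2 <- sm; sm2$participant_ids <- rev(sm2$participant_ids)
  expect_error(inter_domain_matrix(list(sm, sm2)), "participant sets")
})

test_that("independent domains give near-zero second-order correlation", {
  syn <- synthetic_config(consistency = 0, gender_strength = 0,
                          noise_sd = 0.3, seed = 31)
  gen <- generate_cohort(syn)
  sims <- lapply(prepare_ratings(gen$ratings), pairwise_similarity)
  off <- lower_triangle(inter_domain_matrix(sims))
  # independent similarity structures: each entry ~ 0 within 3/sqrt(666)
  expect_true(all(abs(off) <= 3 / sqrt(666) + 0.02))
})

test_that("full consistency with no noise preserves similarity structure", {
  # 400 items per domain: with fewer items the per-domain similarity
  # estimates themselves carry sampling noise that bounds the second-order
  # correlation away from 1 (80-item domains plateau near 0.92)
  syn <- synthetic_config(consistency = 1, gender_strength = 0,
                          noise_sd = 0, seed = 8,
                          items_per_domain = c(art = 400L, face_male = 400L,
                                               face_female = 400L,
                                               scene = 400L))
  gen <- generate_cohort(syn)
  sims <- lapply(prepare_ratings(gen$ratings), pairwise_similarity)
  off <- lower_triangle(inter_domain_matrix(sims))
  expect_true(all(off >= 0.95))
})

test_that("mean similarity is the plain lower-triangle average", {
  m <- matrix(0, 3, 3)
  m[lower.tri(m)] <- c(0.2, 0.4, 0.6)
  m <- m + t(m); diag(m) <- 1
  expect_equal(mean_similarity(sim_from(m)), 0.4)
  expect_equal(mean_similarity(sim_from(diag(5))), 0)
})

test_that("gender modulation creates within-gender similarity blocks", {
  diffs <- vapply(1:20, function(s) {
    syn <- small_cohort(seed = s, consistency = 0.5, gender_strength = 0.5)
    gen <- generate_cohort(syn)
    sims <- lapply(prepare_ratings(gen$ratings), pairwise_similarity)
    male <- gen$cohort$gender == "male"
    mean(vapply(sims, function(sm) {
      v <- sm$values
      within <- c(v[male, male][lower.tri(v[male, male])],
                  v[!male, !male][lower.tri(v[!male, !male])])
      mean(within) - mean(v[male, !male])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})
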