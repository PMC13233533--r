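test_that("z-score normalization matches the population-SD formula", {
  rm <- rm_raw(cbind(c(1, 2, 3), c(2, 2, 4, 4)[1:3]))
  out <- zscore_normalize(rm_raw(matrix(c(1, 2, 3), 3, 1)))
  expect_equal(as.numeric(out$values),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  out2 <- zscore_normalize(rm_raw(matrix(c(2, 2, 4, 4), 4, 1)))
  expect_equal(as.numeric(out2$values), c(-1, -1, 1, 1))
  expect_identical(out2$scale, "normalized")
})

test_that("normalization rejects degenerate columns and names the culprit", {
  expect_error(zscore_normalize(rm_raw(cbind(c(5, 5, 5), c(1, 2, 3)))), "P01")
  expect_error(zscore_normalize(rm_raw(matrix(c(1, NA, NA), 3, 1))),
               "fewer than 2")
})

test_that("normalization preserves missingness and is idempotent", {
  v <- matrix(rnorm(40), 10, 4)
  v[c(3, 17, 25)] <- NA
  z1 <- zscore_normalize(rm_raw(v))
  expect_identical(which(is.na(z1$values)), which(is.na(v)))
  # idempotence: re-normalizing a normalized matrix changes nothing
  z2 <- zscore_normalize(rating_matrix(z1$values, z1$item_ids,
                                       z1$participant_ids, z1$domain,
                                       scale = "raw_monetary"))
  expect_equal(z1$values, z2$values, tolerance = 1e-9)
})

test_that("preference orientation negates, preserves, and involutes", {
  rm <- rm_raw(matrix(c(1, 2, 3), 3, 1), scale = "raw_rank")
  neg <- orient_preferences(rm, higher_is_better = FALSE)
  expect_equal(as.numeric(neg$values), c(-1, -2, -3))
  expect_equal(orient_preferences(rm, TRUE)$values, rm$values)
  expect_equal(orient_preferences(neg, FALSE)$values, rm$values)
})

test_that("item splits have the right sizes and are deterministic partitions", {
  rm <- rm_raw(matrix(rnorm(400 * 3), 400, 3))
  sp <- split_items(rm, 0.25, seed = 11)
  expect_length(sp$test_items, 100)
  expect_length(sp$train_items, 300)
  expect_identical(sp, split_items(rm, 0.25, seed = 11))
  rm8 <- rm_raw(matrix(rnorm(8 * 2), 8, 2))
  for (s in 1:5) {
    sp8 <- split_items(rm8, 0.25, seed = s)
    expect_setequal(c(sp8$train_items, sp8$test_items), rm8$item_ids)
    expect_length(intersect(sp8$train_items, sp8$test_items), 0)
  }
  expect_error(split_items(rm8, 0.01, seed = 1), "empty")
})

test_that("split frequencies match the split fraction", {
  rm <- rm_raw(matrix(rnorm(20 * 2), 20, 2))
  R <- 400
  hits <- rowSums(vapply(seq_len(R), function(s)
    rm$item_ids %in% split_items(rm, 0.25, seed = s)$test_items,
    logical(20)))
  freq <- hits / R
  se <- sqrt(0.25 * 0.75 / R)
  expect_true(all(abs(freq - 0.25) <= 3 * se))
})

test_that("ratings files round-trip and report malformed input", {
  set.seed(4)
  doms <- list(rm_raw(matrix(rnorm(12), 4, 3), "art"),
               rm_raw(matrix(rnorm(15), 5, 3), "face_male"),
               rm_raw(matrix(rnorm(9), 3, 3), "scene"))
  doms[[2]]$values[2, 1] <- NA
  path <- file.path(tempdir(), "ratings.csv")
  write_ratings(doms, path)
  back <- read_ratings(path)
  expect_length(back, 3)
  expect_identical(names(back), c("art", "face_male", "scene"))
  for (i in 1:3) {
    expect_identical(back[[i]]$item_ids, doms[[i]]$item_ids)
    expect_identical(back[[i]]$participant_ids, doms[[i]]$participant_ids)
    expect_equal(back[[i]]$values, doms[[i]]$values, tolerance = 1e-12)
  }
  # duplicated item id within one domain names the id
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_ratings(path), "i01")
  # non-numeric cell is reported with its location
  writeLines(sub("^art,i02,[^,]*", "art,i02,oops", lines), path)
  expect_error(read_ratings(path), "P01")
})

test_that("cohort files round-trip and validate labels", {
  ch <- cohort(c("P01", "P02", "P03"), c("male", "female", "female"))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(ch, path)
  expect_equal(as.data.frame(read_cohort(path)), as.data.frame(ch))
  expect_error(cohort(c("a", "a"), c("male", "male")), "duplicated")
  expect_error(cohort("a", "unknown_label"), "gender")
})

test_that("rating matrix construction enforces shape and id invariants", {
  expect_error(rating_matrix(matrix(0, 2, 2), item_ids = "only_one"),
               "item ids")
  v <- matrix(rnorm(6), 3, 2)
  expect_error(rating_matrix(v, c("a", "a", "b"), c("p", "q"), "art"),
               "duplicated item")
  # a matrix mislabeled as normalized is rejected
  expect_error(rating_matrix(v + 10, paste0("i", 1:3), c("p", "q"), "art",
                             scale = "normalized"), "normalized")
})

test_that("item and participant subsetting preserve structure", {
  rm <- rm_raw(matrix(rnorm(20), 5, 4))
  sub <- subset_items(rm, c("i02", "i04"))
  expect_identical(sub$item_ids, c("i02", "i04"))
  expect_equal(sub$values, rm$values[c(2, 4), ])
  expect_error(subset_items(rm, "nope"), "unknown item")
  subp <- subset_participants(rm, c("P01", "P03"))
  expect_identical(subp$participant_ids, c("P01", "P03"))
  expect_error(subset_participants(rm, "P99"), "unknown participant")
  b <- bind_items(rm_raw(matrix(rnorm(8), 2, 4), "face_male"),
                  rm_raw(matrix(rnorm(8), 2, 4), "face_female"), "face")
  expect_identical(dim(b$values), c(4L, 4L))
  expect_true(all(grepl("^face_(fe)?male:", b$item_ids)))
})
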