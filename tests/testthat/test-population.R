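test_that("training-set size follows round-half-away-from-zero and bounds", {
  expect_identical(training_set_size(40, 0.4), 16L)
  expect_identical(training_set_size(40, 0.5), 20L)
  expect_identical(training_set_size(10, 0.45), 5L) # 4.5 rounds away from zero
  expect_error(training_set_size(40, 0), "k")
  expect_error(training_set_size(40, 1), "k")
  expect_error(training_set_size(10, 0.01), "outside")
  expect_error(training_set_size(2.5, 0.4), "integer")
})

test_that("every Monte Carlo split partitions the batch at the required size", {
  batch <- simulate_batch(n = 15, blends = NULL, seed = 4)
  pop <- build_population(batch$data, k = 0.4, reps = 60, n_lv = 1, seed = 9)
  expect_identical(pop$x, 6L)
  for (r in seq_len(pop$reps)) {
    tr <- pop$train_sets[[r]]
    expect_length(tr, 6)
    expect_identical(sort(union(tr, which(pop$test_member[r, ]))), 1:15)
    expect_length(intersect(tr, which(pop$test_member[r, ])), 0)
  }
  expect_true(all(pop$records$sacr >= 0))
})

test_that("populations are reproducible and prefix-stable in the repetition count", {
  batch <- simulate_batch(n = 12, blends = NULL, seed = 2)
  p1 <- build_population(batch$data, k = 0.5, reps = 40, n_lv = 1, seed = 31)
  p2 <- build_population(batch$data, k = 0.5, reps = 40, n_lv = 1, seed = 31)
  expect_identical(p1$records$sacr, p2$records$sacr)
  expect_identical(p1$train_sets, p2$train_sets)
  # growing T leaves earlier splits untouched
  p3 <- build_population(batch$data, k = 0.5, reps = 80, n_lv = 1, seed = 31)
  expect_identical(p3$records$sacr[1:40], p1$records$sacr)
  expect_identical(p3$train_sets[1:40], p1$train_sets)
  # a different seed gives a different population
  p4 <- build_population(batch$data, k = 0.5, reps = 40, n_lv = 1, seed = 32)
  expect_false(identical(p4$records$sacr, p1$records$sacr))
})

test_that("identical rows yield an all-zero SACR population", {
  d <- tibble::tibble(sample_id = paste0("s", 1:8),
                      a = rep(3, 8), b = rep(7, 8))
  pop <- build_population(d, k = 0.5, reps = 25, n_lv = 1,
                          scaling = "none", seed = 1)
  expect_equal(pop$records$sacr, rep(0, 25), tolerance = 1e-10)
})

test_that("SACR is invariant to the order of variable columns", {
  batch <- simulate_batch(n = 12, seed = 6)
  pop1 <- build_population(batch$data, k = 0.5, reps = 30, n_lv = 2, seed = 5)
  reordered <- batch$data[, c("sample_id", rev(setdiff(names(batch$data),
                                                       "sample_id")))]
  pop2 <- build_population(reordered, k = 0.5, reps = 30, n_lv = 2, seed = 5)
  expect_equal(pop1$records$sacr, pop2$records$sacr, tolerance = 1e-10)
})

test_that("test-set membership frequency matches the sampling design", {
  batch <- simulate_batch(n = 40, blends = NULL, seed = 8)
  pop <- build_population(batch$data, k = 0.4, reps = 10000, n_lv = 1, seed = 17)
  freq <- colMeans(pop$test_member)
  band <- 3 * sqrt(0.6 * 0.4 / 10000)
  expect_true(all(abs(freq - 0.6) < band))
  # slot conservation over any model subset
  prof <- test_set_probabilities(pop, 1:500)
  expect_equal(sum(prof$probability) * 500, 500 * (40 - 16), tolerance = 1e-9)
})

test_that("sorting is stable, ascending, and top selection takes the high end", {
  pop <- manual_population(
    splits = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
    sacr = c(3, 1, 2, 1), n = 6
  )
  sorted <- sort_population(pop)
  expect_equal(sorted$model, c(2, 4, 3, 1)) # tie 1 vs 1 keeps original order
  expect_equal(sorted$sacr, c(1, 1, 2, 3))
  expect_equal(top_models(pop, 2)$model, c(3, 1))
  expect_equal(top_models(pop, 4)$model, c(2, 4, 3, 1))
  # all-equal SACR: top 2 are the last two by original index
  pop2 <- manual_population(pop$train_sets, rep(5, 4), n = 6)
  expect_equal(top_models(pop2, 2)$model, c(3, 4))
  expect_error(top_models(pop, 0), "n_top")
  expect_error(top_models(pop, 5), "n_top")
})

test_that("probabilities and flagging follow the membership counts strictly", {
  pop <- manual_population(
    splits = list(c(1, 2), c(1, 3), c(1, 4)),
    sacr = c(1, 2, 3), n = 5
  )
  prof <- test_set_probabilities(pop)
  # sample 1 always trains; sample 5 always tests
  expect_equal(prof$probability, c(0, 2/3, 2/3, 2/3, 1))
  expect_identical(flag_samples(prof, 0.8), "S5")
  expect_identical(flag_samples(prof, 2/3), "S5") # strict inequality
  # raising the threshold never adds a flagged sample
  for (tau in c(0.1, 0.5, 0.66, 0.9, 1)) {
    expect_true(all(flag_samples(prof, 0.9) %in% flag_samples(prof, tau) |
                      tau > 0.9))
  }
  expect_error(flag_samples(prof, 0), "threshold")
})

test_that("populations serialize to JSON lines and back faithfully", {
  batch <- simulate_batch(n = 10, seed = 3)
  pop <- build_population(batch$data, k = 0.5, reps = 12, n_lv = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_population(pop, path)
  lines <- readLines(path)
  expect_length(lines, 12)
  rec <- jsonlite::fromJSON(lines[5])
  expect_identical(sort(c(rec$train_idx, rec$test_idx)), 1:10)
  expect_equal(rec$sacr, pop$records$sacr[5], tolerance = 1e-12)
})
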