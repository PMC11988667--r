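# Exhaustive enumeration oracle for the expected number of good models:
# count size-x subsets of 1..n avoiding the first m indices.
enum_good <- function(n, m, x, reps) {
  subsets <- utils::combn(n, x)
  good <- sum(apply(subsets, 2, function(s) !any(s <= m)))
  v <- reps * good / ncol(subsets)
  as.integer(floor(v + 0.5))
}

test_that("theoretical good-model counts match published batch configurations", {
  expect_identical(theoretical_good_models(40, 1, 16, 20000), 12000L)
  expect_identical(theoretical_good_models(40, 4, 16, 20000), 2325L)
  expect_identical(theoretical_good_models(40, 6, 16, 20000), 701L)
  expect_identical(theoretical_good_models(40, 4, 20, 20000), 1060L)
  expect_identical(theoretical_good_models(37, 0, 12, 777), 777L)
  expect_identical(theoretical_good_models(5, 1, 2, 10), 6L)
})

test_that("theoretical counts equal exhaustive enumeration for all small designs", {
  for (n in 2:8) for (x in 1:n) for (m in 0:n) for (reps in c(1, 7, 100)) {
    expect_identical(
      theoretical_good_models(n, m, x, reps),
      enum_good(n, m, x, reps)
    )
  }
})

test_that("good-model curve is monotone and vanishes when x exceeds n - m", {
  curve <- good_model_curve(40, 16, 20000, m_max = 30)
  expect_identical(curve$n_good[1], 20000L)
  expect_true(all(diff(curve$n_good) <= 0))
  expect_identical(curve$n_good[curve$m > 40 - 16], rep(0L, sum(curve$m > 24)))
  # monotone in x too
  n_by_x <- vapply(10:20, function(x) theoretical_good_models(40, 4, x, 20000),
                   integer(1))
  expect_true(all(diff(n_by_x) <= 0))
  expect_error(theoretical_good_models(40, -1, 16, 100), "m")
  expect_error(theoretical_good_models(40, 4, 0, 100), "x")
})

test_that("trial-and-error mechanics follow the count/flag/consistency contract", {
  # 8 samples, train size 2; sample 8 is in every test set of the three
  # top-SACR models, sample 7 in two of the three.
  pop <- manual_population(
    splits = list(c(7, 8), c(1, 8), c(1, 7), c(2, 7), c(2, 3), c(3, 7)),
    sacr = c(0.1, 0.2, 5, 6, 4, 7), n = 8
  )
  hy <- trial_and_error(pop, threshold = 0.8, m_max = 3)
  expect_equal(hy$m, 1:3)
  # N(m) = round(6 * C(8-m,2)/C(8,2))
  expect_equal(hy$n_good, vapply(1:3, function(m) enum_good(8, m, 2, 6),
                                 integer(1)))
  # m=1 keeps the top-5 models {2,5,3,4,6}: samples 4,5,6 are in every test
  # set (probability 1), sample 8 in 4 of 5 (0.8, not flagged: strict rule)
  h1 <- hy[hy$m == 1, ]
  p1 <- h1$probabilities[[1]]
  expect_equal(p1$probability, c(0.6, 0.6, 0.6, 1, 1, 1, 0.4, 0.8))
  expect_identical(h1$flagged[[1]], c("S4", "S5", "S6"))
  expect_false(h1$consistent) # three flags under an m = 1 assumption
  # m=3 keeps the top-2 models {4,6}: sample 7 trains in both (prob 0),
  # samples 1, 4, 5, 6, 8 are in both test sets
  h3 <- hy[hy$m == 3, ]
  p3 <- h3$probabilities[[1]]
  expect_equal(p3$probability[7], 0)
  expect_equal(p3$probability[8], 1)
  expect_identical(h3$flagged[[1]], c("S1", "S4", "S5", "S6", "S8"))
  expect_false(h3$consistent) # five flags under an m = 3 assumption
})

test_that("hypothesis selection takes the largest consistent m and marks ambiguity", {
  hyp <- function(m, flagged) {
    nf <- length(flagged)
    tibble::tibble(m = m, n_good = 10L, flagged = list(flagged),
                   n_flagged = nf, consistent = nf == m,
                   probabilities = list(NULL))
  }
  nested <- dplyr::bind_rows(
    hyp(4, c("a", "b", "c", "d")),
    hyp(5, c("a", "b", "c")),
    hyp(6, c("a", "b", "c", "d", "e", "f"))
  )
  sel <- select_hypothesis(nested)
  expect_identical(sel$final_m, 6L)
  expect_identical(sel$final_flagged, c("a", "b", "c", "d", "e", "f"))
  expect_false(sel$ambiguous)
  none <- dplyr::bind_rows(hyp(2, "a"), hyp(3, character(0)))
  sel0 <- select_hypothesis(none)
  expect_identical(sel0$final_m, 0L)
  expect_identical(sel0$final_flagged, character(0))
  single <- hyp(2, c("a", "b"))
  expect_identical(select_hypothesis(single)$final_m, 2L)
  tangled <- dplyr::bind_rows(hyp(2, c("x", "y")), hyp(3, c("a", "b", "c")))
  expect_true(select_hypothesis(tangled)$ambiguous)
})

test_that("construction-guaranteed good models expose adulterants with probability one", {
  batch <- simulate_batch(n = 20, blends = blend_plan(c(3, 14), "soybean", 0.3),
                          seed = 12)
  pop <- build_population(batch$data, k = 0.4, reps = 800, n_lv = 1, seed = 12)
  planted <- c(3, 14)
  clean <- which(vapply(pop$train_sets,
                        function(tr) !any(tr %in% planted), logical(1)))
  expect_gt(length(clean), 30)
  prof <- test_set_probabilities(pop, clean)
  # by construction: never trained on, always tested
  expect_equal(prof$probability[planted], c(1, 1))
  # an authentic sample's expected probability is 1 - x/(n - m)
  expected_auth <- 1 - pop$x / (20 - 2)
  expect_equal(mean(prof$probability[-planted]), expected_auth,
               tolerance = 0.05)
})

test_that("batch authentication confirms a planted blend across sampling ratios", {
  for (seed in 1:3) {
    batch <- simulate_batch(n = 30, blends = blend_plan(12, "rapeseed", 0.4),
                            seed = seed)
    rep <- authenticate_batch(batch$data, reps = 1000, seed = seed)
    expect_identical(rep$final_m, 1L)
    expect_identical(rep$final_flagged, "S12")
  }
})

test_that("batch authentication reports clean batches as clean and is deterministic", {
  batch <- simulate_batch(n = 30, blends = NULL, seed = 73)
  r1 <- authenticate_batch(batch$data, reps = 1000, seed = 3)
  expect_identical(r1$final_m, 0L)
  expect_identical(r1$final_flagged, character(0))
  r2 <- authenticate_batch(batch$data, reps = 1000, seed = 3)
  expect_identical(glance(r1), glance(r2))
  expect_identical(tidy(r1)$flagged, tidy(r2)$flagged)
  expect_identical(
    r1$per_k[[1]]$hypotheses$probabilities[[4]],
    r2$per_k[[1]]$hypotheses$probabilities[[4]]
  )
})

test_that("detection reports serialize to JSON with the full hypothesis table", {
  batch <- simulate_batch(n = 12, seed = 5)
  rep <- authenticate_batch(batch$data, k = c(0.4, 0.5), reps = 60,
                            m_max = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_named(parsed$per_k, c("k=0.4", "k=0.5"))
  expect_equal(parsed$final_m, rep$final_m)
  expect_length(parsed$per_k[[1]]$hypotheses, 3)
  expect_equal(parsed$config$reps, 60)
  sacr <- export_sacr(rep$per_k[[1]]$population)
  expect_named(sacr, c("rank", "sacr"))
  expect_true(!is.unsorted(sacr$sacr))
})
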