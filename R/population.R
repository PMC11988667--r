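# Monte Carlo model population: repeated random train/test splits of the
# batch, one OCPLS fit per split, each split scored by the sum of test-set
# absolute centered residuals (SACR).

#' Training-set size from a sampling ratio
#'
#' `x = round(n * k)` with ties rounded away from zero, constrained to
#' `1 <= x <= n - 1`.
#'
#' @param n Number of samples in the batch (>= 3).
#' @param k Sampling ratio in (0, 1).
#' @return Integer training-set size.
#' @examples
#' training_set_size(40, 0.4) # 16
#' training_set_size(40, 0.5) # 20
#' @export
training_set_size <- function(n, k) {
  if (n < 3 || n != round(n)) abort("`n` must be an integer >= 3.")
  if (k <= 0 || k >= 1) abort("`k` must lie strictly between 0 and 1.")
  x <- as.integer(floor(n * k + 0.5)) # round half away from zero (n*k > 0)
  if (x < 1 || x > n - 1) {
    abort(paste0("training size x = ", x, " outside [1, n-1] for n = ", n))
  }
  x
}

#' Build a Monte Carlo population of one-class PLS models
#'
#' Repeatedly draws a uniformly random training subset of size
#' `x = round(n * k)` (without replacement), fits a one-class PLS model on
#' it, predicts the held-out samples, and records the sum of their absolute
#' centered residuals (SACR). Splits are sampled independently; each
#' repetition runs under its own seed spawned from `seed`, so enlarging
#' `reps` never alters earlier splits.
#'
#' @param data A composition table (see [as_composition()]).
#' @param k Sampling ratio in (0, 1); default 0.4.
#' @param reps Number of Monte Carlo repetitions T; default 20000.
#' @param n_lv Latent variables per model; default 1. Must be `< x`.
#' @param scaling Column scaling, `"unit_variance"` (default) or `"none"`;
#'   applied per training set (test samples are scaled by the training-set
#'   scale).
#' @param seed Integer master seed; the run is fully reproducible from it.
#' @return An object of class `"model_population"`: a `records` tibble
#'   (`model`, `sacr`) with the train/test index sets, plus batch metadata.
#'   Use [sort_population()], [trial_and_error()], [autoplot()].
#' @examples
#' batch <- simulate_batch(n = 12, seed = 1)
#' pop <- build_population(batch$data, k = 0.5, reps = 50, seed = 1)
#' pop
#' @export
build_population <- function(data, k = 0.4, reps = 20000, n_lv = 1,
                             scaling = c("unit_variance", "none"), seed = 1) {
  scaling <- match.arg(scaling)
  X <- composition_matrix(data)
  n <- nrow(X)
  x_size <- training_set_size(n, k)
  if (reps < 1 || reps != round(reps)) abort("`reps` must be a positive integer.")
  if (x_size <= n_lv) {
    abort(paste0("training size x = ", x_size, " must exceed n_lv = ", n_lv, "."))
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps, replace = TRUE)
  sacr <- numeric(reps)
  train_sets <- vector("list", reps)
  test_member <- matrix(FALSE, nrow = reps, ncol = n)
  prescaled <- scaling == "none" # X fixed across splits; scale once conceptually
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    tr <- sample.int(n, x_size)
    fit <- ocpls_fit_matrix(X[tr, , drop = FALSE], n_lv = n_lv, scaling = scaling)
    Xte <- X[-tr, , drop = FALSE]
    if (!prescaled) Xte <- sweep(Xte, 2, fit$scale, "/")
    acr <- abs((1 - Xte %*% fit$coefficients)[, 1] - fit$e_bar)
    if (any(!is.finite(acr))) {
      abort(paste0("non-finite ACR in Monte Carlo split ", r, "."))
    }
    sacr[r] <- sum(acr)
    train_sets[[r]] <- tr
    test_member[r, -tr] <- TRUE
  }
  structure(
    list(
      records = tibble(model = seq_len(reps), sacr = sacr),
      train_sets = train_sets,
      test_member = test_member,
      sample_ids = rownames(X),
      n = n, x = x_size, k = k, reps = reps,
      n_lv = n_lv, scaling = scaling, seed = seed
    ),
    class = "model_population"
  )
}

#' Sort a model population by SACR
#'
#' Stable ascending sort of the population records by SACR; ties keep the
#' original model order. Good models — those whose training sets contain
#' only authentic samples — are expected at the high-SACR end.
#'
#' @param pop A `"model_population"` from [build_population()].
#' @return A tibble (`rank`, `model`, `sacr`) in ascending SACR order.
#' @export
sort_population <- function(pop) {
  stopifnot(inherits(pop, "model_population"))
  ord <- order(pop$records$sacr) # radix sort: stable, ties by original index
  tibble(rank = seq_along(ord), model = pop$records$model[ord],
         sacr = pop$records$sacr[ord])
}

#' Select the top models by SACR
#'
#' Returns the `n_top` records with the highest SACR (the right-hand end of
#' the ascending sort); among equal SACR values, later original models win,
#' matching the stable-sort tie rule.
#'
#' @param pop A `"model_population"`.
#' @param n_top How many top models to keep, `1 <= n_top <= reps`.
#' @return A tibble (`rank`, `model`, `sacr`), still in ascending order.
#' @export
top_models <- function(pop, n_top) {
  stopifnot(inherits(pop, "model_population"))
  if (n_top < 1 || n_top > pop$reps) {
    abort(paste0("`n_top` must lie in [1, ", pop$reps, "]."))
  }
  sorted <- sort_population(pop)
  sorted[(nrow(sorted) - n_top + 1):nrow(sorted), ]
}

#' Per-sample test-set membership probabilities over a model set
#'
#' For each sample, the fraction of the given models in whose test set it
#' appears. Over good (all-authentic-training) models an adulterated sample
#' appears in every test set, so its probability tends to 1, while an
#' authentic sample's tends to `1 - x / n_authentic`.
#'
#' @param pop A `"model_population"`.
#' @param models Integer vector of model ids (e.g. the `model` column of
#'   [top_models()]); defaults to all models.
#' @return A tibble (`sample_id`, `probability`) in batch row order.
#' @export
test_set_probabilities <- function(pop, models = NULL) {
  stopifnot(inherits(pop, "model_population"))
  models <- models %||% pop$records$model
  if (length(models) == 0) abort("`models` must be non-empty.")
  probs <- colMeans(pop$test_member[models, , drop = FALSE])
  tibble(sample_id = pop$sample_ids, probability = unname(probs))
}

#' Flag samples whose test-set probability exceeds a threshold
#'
#' Strict inequality: a sample is flagged when its probability of sitting
#' in the test sets of the assumed-good models exceeds `threshold`.
#'
#' @param profile A tibble from [test_set_probabilities()] (or a numeric
#'   probability vector named by sample).
#' @param threshold Probability cutoff in (0, 1]; default 0.8.
#' @return Character vector of flagged sample IDs.
#' @export
flag_samples <- function(profile, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must lie in (0, 1].")
  if (is.data.frame(profile)) {
    profile$sample_id[profile$probability > threshold]
  } else {
    names(profile)[profile > threshold]
  }
}

#' Write a model population to JSON lines
#'
#' One record per line — model id, train indices, test indices, SACR — so a
#' population can be audited or re-analysed without refitting.
#'
#' @param pop A `"model_population"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "model_population"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  all_idx <- seq_len(pop$n)
  for (r in seq_len(pop$reps)) {
    tr <- pop$train_sets[[r]]
    line <- jsonlite::toJSON(
      list(model = r, train_idx = sort(tr),
           test_idx = setdiff(all_idx, tr), sacr = pop$records$sacr[r]),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(line, con)
  }
  invisible(path)
}

#' @export
print.model_population <- function(x, ...) {
  cat("Monte Carlo OCPLS model population\n")
  cat("  batch size n:", x$n, " training size x:", x$x,
      " (k =", format(x$k), ")\n")
  cat("  models T:", x$reps, " latent variables:", x$n_lv,
      " scaling:", x$scaling, "\n")
  cat("  SACR range: [", format(min(x$records$sacr), digits = 4), ", ",
      format(max(x$records$sacr), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Tidy a model population
#'
#' @param x A `"model_population"`.
#' @param ... Unused.
#' @return `tidy()`: one row per Monte Carlo model with `sacr` and the
#'   train/test index sets as list columns. `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.model_population <- function(x, ...) {
  all_idx <- seq_len(x$n)
  dplyr::mutate(
    x$records,
    train_idx = lapply(x$train_sets, sort),
    test_idx = lapply(x$train_sets, function(tr) setdiff(all_idx, tr))
  )
}

#' @rdname tidy.model_population
#' @exportS3Method generics::glance
glance.model_population <- function(x, ...) {
  tibble(
    n = x$n, x = x$x, k = x$k, reps = x$reps, n_lv = x$n_lv,
    scaling = x$scaling, seed = x$seed,
    sacr_min = min(x$records$sacr), sacr_median = stats::median(x$records$sacr),
    sacr_max = max(x$records$sacr)
  )
}
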