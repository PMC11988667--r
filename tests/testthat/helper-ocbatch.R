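# Shared fixtures, all generated in code.

# Small deterministic composition table.
tiny_batch <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    x = c(1, 2, 3)
  )
}

# Random strictly positive composition table (not closed), for algebraic
# oracle tests.
rand_comp <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * p, 0.5, 5), n, p)
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- paste0("v", seq_len(p))
  dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(n))), out)
}

# Hand-made model population with fully controlled SACR values and splits,
# for testing the ranking/probability mechanics independently of any fit.
# splits: list of integer train-index vectors (all the same size).
manual_population <- function(splits, sacr, n) {
  reps <- length(splits)
  test_member <- matrix(FALSE, reps, n)
  for (r in seq_len(reps)) test_member[r, -splits[[r]]] <- TRUE
  structure(
    list(
      records = tibble::tibble(model = seq_len(reps), sacr = sacr),
      train_sets = splits,
      test_member = test_member,
      sample_ids = paste0("S", seq_len(n)),
      n = n, x = length(splits[[1]]),
      k = length(splits[[1]]) / n, reps = reps,
      n_lv = 1, scaling = "none", seed = 0
    ),
    class = "model_population"
  )
}
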