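# Synthetic batches: authentic avocado-oil fatty-acid profiles drawn around
# the published overall mean composition, plus adulterated samples formed as
# convex blends with typical commodity-oil profiles.

# Fatty-acid variables used throughout; relative content (%).
FA_VARIABLES <- c("C16:0", "C16:1", "C17:0", "C17:1", "C18:0",
                  "C18:1", "C18:2", "C18:3", "C20:0", "C20:1")

# Overall mean authentic avocado-oil composition (%), pooled across
# production areas; sums to 100.
AVOCADO_MEAN <- c(
  "C16:0" = 12.80, "C16:1" = 3.85, "C17:0" = 0.05, "C17:1" = 0.08,
  "C18:0" = 1.67, "C18:1" = 69.44, "C18:2" = 11.11, "C18:3" = 0.58,
  "C20:0" = 0.22, "C20:1" = 0.20
)

# Typical commodity-oil fatty-acid profiles (%), package constants chosen
# from standard compositional ranges for each species; alpha-linolenic
# (C18:3) levels sit inside the literature ranges 4.2-11% (soybean) and
# 5-14% (rapeseed). C22:1 (erucic) carries the rapeseed marker trait.
ADULTERANT_MEANS <- list(
  soybean = c(
    "C16:0" = 10.5, "C16:1" = 0.10, "C17:0" = 0.10, "C17:1" = 0.05,
    "C18:0" = 4.0, "C18:1" = 23.0, "C18:2" = 54.0, "C18:3" = 7.5,
    "C20:0" = 0.35, "C20:1" = 0.20, "C22:1" = 0.0
  ),
  rapeseed = c(
    "C16:0" = 4.5, "C16:1" = 0.20, "C17:0" = 0.05, "C17:1" = 0.05,
    "C18:0" = 1.8, "C18:1" = 60.5, "C18:2" = 20.0, "C18:3" = 9.5,
    "C20:0" = 0.60, "C20:1" = 1.30, "C22:1" = 0.80
  ),
  corn = c(
    "C16:0" = 11.5, "C16:1" = 0.10, "C17:0" = 0.07, "C17:1" = 0.03,
    "C18:0" = 2.0, "C18:1" = 29.0, "C18:2" = 55.0, "C18:3" = 1.0,
    "C20:0" = 0.45, "C20:1" = 0.35, "C22:1" = 0.0
  )
)

closure <- function(x, total = 100) {
  s <- sum(x)
  if (s <= 0) abort("cannot renormalize a profile with nonpositive sum.")
  x * (total / s)
}

#' Reference fatty-acid profiles
#'
#' `avocado_profile()` returns the pooled mean authentic avocado-oil
#' fatty-acid composition (%); `adulterant_profile()` returns a typical
#' commodity-oil profile restricted to the requested variables and
#' renormalized to `closure_total`. Rapeseed carries a positive erucic-acid
#' (`C22:1`) component, its classical marker trait; request
#' `variables = c(fa_variables(), "C22:1")` to expose it.
#'
#' @param name One of `"soybean"`, `"rapeseed"`, `"corn"`.
#' @param variables Fatty-acid names to keep; default the ten standard
#'   variables of [fa_variables()].
#' @param closure_total Compositional total, default 100 (%).
#' @return A named numeric vector summing to `closure_total`.
#' @examples
#' adulterant_profile("rapeseed", c(fa_variables(), "C22:1"))["C22:1"]
#' @export
adulterant_profile <- function(name = c("soybean", "rapeseed", "corn"),
                               variables = fa_variables(),
                               closure_total = 100) {
  name <- match.arg(name)
  ref <- ADULTERANT_MEANS[[name]]
  missing <- setdiff(variables, names(ref))
  if (length(missing)) {
    ref[missing] <- 0 # variables the commodity oil does not carry
  }
  closure(ref[variables], closure_total)
}

#' @rdname adulterant_profile
#' @export
avocado_profile <- function(variables = fa_variables(), closure_total = 100) {
  prof <- AVOCADO_MEAN
  missing <- setdiff(variables, names(prof))
  if (length(missing)) prof[missing] <- 0
  closure(prof[variables], closure_total)
}

#' @rdname adulterant_profile
#' @export
fa_variables <- function() FA_VARIABLES

#' Blend two compositional profiles
#'
#' Convex combination `(1 - fraction) * profile + fraction * adulterant`,
#' renormalized to the compositional total — the linear-mixing model for an
#' oil adulterated at a given volume fraction.
#'
#' @param profile Named numeric vector (%), the authentic profile.
#' @param adulterant Named numeric vector over the same variables.
#' @param fraction Blend fraction in \[0, 1\].
#' @param closure_total Compositional total, default 100.
#' @return A numeric vector over the same variables, summing to
#'   `closure_total`.
#' @export
blend_profiles <- function(profile, adulterant, fraction, closure_total = 100) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  if (length(profile) != length(adulterant)) {
    abort("`profile` and `adulterant` must cover the same variables.")
  }
  closure((1 - fraction) * profile + fraction * adulterant, closure_total)
}

#' Generate authentic composition profiles
#'
#' Draws each sample independently: per variable a Gaussian with mean
#' `mu_j` and standard deviation `cv * mu_j`, truncated at zero, then
#' renormalized to the compositional total (closure). Emulates a batch of
#' same-origin authentic oils with proportional measurement/biological
#' spread.
#'
#' @param n Number of samples.
#' @param profile Named mean profile; default [avocado_profile()].
#' @param cv Per-variable coefficient of variation; default 0.10.
#' @param seed Integer seed.
#' @param closure_total Compositional total, default 100.
#' @param id_prefix Sample-ID prefix, default `"S"`.
#' @return A composition tibble (`sample_id` + variables).
#' @export
generate_authentic <- function(n, profile = avocado_profile(), cv = 0.10,
                               seed = 1, closure_total = 100,
                               id_prefix = "S") {
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (cv < 0) abort("`cv` must be nonnegative.")
  set.seed(seed)
  p <- length(profile)
  draws <- matrix(rnorm(n * p, mean = rep(profile, each = n),
                        sd = rep(cv * profile, each = n)), nrow = n)
  draws <- pmax(draws, 0)
  draws <- t(apply(draws, 1, closure, total = closure_total))
  colnames(draws) <- names(profile)
  dplyr::bind_cols(
    tibble(sample_id = paste0(id_prefix, seq_len(n))),
    as_tibble(draws)
  )
}

#' Specify which samples to adulterate
#'
#' @param target Integer row indices of the samples to replace by blends.
#' @param adulterant Adulterant name(s), recycled to `length(target)`.
#' @param fraction Blend fraction(s) in (0, 1), recycled likewise.
#' @return A tibble (`target`, `adulterant`, `fraction`).
#' @examples
#' blend_plan(c(2, 3, 8, 23, 32, 33),
#'            c("soybean", "soybean", "soybean", "rapeseed", "corn", "corn"),
#'            0.3)
#' @export
blend_plan <- function(target, adulterant, fraction = 0.3) {
  plan <- tibble(target = as.integer(target),
                 adulterant = rep_len(adulterant, length(target)),
                 fraction = rep_len(fraction, length(target)))
  if (anyDuplicated(plan$target)) abort("duplicate blend target index.")
  if (any(plan$fraction <= 0 | plan$fraction >= 1)) {
    abort("blend fractions must lie strictly between 0 and 1.")
  }
  plan
}

#' Simulate an inspected batch with ground truth
#'
#' Generates `n` authentic profiles, then replaces the rows named in
#' `blends` by convex blends of their own authentic draw with the chosen
#' adulterant profile — a batch in which a minority of market samples are
#' adulterated and the rest authentic. The default blend plan mirrors the
#' study design used throughout the package: 6 of 40 samples adulterated at
#' fraction 0.3 (three with soybean, one with rapeseed, two with corn oil).
#'
#' @param n Batch size; default 40.
#' @param blends A [blend_plan()] tibble, `NULL` for an all-authentic
#'   batch, or `"default"` for the 6-of-40 demonstration plan.
#' @param profile Authentic mean profile; default [avocado_profile()] over
#'   `variables`.
#' @param variables Variables to simulate; include `"C22:1"` to expose the
#'   rapeseed erucic-acid trait.
#' @param cv Coefficient of variation of authentic profiles; default 0.10.
#' @param seed Integer seed.
#' @param closure_total Compositional total, default 100.
#' @return A `"synthetic_batch"`: `$data` (composition tibble), `$labels`
#'   (`sample_id`, `label`, `adulterant`, `fraction`), `$seed`.
#' @examples
#' batch <- simulate_batch(seed = 1)
#' table(batch$labels$label)
#' @export
simulate_batch <- function(n = 40, blends = "default", profile = NULL,
                           variables = fa_variables(), cv = 0.10, seed = 1,
                           closure_total = 100) {
  if (identical(blends, "default")) {
    blends <- blend_plan(
      target = c(2, 3, 8, 23, 32, 33),
      adulterant = c("soybean", "soybean", "soybean", "rapeseed",
                     "corn", "corn"),
      fraction = 0.3
    )
    blends <- blends[blends$target <= n, ]
  }
  profile <- profile %||% avocado_profile(variables, closure_total)
  data <- generate_authentic(n, profile = profile, cv = cv, seed = seed,
                             closure_total = closure_total)
  labels <- tibble(sample_id = data$sample_id, label = "authentic",
                   adulterant = NA_character_, fraction = NA_real_)
  if (!is.null(blends) && nrow(blends) > 0) {
    if (any(blends$target < 1 | blends$target > n)) {
      abort("blend target index outside the batch.")
    }
    vars <- names(profile)
    for (i in seq_len(nrow(blends))) {
      tgt <- blends$target[i]
      adu <- adulterant_profile(blends$adulterant[i], vars, closure_total)
      row <- as.numeric(data[tgt, vars])
      data[tgt, vars] <- as.list(blend_profiles(row, adu, blends$fraction[i],
                                                closure_total))
      labels$label[tgt] <- "adulterated"
      labels$adulterant[tgt] <- blends$adulterant[i]
      labels$fraction[tgt] <- blends$fraction[i]
    }
  }
  structure(list(data = data, labels = labels,
                 blends = blends, seed = seed),
            class = "synthetic_batch")
}

#' @export
print.synthetic_batch <- function(x, ...) {
  n_adu <- sum(x$labels$label == "adulterated")
  cat("Synthetic inspected batch:", nrow(x$data), "samples,",
      ncol(x$data) - 1, "variables;", n_adu, "adulterated\n")
  if (n_adu > 0) {
    adu <- x$labels[x$labels$label == "adulterated", ]
    cat("  ", paste0(adu$sample_id, " (", adu$adulterant, ", f=",
                     format(adu$fraction), ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a synthetic batch to CSV
#'
#' Writes the composition table (same dialect as [read_composition()]) and
#' a labels table (`sample_id`, `label`, `adulterant`, `fraction`).
#'
#' @param batch A `"synthetic_batch"`.
#' @param data_path,labels_path Output CSV paths.
#' @return `batch`, invisibly.
#' @export
write_batch <- function(batch, data_path, labels_path) {
  stopifnot(inherits(batch, "synthetic_batch"))
  write_composition(batch$data, data_path)
  readr::write_csv(batch$labels, labels_path)
  invisible(batch)
}
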