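#' Composition tables
#'
#' A composition table holds one inspected batch: one row per oil sample,
#' a `sample_id` character column first, then one numeric column per
#' chemical variable (fatty acids as relative %, optionally tocopherols in
#' mg/kg or phytosterols in mg/100 g). All user-facing functions in ocbatch
#' take and return this shape.
#'
#' `as_composition()` validates a data frame and returns it as a tibble;
#' `composition_matrix()` extracts the numeric body as a matrix with sample
#' IDs as row names (mostly for internal use).
#'
#' @param data A data frame: `sample_id` column plus numeric variable
#'   columns.
#' @param min_rows Minimum number of samples required (default 2).
#' @return `as_composition()`: a validated tibble. `composition_matrix()`:
#'   a numeric matrix, rows named by sample ID.
#' @examples
#' batch <- tibble::tibble(sample_id = c("a", "b"), C18.1 = c(70, 68),
#'                         C18.2 = c(11, 12))
#' as_composition(batch)
#' @export
as_composition <- function(data, min_rows = 2) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (sample_id column + numeric variables).")
  }
  data <- as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    # tolerate an unnamed first id column
    names(data)[1] <- "sample_id"
  }
  data$sample_id <- as.character(data$sample_id)
  vars <- setdiff(names(data), "sample_id")
  if (length(vars) < 1) abort("composition table needs at least one variable column.")
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  if (nrow(data) < min_rows) {
    abort(paste0("composition table needs at least ", min_rows, " samples."))
  }
  for (v in vars) {
    col <- data[[v]]
    if (!is.numeric(col)) abort(paste0("column '", v, "' is not numeric."))
    if (anyNA(col) || any(!is.finite(col))) {
      abort(paste0("column '", v, "' contains missing or non-finite values."))
    }
    if (any(col < 0)) abort(paste0("column '", v, "' contains negative values."))
  }
  data
}

#' @rdname as_composition
#' @export
composition_matrix <- function(data, min_rows = 2) {
  data <- as_composition(data, min_rows = min_rows)
  vars <- setdiff(names(data), "sample_id")
  x <- as.matrix(data[vars])
  rownames(x) <- data$sample_id
  x
}

#' Read and write composition tables
#'
#' Plain CSV: first column the sample ID, header row of variable names,
#' numeric body, UTF-8, decimal point. `write_composition()` followed by
#' `read_composition()` is the identity on content.
#'
#' @param path Path to a CSV file.
#' @param data A composition table (see [as_composition()]).
#' @return `read_composition()`: a validated composition tibble.
#'   `write_composition()`: `data`, invisibly.
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  as_composition(raw)
}

#' @rdname read_composition
#' @export
write_composition <- function(data, path) {
  data <- as_composition(data, min_rows = 1)
  readr::write_csv(data, path)
  invisible(data)
}

#' Size-weighted pooled mean across groups
#'
#' Pools per-group variable means into one overall mean, weighting each
#' group by its sample count — the way a published composition table's
#' overall "mean" column is formed from per-origin columns.
#'
#' @param group_means A data frame of per-group means: one row per group,
#'   numeric variable columns (any non-numeric columns such as group labels
#'   are carried along but ignored), or a numeric matrix.
#' @param group_sizes Positive integer vector, one per row of `group_means`.
#' @return A named numeric vector: the pooled mean per variable.
#' @examples
#' m <- tibble::tibble(area = c("A", "B"), C18.1 = c(73.24, 68.75))
#' weighted_group_mean(m, c(10, 8))
#' @export
weighted_group_mean <- function(group_means, group_sizes) {
  if (is.data.frame(group_means)) {
    group_means <- as.matrix(group_means[vapply(group_means, is.numeric, logical(1))])
  }
  if (!is.matrix(group_means)) group_means <- rbind(group_means)
  if (length(group_sizes) != nrow(group_means)) {
    abort("`group_sizes` must have one entry per group (row of `group_means`).")
  }
  if (any(group_sizes < 1) || any(group_sizes != round(group_sizes))) {
    abort("`group_sizes` must be positive integers.")
  }
  colSums(group_means * group_sizes) / sum(group_sizes)
}

#' Per-group and pooled composition summary
#'
#' Splits a composition table by a grouping column, reports per-group
#' variable means and sizes, and appends the size-weighted pooled mean row.
#'
#' @param data A composition table with one extra (non-numeric) grouping
#'   column.
#' @param group Name of the grouping column (string).
#' @param digits Rounding for display; `NULL` keeps full precision.
#' @return A tibble: one row per group plus a final `"pooled"` row, with
#'   `n` and the per-variable means.
#' @export
summarize_groups <- function(data, group, digits = 2) {
  data <- as_tibble(data)
  if (!group %in% names(data)) abort(paste0("no column '", group, "' in data."))
  vars <- setdiff(names(data), c("sample_id", group))
  vars <- vars[vapply(data[vars], is.numeric, logical(1))]
  if (length(vars) == 0) abort("no numeric variable columns to summarize.")
  grp <- dplyr::group_by(data, .data[[group]])
  means <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(vars), mean),
    .groups = "drop"
  )
  pooled <- weighted_group_mean(means[vars], means$n)
  pooled_row <- tibble(!!group := "pooled", n = sum(means$n), !!!as.list(pooled))
  out <- dplyr::bind_rows(means, pooled_row)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(vars), ~ round(.x, digits)))
  }
  out
}
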