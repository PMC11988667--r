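# Rule-based chemical-marker screen: attributes which cheaper oil was added
# to a flagged sample. Composition anomalies (fatty-acid, sterol, tocopherol
# levels outside the authentic range) are 'suggestive'; species-specific
# markers (brassicasterol, soy isoflavones, oryzanol ferulates) are
# 'confirmatory' and alone set the verdict.

#' Default adulterant-attribution rules
#'
#' The packaged rule set, one row per rule. Thresholds separating
#' "authentic range" from "anomalous" are configurable; the authentic
#' upper bounds for campesterol share (6.09% of total sterols) and total
#' phytosterols (360 mg/100 g) follow published authentic avocado-oil
#' ranges, while the alpha-linolenic (1.0%) and total-tocopherol
#' (1200 mg/kg) ceilings are package defaults above the authentic means.
#'
#' Note: oryzanol ferulates are classically a rice-bran marker; here their
#' presence is used to confirm corn-oil adulteration, the attribution this
#' screen is designed around.
#'
#' @param c18_3_max Authentic ceiling for alpha-linolenic acid (%); 1.0.
#' @param campesterol_max Authentic ceiling for campesterol as % of total
#'   sterols; 6.09.
#' @param sterol_total_max Authentic ceiling for total phytosterols
#'   (mg/100 g); 360.
#' @param tocopherol_total_max Ceiling for total tocopherols (mg/kg) above
#'   which a gamma-dominant profile suggests soybean; 1200.
#' @return A tibble with columns `id`, `adulterant`, `strength`
#'   (`"suggestive"` or `"confirmatory"`), `requires` (list column of
#'   field names), `predicate` (list column of functions), `description`.
#' @export
marker_rules <- function(c18_3_max = 1.0, campesterol_max = 6.09,
                         sterol_total_max = 360, tocopherol_total_max = 1200) {
  rule <- function(id, adulterant, strength, requires, predicate, description) {
    tibble(id = id, adulterant = adulterant, strength = strength,
           requires = list(requires), predicate = list(predicate),
           description = description)
  }
  dplyr::bind_rows(
    rule("c18_3_high", "soybean|rapeseed", "suggestive", "c18_3_pct",
         function(s) s$c18_3_pct > c18_3_max,
         paste0("alpha-linolenic acid above authentic ceiling (",
                c18_3_max, "%)")),
    rule("erucic_present", "rapeseed", "suggestive", "c22_1_pct",
         function(s) s$c22_1_pct > 0,
         "erucic acid (C22:1) detected"),
    rule("brassicasterol", "rapeseed", "confirmatory",
         "brassicasterol_present",
         function(s) isTRUE(as.logical(s$brassicasterol_present)),
         "brassicasterol detected (rapeseed-specific sterol)"),
    rule("campesterol_high", "soybean|corn", "suggestive",
         "campesterol_pct_of_sterols",
         function(s) s$campesterol_pct_of_sterols > campesterol_max,
         paste0("campesterol share of sterols above authentic range (",
                campesterol_max, "%)")),
    rule("sterols_high", "corn|foreign", "suggestive",
         "phytosterol_total_mg_100g",
         function(s) s$phytosterol_total_mg_100g > sterol_total_max,
         paste0("total phytosterols above authentic range (",
                sterol_total_max, " mg/100 g)")),
    rule("tocopherol_high_gamma", "soybean", "suggestive",
         c("tocopherol_total_mg_kg", "gamma_tocopherol_mg_kg"),
         function(s) s$tocopherol_total_mg_kg > tocopherol_total_max &&
           s$gamma_tocopherol_mg_kg > 0.5 * s$tocopherol_total_mg_kg,
         paste0("total tocopherols above ", tocopherol_total_max,
                " mg/kg with gamma-tocopherol dominant")),
    rule("isoflavones", "soybean", "confirmatory",
         c("daidzein_present", "genistein_present"),
         function(s) isTRUE(as.logical(s$daidzein_present)) &&
           isTRUE(as.logical(s$genistein_present)),
         "daidzein and genistein detected (soy isoflavones)"),
    rule("oryzanol", "corn", "confirmatory", "oryzanol_present",
         function(s) isTRUE(as.logical(s$oryzanol_present)),
         "oryzanol ferulates detected")
  )
}

#' Read a marker table from CSV
#'
#' First column the sample ID, named marker columns, booleans coded 0/1.
#' Any marker column may be absent; rules needing it are skipped.
#'
#' @param path CSV path.
#' @return A tibble with `sample_id` first.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                       collapse = ", ")))
  }
  raw
}

#' Screen samples against adulterant-attribution rules
#'
#' Applies each rule to each sample for which all of the rule's required
#' fields are present (non-missing). Confirmatory hits set the sample's
#' adulterant verdict; suggestive hits are reported as supporting evidence
#' but never set a verdict by themselves.
#'
#' @param data A marker table: `sample_id` column plus any of the marker
#'   fields named in `rules` (see [marker_rules()]). Percent fields must
#'   lie in \[0, 100\] and concentrations be nonnegative.
#' @param rules A rules tibble; default [marker_rules()].
#' @return A `"marker_report"`: `$hits` (one row per rule firing:
#'   `sample_id`, `rule_id`, `adulterant`, `strength`, `description`) and
#'   `$verdicts` (`sample_id`, `verdict` — comma-joined confirmed
#'   adulterants, `""` when none).
#' @examples
#' tbl <- tibble::tibble(sample_id = "s23", c22_1_pct = 0.9,
#'                       c18_3_pct = 3.13, brassicasterol_present = 1)
#' screen_markers(tbl)$verdicts
#' @export
screen_markers <- function(data, rules = marker_rules()) {
  data <- as_tibble(data)
  if (!"sample_id" %in% names(data)) names(data)[1] <- "sample_id"
  data$sample_id <- as.character(data$sample_id)
  pct_fields <- intersect(c("c18_3_pct", "c22_1_pct",
                            "campesterol_pct_of_sterols"), names(data))
  for (f in pct_fields) {
    v <- data[[f]]
    if (!is.numeric(v)) abort(paste0("marker field '", f, "' must be numeric."))
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      abort(paste0("marker field '", f, "' outside [0, 100]."))
    }
  }
  conc_fields <- intersect(c("tocopherol_total_mg_kg", "gamma_tocopherol_mg_kg",
                             "phytosterol_total_mg_100g"), names(data))
  for (f in conc_fields) {
    v <- data[[f]]
    if (!is.numeric(v)) abort(paste0("marker field '", f, "' must be numeric."))
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("marker field '", f, "' must be nonnegative."))
    }
  }
  hits <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    s <- data[i, ]
    purrr::map_dfr(seq_len(nrow(rules)), function(j) {
      req <- rules$requires[[j]]
      if (!all(req %in% names(s))) return(NULL)
      if (any(vapply(req, function(f) is.na(s[[f]]), logical(1)))) return(NULL)
      fired <- isTRUE(rules$predicate[[j]](s))
      if (!fired) return(NULL)
      tibble(sample_id = s$sample_id, rule_id = rules$id[j],
             adulterant = rules$adulterant[j], strength = rules$strength[j],
             description = rules$description[j])
    })
  })
  if (nrow(hits) == 0) {
    hits <- tibble(sample_id = character(), rule_id = character(),
                   adulterant = character(), strength = character(),
                   description = character())
  }
  verdicts <- tibble(sample_id = data$sample_id, verdict = "")
  conf <- hits[hits$strength == "confirmatory", ]
  if (nrow(conf) > 0) {
    by_sample <- dplyr::summarise(
      dplyr::group_by(conf, .data$sample_id),
      verdict = paste(sort(unique(.data$adulterant)), collapse = ","),
      .groups = "drop"
    )
    idx <- match(by_sample$sample_id, verdicts$sample_id)
    verdicts$verdict[idx] <- by_sample$verdict
  }
  structure(list(hits = hits, verdicts = verdicts, rules = rules),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Chemical-marker attribution report\n")
  cat("  samples screened:", nrow(x$verdicts), "\n")
  hit_n <- nrow(x$hits)
  cat("  rule hits:", hit_n, "\n")
  with_verdict <- x$verdicts[x$verdicts$verdict != "", ]
  if (nrow(with_verdict) == 0) {
    cat("  no confirmed adulterant\n")
  } else {
    for (i in seq_len(nrow(with_verdict))) {
      cat("  ", with_verdict$sample_id[i], "->", with_verdict$verdict[i], "\n")
    }
  }
  invisible(x)
}

#' Tidy a marker report
#'
#' @param x A `"marker_report"`.
#' @param ... Unused.
#' @return `tidy()`: the hits table. `glance()`: one-row counts.
#' @exportS3Method generics::tidy
tidy.marker_report <- function(x, ...) x$hits

#' @rdname tidy.marker_report
#' @exportS3Method generics::glance
glance.marker_report <- function(x, ...) {
  tibble(
    n_samples = nrow(x$verdicts),
    n_hits = nrow(x$hits),
    n_confirmed = sum(x$verdicts$verdict != "")
  )
}

#' Write a marker report to JSON
#'
#' @param report A `"marker_report"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path) {
  stopifnot(inherits(report, "marker_report"))
  out <- list(
    hits = report$hits,
    verdicts = report$verdicts
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
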