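# ggplot2 views of the main result types.

#' Plot the sorted SACR curve of a model population
#'
#' Ascending bar/step plot of SACR against model rank. In an adulterated
#' batch the curve shows tiers: the right-hand (high-SACR) tier holds the
#' good models whose training sets contain only authentic samples.
#'
#' @param object A `"model_population"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.model_population <- function(object, ...) {
  sorted <- sort_population(object)
  ggplot2::ggplot(sorted, ggplot2::aes(x = .data$rank, y = .data$sacr)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(
      x = "model rank (ascending SACR)",
      y = "SACR (sum of test-set |centered residual|)",
      title = sprintf("Monte Carlo OCPLS population (T = %d, k = %s)",
                      object$reps, format(object$k))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.model_population
#' @export
plot_sacr <- function(object, ...) autoplot.model_population(object, ...)

#' Plot per-sample test-set probabilities of a detection report
#'
#' One panel per assumed adulteration count `m` (and sampling ratio k),
#' showing each sample's probability of sitting in the test sets of the
#' top good models, with the flagging threshold drawn as a horizontal
#' line.
#'
#' @param object A `"detection_report"`.
#' @param m Assumed counts to show; default all that were tried.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_report <- function(object, m = NULL, ...) {
  df <- purrr::map_dfr(object$per_k, function(res) {
    purrr::map_dfr(seq_len(nrow(res$hypotheses)), function(i) {
      h <- res$hypotheses[i, ]
      dplyr::mutate(h$probabilities[[1]], k = res$k, m = h$m)
    })
  })
  if (!is.null(m)) df <- df[df$m %in% m, ]
  df$sample <- factor(df$sample_id, levels = unique(df$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$probability)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = object$config$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$m),
                        cols = ggplot2::vars(.data$k),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample", y = "test-set probability in good models") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' @rdname autoplot.detection_report
#' @export
plot_probabilities <- function(object, m = NULL, ...) {
  autoplot.detection_report(object, m = m, ...)
}

#' Plot a synthetic batch's composition by ground-truth label
#'
#' @param object A `"synthetic_batch"`.
#' @param ... Unused.
#' @return A ggplot: per-variable composition, coloured by label.
#' @exportS3Method ggplot2::autoplot
autoplot.synthetic_batch <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::left_join(object$data, object$labels[c("sample_id", "label")],
                     by = "sample_id"),
    cols = -c("sample_id", "label"),
    names_to = "variable", values_to = "percent"
  )
  long$variable <- factor(long$variable, levels = unique(long$variable))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$percent,
                                     colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, size = 1) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = NULL, y = "relative content (%)") +
    ggplot2::theme_minimal()
}
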