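# ggplot2 views of the main result types; all return a ggplot object

#' Heat-map view of a trained signature
#'
#' Feature x drug tile map of the correlation matrix, optionally restricted
#' to the recurrently significant features (the marker-by-drug view of the
#' top correlates).
#'
#' @param object a `signature_matrix`.
#' @param recurrent_only restrict rows to [recurrent_features()] hits.
#' @param alpha,min_drugs passed to [recurrent_features()] when
#'   `recurrent_only = TRUE`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot signature_matrix
#' @export
autoplot.signature_matrix <- function(object, recurrent_only = FALSE,
                                      alpha = 0.01, min_drugs = 2, ...) {
  df <- tidy(object)
  if (recurrent_only) {
    keep <- recurrent_features(object, alpha = alpha, min_drugs = min_drugs)
    df <- dplyr::filter(df, .data$feature %in% keep)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug, y = .data$feature,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1),
                                  name = "r (sensitivity)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Feature-drug sensitivity correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Heat-map view of prediction scores
#'
#' Drug x sample tile map of correlation scores; blue marks predicted
#' sensitivity, red predicted resistance.
#'
#' @param object a `prediction_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot prediction_matrix
#' @export
autoplot.prediction_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$drug,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1), name = "score") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Predicted relative drug sensitivity (%s)",
                                  object$provenance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Per-drug concordance-index plot
#'
#' Dot plot of per-drug c-indices with the 0.5 chance line and, when a
#' permutation null was run, a shaded mean +/- 2 SD chance band.
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$evaluable)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$c_index,
                                        y = stats::reorder(.data$drug,
                                                           .data$c_index)))
  if (!is.null(object$null)) {
    g <- g + ggplot2::annotate("rect",
                               xmin = object$null$null_mean - 2 * object$null$null_sd,
                               xmax = object$null$null_mean + 2 * object$null$null_sd,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  g +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concordance index", y = NULL,
                  title = sprintf("Per-drug prediction accuracy (aggregate %.3f)",
                                  object$aggregate_c)) +
    ggplot2::theme_minimal()
}
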