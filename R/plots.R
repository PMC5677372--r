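#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weight solution
#'
#' Feature weights as a stem plot, active features highlighted.
#'
#' @param object A [solve_weights()] result.
#' @param ... Unused.
#' @method autoplot weight_solution
#' @export
autoplot.weight_solution <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$weight,
                                   colour = .data$active)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "feature weight",
      title = sprintf("IMIM weights (lambda = %.3g, beta = %.3g)",
                      object$lam, object$objective)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a lambda selection curve
#'
#' Mean cross-validated accuracy and mean active-feature count along the
#' candidate grid, with the selected lambda marked.
#'
#' @param object A [select_lambda()] result.
#' @param ... Unused.
#' @method autoplot lambda_selection
#' @export
autoplot.lambda_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("accuracy", "n_active"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression(lambda), y = NULL,
                  title = "lambda selection (inner leave-one-subject-out)") +
    ggplot2::theme_minimal()
}

#' Plot per-subject cross-validation accuracies
#'
#' @param object A [lopo_cv()] result.
#' @param ... Unused.
#' @method autoplot lopo_cv
#' @export
autoplot.lopo_cv <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$subject_id, y = .data$accuracy,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "held-out subject", y = "accuracy",
                  title = "leave-one-proband-out accuracy") +
    ggplot2::theme_minimal()
}
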