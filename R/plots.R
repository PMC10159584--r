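# ggplot2 graphics: contrast scatterplots with through-origin fits.

#' Scatterplot of contrasts with the through-origin regression line
#'
#' The classic comparative-methods figure: standardized independent
#' contrasts of a response against those of a predictor, with the
#' no-intercept least-squares line. Pairs are positivized on the x axis
#' (joint sign flips, under which the fit is invariant).
#'
#' @param dataset A `species_dataset`.
#' @param x_var,y_var Log-variable names (see [dataset_log_vars()]).
#' @return A ggplot.
#' @export
plot_contrasts <- function(dataset, x_var = "log_range_km2",
                           y_var = "log_pi_s") {
  cp <- contrast_pair(dataset, x_var, y_var)
  fit <- origin_regression(cp$y, cp$x, y_name = y_var)
  flip <- ifelse(cp$x$contrast < 0, -1, 1)
  df <- tibble(x = flip * cp$x$contrast, y = flip * cp$y$contrast)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = fit$slopes[1],
                         colour = "firebrick") +
    ggplot2::labs(
      x = paste("contrasts in", x_var),
      y = paste("contrasts in", y_var),
      subtitle = sprintf("through-origin slope %.3f (SE %.3f), n = %d",
                         fit$slopes[1], fit$slope_se[1], fit$n)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' Contrast scatterplots of both diversity responses against log range,
#' faceted, mirroring the headline figure of this kind of analysis.
#'
#' @param object A `study_report`.
#' @param predictor Predictor log-variable.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, predictor = "log_range_km2",
                                  ...) {
  ds <- object$dataset
  build <- function(resp) {
    cp <- contrast_pair(ds, predictor, resp)
    fit <- origin_regression(cp$y, cp$x, y_name = resp)
    flip <- ifelse(cp$x$contrast < 0, -1, 1)
    tibble(
      response = resp, x = flip * cp$x$contrast,
      y = flip * cp$y$contrast, slope = fit$slopes[1]
    )
  }
  df <- purrr::map_dfr(c("log_pi_s", "log_ratio"), build)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(
      data = distinct(df, .data$response, .data$slope),
      ggplot2::aes(intercept = 0, slope = .data$slope),
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = paste("contrasts in", predictor),
                  y = "contrasts in response") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
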