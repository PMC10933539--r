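#' @export
autoplot.allom_fit <- function(object, ...) {
  aug <- augment(object)
  grid <- tibble::tibble(x = seq(min(aug$x), max(aug$x), length.out = 200))
  grid$fitted <- object$a * grid$x^object$b
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$x, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = object$predictor_label, y = "AGB (Mg)",
                  title = sprintf("AGB = %.3g x^%.3g  (r² = %.3f, RMSE = %.2f Mg)",
                                  object$a, object$b, object$r2, object$rmse)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.allom_bootstrap <- function(object, band = c("minmax", "percentile"), ...) {
  band <- match.arg(band)
  env <- object$envelope
  lo <- if (band == "minmax") env$ymin else env$q025
  hi <- if (band == "minmax") env$ymax else env$q975
  env$lo <- lo; env$hi <- hi
  obs <- tibble::tibble(x = object$fit$x, y = object$fit$y)
  ggplot2::ggplot(env, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y), alpha = 0.7) +
    ggplot2::labs(x = object$fit$predictor_label, y = "AGB (Mg)",
                  title = sprintf("parametric bootstrap (%d refits)", object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Box plots of per-tree annual rates by site and cohort
#'
#' @param rates Output of [growth_rates()].
#' @param cohorts Optional cohort rule, see [site_summary()].
#' @return A ggplot object faceted by rate metric.
#' @export
plot_site_rates <- function(rates, cohorts = NULL) {
  long <- rates_long(rates, cohorts = cohorts)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$rate,
                                     fill = .data$cohort)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "annual rate") +
    ggplot2::theme_minimal()
}

#' Side profile of a point cloud
#'
#' @param object A [point_cloud()].
#' @param max_points Subsample cap for plotting speed.
#' @param ... Unused.
#' @export
autoplot.point_cloud <- function(object, max_points = 20000L, ...) {
  df <- object
  if (nrow(df) > max_points) df <- df[seq(1, nrow(df), length.out = max_points), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", title = cloud_source(object)) +
    ggplot2::theme_minimal()
}
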