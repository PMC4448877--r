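#' Plot a fitted bulker discharge mixture
#'
#' Scatter of discharge against calculated ballast capacity with each
#' component's regression mean line; points are coloured by their most
#' probable component.
#'
#' @param object A `mixture_discharge` fit.
#' @param x Calculated ballast capacity (m3) of the fitted data.
#' @param y Observed discharge (m3) of the fitted data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_discharge <- function(object, x, y, ...) {
  L <- vapply(seq_len(object$K), function(j) {
    log(object$weights[j]) +
      stats::dnorm(y, object$beta1[j] + object$beta2[j] * x,
                   object$sigma[j], log = TRUE)
  }, numeric(length(y)))
  comp <- factor(max.col(L))
  pts <- tibble::tibble(capacity_m3 = x, discharge_m3 = y,
                        component = comp)
  lines <- tidy.mixture_discharge(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$capacity_m3,
                                    .data$discharge_m3)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$component),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = factor(.data$component))) +
    ggplot2::labs(x = "calculated ballast capacity (m3)",
                  y = "ballast discharge (m3)", colour = "component")
}

#' Plot hindcast discharge over time
#'
#' Annual total hindcast discharge with +/- 2 s.d. predictive error bars.
#'
#' @param by_year An [aggregate_discharge()] table grouped by year.
#' @return A ggplot object.
#' @export
plot_hindcast_by_year <- function(by_year) {
  ggplot2::ggplot(by_year, ggplot2::aes(.data$year,
                                        .data$total_discharge_m3)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$total_discharge_m3 -
                     2 * sqrt(.data$total_variance_m6),
                   ymax = .data$total_discharge_m3 +
                     2 * sqrt(.data$total_variance_m6)),
      width = 0.3) +
    ggplot2::labs(x = "year", y = "hindcast ballast discharge (m3)")
}

#' Plot ecoregion rank trajectories against the decay rate
#'
#' One line per ecoregion showing how its importance rank (1 = greatest
#' propagule pressure) moves as the decay rate lambda varies, faceted by
#' source/arrival side. Nearer sources climb as lambda grows.
#'
#' @param object A [sensitivity_rank()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(.data$lambda, .data$rank,
                               colour = .data$ecoregion)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~side) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(lambda ~ "(per day)"),
                  y = "importance rank (1 = most important)")
}
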