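#' Plot cluster mean response curves
#'
#' Mean ordinal response over the assessment grid per cluster, cluster 1
#' (most favorable) first.
#'
#' @param object A [shape_kmeans()] fit.
#' @param trajectories The trajectories the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_kmeans <- function(object, trajectories, ...) {
  curves <- cluster_mean_curves(object, trajectories)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$month, y = .data$mean_value,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = assessment_months()) +
    ggplot2::labs(x = "Months since index date",
                  y = "Mean response (0 = nonresponse, 3 = remission)",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the probability of not yet having achieved a complete
#' response, with the Greenwood 95% band.
#'
#' @param object A [km_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, lower = 1, upper = 1),
    tibble::as_tibble(object)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since index date",
                  y = "Proportion without complete response") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios
#'
#' Point-and-interval display of the odds ratios from one or more
#' predictor models, with the no-effect line at OR = 1; the x axis is
#' logarithmic.
#'
#' @param table A [forest_table()] tibble.
#' @return A ggplot object.
#' @export
plot_forest <- function(table) {
  table <- dplyr::mutate(table,
                         term = factor(.data$term, levels = rev(unique(.data$term))))
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot medication-score trajectories by cluster
#'
#' Mean medication score at each assessment month within each cluster.
#'
#' @param scores Long tibble from [score_series()].
#' @param assignments Tibble `patient_id`, `cluster`.
#' @return A ggplot object.
#' @export
plot_score_curves <- function(scores, assignments) {
  d <- dplyr::inner_join(scores, assignments, by = "patient_id") |>
    dplyr::group_by(.data$cluster, .data$month) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$month, y = .data$mean_score,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = assessment_months()) +
    ggplot2::labs(x = "Months since index date", y = "Mean medication score",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}
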