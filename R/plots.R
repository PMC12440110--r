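#' Plot a posterior predictive check
#'
#' Observed correct-choice curves by trial type with the posterior
#' predictive band.
#'
#' @param object A `ppc_result` from [posterior_predictive()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppc_result <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$position, y = .data$observed)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$predicted),
      color = "steelblue"
    ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trial_type) +
    ggplot2::labs(
      x = "trial within type", y = "correct-choice rate",
      title = "Posterior predictive check"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery report
#'
#' True versus estimated subject-level parameters with credible intervals
#' and the identity line.
#'
#' @param object A `recovery_report` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$truth, y = .data$estimate)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2, linewidth = 0.3
    ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(
      x = "true value", y = "posterior mean",
      title = "Parameter recovery"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a directed influence graph
#'
#' Nodes on a circle with the hub centered; significant directed edges
#' drawn as arrows, colored by the sign of the regression estimate.
#'
#' @param object An `influence_graph` from [edge_graph()].
#' @param hub Hub label (default `"VTA"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.influence_graph <- function(object, hub = "VTA", ...) {
  nodes <- attr(object, "nodes")
  others <- setdiff(nodes, hub)
  angle <- seq(0, 2 * pi, length.out = length(others) + 1L)[-1]
  pos <- tibble::tibble(
    node = c(hub, others),
    x = c(0, cos(angle)),
    y = c(0, sin(angle))
  )
  edges <- tibble::as_tibble(object) |>
    dplyr::filter(.data$edge) |>
    dplyr::left_join(pos, by = c(from = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(to = "node")) |>
    dplyr::mutate(direction = ifelse(.data$estimate > 0, "positive", "negative"))
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
        color = .data$direction
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      linewidth = 0.7
    )
  }
  p +
    ggplot2::geom_point(
      data = pos, ggplot2::aes(x = .data$x, y = .data$y),
      size = 10, color = "grey85"
    ) +
    ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = paste0(
        "Directed influence (predictor: ",
        attr(object, "predictor"), ")"
      )
    )
}

#' Plot influence degrees by group
#'
#' @param degrees Long degrees tibble from [depna()].
#' @param cohort Cohort tibble with `subject_id` and `group`.
#' @param node Node to display (default `"VTA"`).
#' @return A ggplot.
#' @export
plot_degrees <- function(degrees, cohort, node = "VTA") {
  df <- degrees |>
    dplyr::filter(.data$node == !!node) |>
    dplyr::inner_join(cohort[, c("subject_id", "group")], by = "subject_id") |>
    tidyr::pivot_longer(c("influencing", "influenced"),
      names_to = "direction", values_to = "degree"
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$group, y = .data$degree, fill = .data$group)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(
      x = NULL, y = paste(node, "degree"),
      title = paste(node, "network influence by group")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
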