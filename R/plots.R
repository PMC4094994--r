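# ggplot2 displays for generation results and sweeps.

#' @describeIn generate_modular_graph Plot a generated graph as its
#'   module-ordered adjacency pattern: nodes are sorted by module and each
#'   edge drawn as a point, so the planted block structure appears as dense
#'   diagonal blocks whose contrast grows with Q.
#' @param object A `modular_graph` object (for `autoplot`).
#' @export
autoplot.modular_graph <- function(object, ...) {
  edges <- tidy(object)
  both <- dplyr::bind_rows(
    edges,
    dplyr::rename(edges, from = "to", to = "from", module_from = "module_to", module_to = "module_from")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$from, y = .data$to, colour = .data$class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(within = "#2166ac", between = "#b2182b")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "node (module-ordered)", y = "node (module-ordered)",
      title = sprintf("Planted Q = %.3f (target %.3f)", object$achieved_q, object$target_q),
      colour = "edge class"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn structural_sweep Plot ensemble mean +/- sd of assortativity,
#'   clustering and path length against the target modularity.
#' @param object A `modular_sweep` tibble (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.modular_sweep <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      c("assortativity", "clustering", "path_length"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$target_q, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_q, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "target modularity Q", y = "ensemble mean ± sd") +
    ggplot2::theme_minimal()
}
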