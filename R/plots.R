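#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RMSF profile
#' @param object An `"rmsf_profile"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$residue_number, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "residue",
      y = "backbone RMSF (Å)",
      title = sprintf("RMSF, %s ns windows, %d run(s)",
                      format(attr(object, "window_ns")),
                      attr(object, "n_runs_averaged"))) +
    ggplot2::theme_minimal()
}

#' Plot an RMSF difference curve
#' @param diff Tibble from [rmsf_difference()].
#' @return A ggplot.
#' @export
plot_rmsf_difference <- function(diff) {
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$residue_number,
                                     y = .data$drmsf)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "ΔRMSF (Å)") +
    ggplot2::theme_minimal()
}

network_layout <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  xy <- igraph::layout_with_fr(g)
  tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Plot a coarse-grained binding-mode network
#'
#' Node area is proportional to basin population, edge width to total
#' transition probability; nodes are labelled by their dominant contact
#' pattern with minor patterns in parentheses.
#'
#' @param object A `"coarse_network"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coarse_network <- function(object, ...) {
  nodes <- data.frame(name = object$nodes$basin,
                      fraction = object$nodes$fraction,
                      label = ifelse(
                        nzchar(object$nodes$minor_patterns),
                        sprintf("%s (%s)", object$nodes$label,
                                object$nodes$minor_patterns),
                        object$nodes$label))
  xy <- network_layout(nodes, object$edges[, c("from", "to")])
  nodes <- dplyr::left_join(nodes, xy, by = "name")
  seg <- dplyr::left_join(object$edges, xy, by = c("from" = "name"))
  seg <- dplyr::left_join(seg, xy, by = c("to" = "name"),
                          suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$probability),
      colour = "grey55") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$fraction),
      colour = "steelblue", alpha = 0.85) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1.6, size = 3) +
    ggplot2::scale_size_area(max_size = 18, labels = scales_percent) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "population", linewidth = "transition prob.")
}

scales_percent <- function(x) sprintf("%.0f%%", 100 * x)

#' Plot a helical-propensity profile by residue class
#' @param object A `"propensity_profile"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.propensity_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$mean_propensity,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "position downstream of domain C-terminus",
                  y = "mean helical propensity (weighted)") +
    ggplot2::theme_minimal()
}
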