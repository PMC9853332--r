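#' Plot a discharge series
#'
#' @param object A `discharge_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.discharge_series <- function(object, ...) {
  ggplot(object, aes(x = .data$day, y = .data$q_mm)) +
    geom_line(colour = "steelblue") +
    labs(x = "day", y = "specific discharge (mm/d)") +
    theme_minimal()
}

#' Plot a duration curve
#'
#' @param object A [duration_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.duration_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$exceedance, y = .data$value)) +
    geom_step() +
    labs(x = "fraction of time equalled or exceeded", y = "length (m)") +
    theme_minimal()
}

#' Plot occupancy trajectories of a scenario ensemble
#'
#' Grey spaghetti of individual replicates with the ensemble mean overlaid,
#' one panel per model variant (dynamic vs static).
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_result <- function(object, ...) {
  om <- object$omega
  mean_om <- om |>
    group_by(.data$model, .data$day) |>
    summarise(omega = mean(.data$omega), .groups = "drop")
  ggplot(om, aes(x = .data$day, y = .data$omega, group = .data$replicate)) +
    geom_line(alpha = 0.15, colour = "grey40") +
    geom_line(data = mean_om, aes(group = NULL, colour = .data$model),
              linewidth = 1) +
    facet_wrap(~model) +
    scale_colour_manual(values = c(dynamic = "#2166ac", static = "#b2182b"),
                        guide = "none") +
    labs(x = "day", y = expression(Omega(t))) +
    theme_minimal()
}

#' Map a per-node statistic on the network
#'
#' @param net A [stream_network].
#' @param values A tibble with `node_id` and one value column (e.g.
#'   [local_occupancy()] output), or a numeric vector in node-id order.
#' @param name Legend title.
#' @return A ggplot of node points at their planar coordinates, coloured by
#'   the value, with the tree edges drawn underneath.
#' @export
plot_node_map <- function(net, values, name = "value") {
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "node_id")[1]
    v <- values[[vcol]][match(net$nodes$node_id, values$node_id)]
    if (name == "value") name <- vcol
  } else {
    v <- as.numeric(values)
  }
  nd <- net$nodes |> mutate(value = v)
  seg <- nd |>
    filter(!is.na(.data$downstream_id)) |>
    mutate(xend = nd$x[.data$downstream_id + 1L],
           yend = nd$y[.data$downstream_id + 1L])
  ggplot(nd) +
    geom_segment(data = seg, aes(x = .data$x, y = .data$y,
                                 xend = .data$xend, yend = .data$yend),
                 colour = "grey70") +
    geom_point(aes(x = .data$x, y = .data$y, colour = .data$value), size = 2) +
    scale_colour_viridis_c(name = name) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)") +
    theme_minimal()
}

#' Plot a survival sensitivity map
#'
#' Tile map of survival probability over the colonization/extinction grid,
#' dynamic and static variants side by side.
#'
#' @param sens A [sensitivity_analysis()] result.
#' @return A ggplot.
#' @export
plot_sensitivity <- function(sens) {
  long <- sens |>
    tidyr::pivot_longer(c("survival_dynamic", "survival_static"),
                        names_to = "model", names_prefix = "survival_",
                        values_to = "survival")
  ggplot(long, aes(x = log10(.data$c), y = log10(.data$e),
                   fill = .data$survival)) +
    geom_tile() +
    facet_wrap(~model) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = expression(log[10] ~ c ~ (m^-2 ~ d^-1)),
         y = expression(log[10] ~ e ~ (m^2 ~ d^-1))) +
    theme_minimal()
}
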