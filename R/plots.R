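#' Plot the efficiency-cost optimization curve
#'
#' Quality function J and its two efficiency components against network
#' density, with the selected density marked.
#'
#' @param object An `eco_curve` from [eco_select_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.eco_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("J", "E_g", "E_l"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$density, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_density, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "network density ρ", y = NULL,
                  colour = NULL,
                  title = "Efficiency-cost optimization",
                  subtitle = sprintf("selected density %.3f (%d edges)",
                                     object$best_density,
                                     object$best_graph$n_edges)) +
    ggplot2::theme_minimal()
}

#' Node-role plane
#'
#' Scatter of participation coefficient against within-module degree
#' z-score, coloured by role, with the classification boundaries drawn.
#'
#' @param roles Output of [node_roles()].
#' @param z_hub,p_hub_connector,p_nonhub_connector Thresholds used when
#'   the roles were assigned (drawn as boundaries).
#' @param label_hubs Label nodes with `z >= z_hub`.
#' @return A ggplot object.
#' @export
plot_node_roles <- function(roles, z_hub = 2.5, p_hub_connector = 0.30,
                            p_nonhub_connector = 0.62, label_hubs = TRUE) {
  p <- ggplot2::ggplot(roles, ggplot2::aes(x = .data$participation,
                                           y = .data$z,
                                           colour = .data$role)) +
    ggplot2::geom_hline(yintercept = z_hub, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = p_nonhub_connector, linetype = 3,
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "participation coefficient P",
                  y = "within-module degree z-score", colour = NULL) +
    ggplot2::theme_minimal()
  if (label_hubs && any(roles$z >= z_hub)) {
    p <- p + ggplot2::geom_text(
      data = roles[roles$z >= z_hub, ],
      ggplot2::aes(label = .data$region), vjust = -0.8, size = 3,
      show.legend = FALSE)
  }
  p
}

#' Top regions by centrality
#'
#' Bar chart of degree and eigenvector centrality for the top-`k` regions
#' (ranked by degree), highlighting regions in the top `k` of both.
#'
#' @param cent Output of [centralities()].
#' @param top_n Number of regions shown (default 15).
#' @return A ggplot object.
#' @export
plot_centralities <- function(cent, top_n = 15) {
  top_deg <- head(cent[order(-cent$degree), ], top_n)
  top_ev <- head(cent[order(-cent$eigenvector), ], top_n)
  both <- intersect(top_deg$region, top_ev$region)
  long <- dplyr::bind_rows(
    dplyr::mutate(top_deg, measure = "degree", value = .data$degree),
    dplyr::mutate(top_ev, measure = "eigenvector", value = .data$eigenvector)
  )
  long$in_both <- long$region %in% both
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$region, .data$value),
                               y = .data$value, fill = .data$in_both)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey35", `FALSE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Top %d regions by centrality", top_n),
                  subtitle = "grey: top ranks in both measures") +
    ggplot2::theme_minimal()
}

#' Time-course plot of a per-subject summary
#'
#' Group means with standard-error bars, groups in design order.
#'
#' @param data Per-subject tibble (e.g. from [whole_brain_density()]).
#' @param value Column to summarise (default `"density"`).
#' @param group_order Group display order; defaults to order of
#'   appearance.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(data, value = "density", group_order = NULL) {
  data <- as_tibble(data)
  if (is.null(group_order)) group_order <- unique(data$group)
  data$group <- factor(data$group, levels = group_order)
  summ <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data[[value]]),
                     sem = sd(.data[[value]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
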