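#' Plot a degree distribution on log-log axes
#'
#' Observed p(k) as points on log10 axes; when a power-law fit is supplied
#' (or `fit = TRUE`), the fitted line `p(k) = c k^-r` is overlaid.
#'
#' @param edges Edge tibble, igraph, or a degree-distribution tibble.
#' @param fit `TRUE` to fit and overlay a power law, or a `powerlaw_fit`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(edges, fit = TRUE) {
  dist <- if (is.data.frame(edges) && all(c("degree", "p") %in% names(edges))) {
    edges
  } else {
    degree_distribution(edges)
  }
  dist <- dist[dist$degree >= 1 & dist$p > 0, ]
  gg <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$degree, y = .data$p)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "p(k)") +
    ggplot2::theme_minimal()
  pl <- if (isTRUE(fit)) fit_power_law(dist) else fit
  if (inherits(pl, "powerlaw_fit")) {
    line <- tibble(
      degree = dist$degree,
      p = pl$prefactor * dist$degree^(-pl$exponent)
    )
    gg <- gg +
      ggplot2::geom_line(
        data = line, color = "firebrick", linewidth = 0.4
      ) +
      ggplot2::labs(subtitle = sprintf(
        "p(k) = c k^-r: r = %.2f, R² = %.3f", pl$exponent, pl$r_squared
      ))
  }
  gg
}

#' @rdname fit_power_law
#' @param object A `powerlaw_fit` object.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  plot_degree_distribution(object$distribution, fit = object)
}

#' @rdname efficiency_zscore
#' @param object An `efficiency_zscore` object.
#' @export
autoplot.efficiency_zscore <- function(object, ...) {
  nulls <- tibble(efficiency = object$null_efficiencies)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$efficiency)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(
      xintercept = object$observed, color = "firebrick",
      linetype = "dashed", linewidth = 0.7
    ) +
    ggplot2::labs(
      x = "global efficiency of null samples",
      y = "count",
      subtitle = sprintf(
        "observed %.3f, z = %s, empirical p = %.3g",
        object$observed,
        ifelse(is.na(object$z), "NA", sprintf("%.2f", object$z)),
        object$p_empirical
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the InteroScore distribution
#'
#' Histogram of InteroScores, faceted by origin (known vs predicted), with
#' the high-confidence cutoff marked.
#'
#' @param scored Scored interactions ([score_interactions()]).
#' @param cutoff Cutoff line to draw (default 1.5).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scored, cutoff = 1.5) {
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$intero_score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", color = "white") +
    ggplot2::geom_vline(
      xintercept = cutoff, color = "firebrick", linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~origin, scales = "free_y") +
    ggplot2::labs(x = "InteroScore", y = "interactions") +
    ggplot2::theme_minimal()
}

#' Known versus predicted degree per node
#'
#' Scatter plot of each node's number of known interactions against its
#' number of predicted interactions; under interolog prediction, heavily
#' studied hubs tend to gain proportionally fewer new edges.
#'
#' @param known_edges,predicted_edges Edge tibbles for one species.
#' @return A ggplot object.
#' @export
plot_known_vs_predicted <- function(known_edges, predicted_edges) {
  deg <- function(e, label) {
    g <- as_interaction_graph(e)
    tibble(
      gene = igraph::V(g)$name,
      degree = as.integer(igraph::degree(g)),
      what = label
    )
  }
  both <- dplyr::full_join(
    deg(known_edges, "known")[, c("gene", "degree")] |>
      dplyr::rename(known = "degree"),
    deg(predicted_edges, "predicted")[, c("gene", "degree")] |>
      dplyr::rename(predicted = "degree"),
    by = "gene"
  ) |>
    tidyr::replace_na(list(known = 0L, predicted = 0L))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$known, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "known interactions per node",
      y = "predicted interactions per node"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
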