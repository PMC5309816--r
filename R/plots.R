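#' Plot a similarity profile
#'
#' Smoothed differential score along the *Neolecta* sequence, the grey
#' Monte-Carlo insignificance band, conserved residues highlighted, and
#' regions missing in yeast marked along the axis.
#'
#' @param object A `similarity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_profile
#' @export
autoplot.similarity_profile <- function(object, ...) {
  p <- object$profile
  gg <- ggplot2::ggplot(p, ggplot2::aes(x = .data$neolecta_pos)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$band$q_low, ymax = object$band$q_high,
                      fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), na.rm = TRUE) +
    ggplot2::geom_point(
      data = p[which(p$conserved), ],
      ggplot2::aes(y = .data$smoothed), colour = "red", size = 0.6,
      na.rm = TRUE) +
    ggplot2::labs(x = "Neolecta position",
                  y = "Pezizomycotina-similarity score")
  miss <- p[which(p$missing_in_yeast), ]
  if (nrow(miss) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = miss, ggplot2::aes(y = object$band$q_low), shape = 45,
      colour = "grey40", na.rm = TRUE)
  }
  gg
}

#' Plot divergence-score greyscale
#'
#' One tile per species shaded by divergence from the Pezizomycotina
#' average (lighter = more divergent), mirroring the substitution-rate
#' greyscale panels.
#'
#' @param scores A `divergence_scores` tibble with a `shade` column (see
#'   [greyscale()]).
#' @return A ggplot object.
#' @export
plot_divergence_shades <- function(scores) {
  if (!"shade" %in% names(scores)) scores <- greyscale(scores)
  scores$species <- factor(scores$species,
                           levels = scores$species[order(scores$s)])
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$species, y = 1,
                               fill = .data$shade)) +
    ggplot2::geom_tile(colour = "black") +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "shade")
}

#' Plot a Dollo gain/loss map
#'
#' Gains and losses per node as a diverging bar chart.
#'
#' @param object A `gain_loss_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gain_loss_map
#' @export
autoplot.gain_loss_map <- function(object, ...) {
  nd <- object$nodes[object$nodes$gains > 0 | object$nodes$losses > 0, ]
  long <- tidyr::pivot_longer(nd[, c("label", "gains", "losses")],
                              c("gains", "losses"),
                              names_to = "event", values_to = "count")
  long$count <- ifelse(long$event == "losses", -long$count, long$count)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$count,
                                     fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(gains = "darkgreen",
                                          losses = "black")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "families gained (+) / lost (-)")
}
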