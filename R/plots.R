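#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chain-averaged precision-recall curve
#'
#' @param object A `tm_pr_curve` from [averaged_pr_curve()].
#' @param baseline Optional random-prediction precision (the average contact
#'   prevalence), drawn as a horizontal dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tm_pr_curve <- function(object, baseline = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall (coverage)", y = "Average precision",
      title = sprintf("Chain-averaged precision-recall (AUPRC = %.3f)",
                      attr(object, "auprc"))) +
    ggplot2::theme_minimal()
  if (!is.null(baseline))
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed",
                                 colour = "grey40")
  p
}

#' Plot predicted and observed contacts of one chain
#'
#' Observed contacts are drawn as grey tiles and the top `L/divisor`
#' predictions as points, one panel per helix pair.
#'
#' @param pred A `tm_predictions` tibble.
#' @param observed Optional `tm_contact_map` with the chain's true contacts.
#' @param divisor Ranking depth divisor (default 5).
#' @return A ggplot.
#' @export
plot_contact_map <- function(pred, observed = NULL, divisor = 5) {
  top <- top_k_contacts(pred, divisor)
  top$pair <- sprintf("helices %d-%d", top$helix_a, top$helix_b)
  p <- ggplot2::ggplot()
  if (!is.null(observed) && nrow(observed$contacts) > 0) {
    obs <- observed$contacts
    obs$pair <- sprintf("helices %d-%d", obs$helix_a, obs$helix_b)
    p <- p + ggplot2::geom_tile(
      data = obs, ggplot2::aes(x = .data$seqpos_i, y = .data$seqpos_j),
      fill = "grey75")
  }
  p + ggplot2::geom_point(
    data = top,
    ggplot2::aes(x = .data$seqpos_i, y = .data$seqpos_j,
                 colour = .data$score), size = 2) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Residue in first helix", y = "Residue in second helix",
                  title = sprintf("Top L/%g predicted contacts", divisor)) +
    ggplot2::theme_minimal()
}

#' Plot per-position conservation of a chain
#'
#' @param cons A `tm_conservation` tibble.
#' @return A ggplot of the standardized entropy along TM positions.
#' @export
plot_conservation <- function(cons) {
  ggplot2::ggplot(cons, ggplot2::aes(x = .data$seqpos,
                                     y = .data$standardized)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::facet_grid(~.data$helix_index, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Sequence position", y = "Standardized entropy",
                  title = "Positional conservation over TM helices") +
    ggplot2::theme_minimal()
}
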