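# ggplot2 views of the result types: density trajectories, per-session
# degree/centrality distributions, and activation rasters. Plots are
# descriptive aids; the tables are the analysis surface.

#' Plot network-density trajectories by speaker
#'
#' @param measures A measure table from [measure_table()] (one or more
#'   dyads).
#' @return A ggplot: density against session, one line per dyad x speaker.
#' @export
plot_density_trajectory <- function(measures) {
  dat <- dplyr::filter(tibble::as_tibble(measures),
                       .data$level == "network", !is.na(.data$density))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$session_index, y = .data$density,
    colour = .data$dyad_id, linetype = .data$speaker)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "recording session", y = "network density",
                  colour = "dyad", linetype = "speaker") +
    ggplot2::theme_minimal()
}

#' Plot per-session node-measure distributions
#'
#' Boxplots of node degree or centrality per recording session, faceted by
#' speaker.
#'
#' @param measures A measure table.
#' @param measure `"degree"` or `"centrality"`.
#' @return A ggplot.
#' @export
plot_measure_distribution <- function(measures,
                                      measure = c("degree", "centrality")) {
  measure <- match.arg(measure)
  dat <- dplyr::filter(tibble::as_tibble(measures), .data$level == "node",
                       !is.na(.data[[measure]]))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$session_index), y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.2) +
    ggplot2::facet_grid(ggplot2::vars(.data$speaker),
                        ggplot2::vars(.data$dyad_id), scales = "free_y") +
    ggplot2::scale_x_discrete(breaks = function(b) b[seq(1, length(b), 5)]) +
    ggplot2::labs(x = "recording session", y = paste("node", measure)) +
    ggplot2::theme_minimal()
}

#' Plot a node-activation raster
#'
#' One row per node, filled where the node is active in the session — the
#' visual signature of punctuated (child) vs continuous (parent) usage.
#'
#' @param activation An `activation_table` from [activation_timeline()].
#' @param class Optional node class filter (`"root"` or `"pattern"`).
#' @return A ggplot.
#' @export
plot_activation_raster <- function(activation, class = NULL) {
  stopifnot(inherits(activation, "activation_table"))
  dat <- activation$activity
  if (!is.null(class)) dat <- dplyr::filter(dat, .data$class == !!class)
  dat <- dplyr::filter(dat, .data$active)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$session_index,
    y = stats::reorder(.data$node, .data$session_index, FUN = min))) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(
      x = "recording session", y = NULL,
      title = sprintf("%s / %s node activation", activation$dyad_id,
                      activation$speaker)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot an effect ledger as a coefficient dot plot
#'
#' @param ledger An [effect_summary()] tibble.
#' @return A ggplot of estimates by predictor, faceted by response, with
#'   significant effects filled.
#' @export
plot_effect_ledger <- function(ledger) {
  ggplot2::ggplot(tibble::as_tibble(ledger), ggplot2::aes(
    x = .data$estimate, y = .data$term, shape = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$response)) +
    ggplot2::labs(x = "standardized estimate", y = NULL,
                  shape = "p < 0.05") +
    ggplot2::theme_minimal()
}
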