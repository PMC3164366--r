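#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-rank overlap plot of a list comparison
#'
#' The diagnostic scatter of the marching algorithm: the fraction of genes
#' in common between the two lists (`k/m`) against the fraction of genes
#' selected in each list (`m/N`), with statistically significant steps in
#' red and chance-level steps in blue. Unrelated lists track the identity
#' expectation `k/m ~ m/N`; strongly related lists rise far above it.
#' Call the comparison with `trace_full = TRUE` to draw the whole rank
#' range beyond the stopping point.
#'
#' @param object A `list_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.list_comparison <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$m_frac, y = .data$k_frac)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "blue"),
      labels = c(`TRUE` = "significant", `FALSE` = "chance"),
      name = NULL
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "fraction of genes selected (m/N)",
      y = "fraction of genes in common (k/m)",
      title = sprintf(
        "%s-regulated: %s (m* = %d, k* = %d)",
        object$direction, object$verdict, object$m_star, object$k_star
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.list_comparison
#' @export
autoplot.directional_comparison <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$m_frac, y = .data$k_frac)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "blue"),
      labels = c(`TRUE` = "significant", `FALSE` = "chance"),
      name = NULL
    ) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "fraction of genes selected (m/N)",
      y = "fraction of genes in common (k/m)"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of an overlap-distance matrix
#'
#' @param object An `overlap_dist`.
#' @param what Plot the distance matrix (`"distance"`, default) or the raw
#'   overlap counts (`"overlap"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_dist <- function(object, what = c("distance", "overlap"), ...) {
  what <- match.arg(what)
  mat <- if (what == "distance") object$d else object$k
  dat <- tibble::as_tibble(as.table(mat), .name_repair = ~ c("row", "col", "value"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (what == "distance") "m_ij" else "k_ij") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
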