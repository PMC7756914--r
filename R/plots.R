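#' @describeIn patient_distance_matrix Heatmap of the distance matrix with
#'   rows and columns in dendrogram leaf order (when clustering is
#'   possible), shorter distances hotter.
#' @param object A `dtw_distmat`.
#' @method autoplot dtw_distmat
#' @export
autoplot.dtw_distmat <- function(object, ...) {
  d <- unclass(object)
  ord <- if (nrow(d) >= 3) ward_cluster(object)$order else seq_len(nrow(d))
  nms <- rownames(d)[ord]
  long <- tidyr::expand_grid(row = nms, col = nms)
  long$distance <- d[cbind(match(long$row, rownames(d)), match(long$col, colnames(d)))]
  long$row <- factor(long$row, levels = nms)
  long$col <- factor(long$col, levels = rev(nms))
  ggplot2::ggplot(long, ggplot2::aes(.data$row, .data$col, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#b2182b", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL, fill = "DTW\ndistance",
                  title = "Pairwise DTW distances between symptom trajectories") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn scree_and_elbow Scree plot of the Ward merge heights with
#'   the selected elbow marked.
#' @param object A `scree_elbow`.
#' @param ... Unused.
#' @method autoplot scree_elbow
#' @export
autoplot.scree_elbow <- function(object, ...) {
  p <- ggplot2::ggplot(object$heights, ggplot2::aes(.data$k, .data$height)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of clusters k", y = "Merge height",
                  title = "Scree of Ward.D2 merge heights") +
    ggplot2::theme_minimal()
  if (!is.na(object$k_star)) {
    p <- p + ggplot2::geom_vline(xintercept = object$k_star,
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @describeIn build_network Circular-layout network: edge thickness and
#'   opacity follow the similarity weight; node size follows strength.
#' @param object A `symptom_network`.
#' @method autoplot symptom_network
#' @export
autoplot.symptom_network <- function(object, ...) {
  cent <- object$centrality
  K <- nrow(cent)
  theta <- 2 * pi * (seq_len(K) - 1) / K
  pos <- tibble::tibble(item = cent$item, name = cent$name,
                        x = cos(theta), y = sin(theta),
                        strength = cent$strength)
  ed <- object$edges |>
    dplyr::left_join(dplyr::select(pos, "item", xa = "x", ya = "y"),
                     by = c(item_a = "item")) |>
    dplyr::left_join(dplyr::select(pos, "item", xb = "x", yb = "y"),
                     by = c(item_b = "item"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   linewidth = .data$weight, alpha = .data$weight),
      colour = "#2166ac"
    ) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(.data$x, .data$y, size = .data$strength),
                        colour = "#b2182b") +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15, label = .data$item)) +
    ggplot2::scale_linewidth(range = c(0.1, 1.6)) +
    ggplot2::scale_alpha(range = c(0.05, 0.9)) +
    ggplot2::coord_equal() +
    ggplot2::guides(alpha = "none") +
    ggplot2::labs(title = "Symptom network (thicker edge = shorter DTW distance)") +
    ggplot2::theme_void()
}

#' @describeIn distatis Compromise plot: items positioned by their first
#'   two compromise factor scores.
#' @param object A `distatis_fit`.
#' @method autoplot distatis_fit
#' @export
autoplot.distatis_fit <- function(object, ...) {
  fs <- tidy(object)
  if (!all(c("F1", "F2") %in% names(fs))) {
    stop("need at least two positive compromise components to plot", call. = FALSE)
  }
  ev <- object$eigenvalues
  pct <- round(100 * ev[1:2] / sum(ev[ev > 0]), 1)
  ggplot2::ggplot(fs, ggplot2::aes(.data$F1, .data$F2, label = .data$item)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "#b2182b") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(x = paste0("Factor 1 (", pct[1], "%)"),
                  y = paste0("Factor 2 (", pct[2], "%)"),
                  title = "Distatis compromise of per-patient distance matrices") +
    ggplot2::theme_minimal()
}

#' @describeIn density_comparison Box plots of the (adjusted) mean DTW
#'   distances by response and remission status.
#' @param object A `density_comparison`.
#' @method autoplot density_comparison
#' @export
autoplot.density_comparison <- function(object, ...) {
  long <- object$data |>
    tidyr::pivot_longer(c("responder", "remitter"),
                        names_to = "contrast", values_to = "reached") |>
    dplyr::filter(!is.na(.data$reached))
  ylab <- if (object$adjust) "Adjusted mean DTW distance (residual)" else "Mean DTW distance"
  ggplot2::ggplot(long, ggplot2::aes(.data$reached, .data$residual)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "Outcome reached", y = ylab,
                  title = "Symptom-network density by treatment outcome") +
    ggplot2::theme_minimal()
}
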