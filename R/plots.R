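#' Heatmap of pairwise uncorrected distances
#'
#' @param object A \code{pdist_tbl} from [distance_matrix()].
#' @param ... Unused.
#' @return A ggplot: symmetric tile heatmap of p-distances in sample order.
#' @method autoplot pdist_tbl
#' @export
autoplot.pdist_tbl <- function(object, ...) {
  ids <- attr(object, "ids") %||%
    unique(c(object$sample_a, object$sample_b))
  both <- dplyr::bind_rows(
    object[, c("sample_a", "sample_b", "p")],
    dplyr::rename(object[, c("sample_a", "sample_b", "p")],
                  sample_a = "sample_b", sample_b = "sample_a"),
    tibble::tibble(sample_a = ids, sample_b = ids, p = 0))
  ggplot2::ggplot(both, ggplot2::aes(
      x = factor(.data$sample_a, levels = ids),
      y = factor(.data$sample_b, levels = rev(ids)),
      fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Uncorrected pairwise p-distances") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Cluster membership plot
#'
#' @param object A \code{haplogroup_clusters} tibble from
#'   [single_linkage_clusters()].
#' @param ... Unused.
#' @return A ggplot: samples stacked by cluster, coloured by cluster.
#' @method autoplot haplogroup_clusters
#' @export
autoplot.haplogroup_clusters <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cluster,
                                       fill = .data$cluster)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "haplogroup cluster", y = "samples",
                  title = sprintf("Single-linkage clusters at p <= %.3g",
                                  attr(object, "threshold"))) +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' Divergence summary plot
#'
#' @param object A \code{divergence_summary} tibble.
#' @param ... Unused.
#' @return A ggplot: fixed-substitution count against minimal inter-group
#'   p-distance for every group pair.
#' @method autoplot divergence_summary
#' @export
autoplot.divergence_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
      x = .data$min_p * 100, y = .data$fixed_count,
      label = paste(.data$group_a, .data$group_b, sep = "|"))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "minimal inter-group p-distance (%)",
                  y = "fixed substitutions",
                  title = "Barcode divergence by group pair") +
    ggplot2::theme_minimal()
}

#' Divergence-time interval plot
#'
#' @param object A \code{divergence_interval}.
#' @param ... Unused.
#' @return A ggplot: per-calibration point estimates spanning the interval.
#' @method autoplot divergence_interval
#' @export
autoplot.divergence_interval <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$t, y = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = c(object$t_low, object$t_high),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "divergence time (Myr)", y = "calibration",
                  title = sprintf("p = %s %% dates to %s",
                                  format(object$p_percent), object$rendered)) +
    ggplot2::theme_minimal()
}
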