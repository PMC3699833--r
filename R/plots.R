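#' Elbow plot of the K sweep
#'
#' Plots the within-cluster sum of squares against the candidate number of
#' clusters, marking the knee selected by [select_k_knee()].
#'
#' @param object A `k_sweep_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot k_sweep_curve
#' @export
autoplot.k_sweep_curve <- function(object, ...) {
  k_star <- tryCatch(suppressWarnings(select_k_knee(object)),
                     error = function(e) NA_integer_)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of clusters K",
                  y = "Within-cluster sum of squares",
                  title = "K-means sweep over candidate chromosome numbers")
  if (!is.na(k_star))
    p <- p + ggplot2::geom_vline(xintercept = k_star, linetype = "dashed",
                                 colour = "firebrick")
  p
}

#' Per-well occupancy profiles of the chromosome clusters
#'
#' Bar panels of each cluster's mean normalized read value per well, with
#' wells called occupied highlighted — the computational rendering of the
#' per-well peak plots used to read chromosome presence.
#'
#' @param object A `well_configuration`.
#' @param clusters Optional subset of cluster ids to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot well_configuration
#' @export
autoplot.well_configuration <- function(object, clusters = NULL, ...) {
  tbl <- tibble::as_tibble(object)
  if (!is.null(clusters))
    tbl <- tbl[tbl$cluster %in% as.character(clusters), ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$well_id, y = .data$mean_value,
                                    fill = factor(.data$present))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey70", `1` = "firebrick"),
                               name = "called present") +
    ggplot2::labs(x = "Well (chromosome preparation)",
                  y = "Mean normalized reads") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Heat map of the deduced occupancy matrix
#'
#' @param config A `well_configuration`.
#' @return A ggplot object showing the binary cluster-by-well occupancy.
#' @export
plot_occupancy <- function(config) {
  tbl <- tibble::as_tibble(config)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$well_id, y = .data$cluster,
                                    fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "firebrick"),
                               name = "present") +
    ggplot2::labs(x = "Well", y = "Chromosome cluster") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
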