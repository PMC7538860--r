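#' Plot a QC report
#'
#' Histogram of per-cell UMI totals with the IQR window, coloured by
#' retention status.
#'
#' @param object an `sn_qc` from [apply_qc()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sn_qc <- function(object, ...) {
  d <- object$cells
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_umi, fill = .data$keep)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.85, position = "identity") +
    ggplot2::geom_vline(xintercept = c(object$bounds$lower, object$bounds$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "total UMI per cell", y = "cells", fill = "retained",
                  title = "QC: per-cell UMI totals and IQR window") +
    ggplot2::theme_minimal()
}

#' Plot cell-cycle scores
#'
#' S vs G2/M score scatter coloured by assigned phase, with the zero axes
#' that define the quiescent quadrant.
#'
#' @param object an `sn_cycle` from [score_cell_cycle()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sn_cycle <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_score, y = .data$g2m_score,
                                       colour = .data$phase)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "S score", y = "G2/M score",
                  title = "Cell-cycle module scores and phase calls") +
    ggplot2::theme_minimal()
}

#' Plot a communication network as a source-by-target heatmap
#'
#' @param object an `sn_comm` from [comm_network()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sn_comm <- function(object, ...) {
  d <- as.data.frame.table(object$pair_counts, responseName = "n")
  names(d)[1:2] <- c("source", "target")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target, y = .data$source,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "target (receptor) cluster", y = "source (ligand) cluster",
                  fill = "pairs",
                  title = "Ligand-receptor interactions per cluster pair") +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Dot plot of -log10 adjusted p per (cluster, panel); dot size is the
#' overlap count.
#'
#' @param object an `sn_enrichment` from [enrich_clusters()].
#' @param alpha significance line (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sn_enrichment <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$panel)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = -log10(.data$p_adj))) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "firebrick",
                                   name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = "cluster", y = "panel", size = "overlap",
                  title = "Panel enrichment of cluster markers") +
    ggplot2::theme_minimal()
}

#' Plot a pooled-profile correlation network
#'
#' Force-directed layout (igraph Fruchterman-Reingold, seeded) of pools,
#' coloured by cluster; edges are correlations above the threshold.
#'
#' @param object an `sn_corr` from [correlation_edges()].
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sn_corr <- function(object, seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes$pool_id)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(pool_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(object$nodes, by = "pool_id")
  segs <- object$edges |>
    left_join(select(nodes, "pool_id", "x", "y"),
              by = c(pool_i = "pool_id")) |>
    left_join(select(nodes, "pool_id", xend = "x", yend = "y"),
              by = c(pool_j = "pool_id"))
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 2) +
    ggplot2::labs(title = sprintf("Pooled-profile correlation network (r > %g)",
                                  object$r_threshold),
                  colour = "cluster") +
    ggplot2::theme_void()
}
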