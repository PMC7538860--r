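#' Tidy a QC report into one row per cell
#'
#' @param x an `sn_qc` from [apply_qc()].
#' @param ... unused.
#' @return tibble of per-cell metrics with pass flags and fail reasons.
#' @export
tidy.sn_qc <- function(x, ...) x$cells

#' One-row summary of a QC run
#'
#' @param x an `sn_qc`.
#' @param ... unused.
#' @return one-row tibble: input/output tallies, the UMI window, and the
#'   housekeeping detection rate (`NA` when no list was supplied).
#' @export
glance.sn_qc <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble(umi_lower = x$bounds$lower, umi_upper = x$bounds$upper,
           q1 = x$bounds$q1, q3 = x$bounds$q3,
           housekeeping_rate = if (is.null(x$housekeeping)) NA_real_ else
             x$housekeeping$rate))
}

#' @export
tidy.sn_comm <- function(x, ...) x$edges

#' @export
glance.sn_comm <- function(x, ...) {
  tibble(n_edges = nrow(x$edges),
         n_clusters = nrow(x$pair_counts),
         n_self_edges = sum(x$edges$source == x$edges$target),
         n_skipped_symbols = length(x$skipped_symbols),
         threshold = x$threshold)
}

#' @export
tidy.sn_enrichment <- function(x, ...) {
  d <- as_tibble(x)
  d$overlap <- map_chr(d$overlap, paste, collapse = ";")
  d
}

#' @export
glance.sn_enrichment <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$p_adj < 0.05),
         min_p_adj = if (nrow(x)) min(x$p_adj) else NA_real_)
}

#' @export
tidy.sn_corr <- function(x, ...) x$edges

#' @export
glance.sn_corr <- function(x, ...) {
  within <- x$nodes$cluster[match(x$edges$pool_i, x$nodes$pool_id)] ==
    x$nodes$cluster[match(x$edges$pool_j, x$nodes$pool_id)]
  tibble(n_pools = nrow(x$nodes), n_edges = nrow(x$edges),
         n_within_cluster = sum(within), n_between_cluster = sum(!within),
         r_threshold = x$r_threshold)
}

#' @export
tidy.sn_cycle <- function(x, ...) as_tibble(x)

#' @export
glance.sn_cycle <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_g1 = sum(x$phase == "G1"), n_s = sum(x$phase == "S"),
         n_g2m = sum(x$phase == "G2M"),
         frac_proliferative = mean(x$phase != "G1"))
}

#' @export
tidy.sn_markers <- function(x, ...) as_tibble(x)

#' @export
glance.sn_markers <- function(x, ...) {
  x |>
    group_by(.data$cluster) |>
    summarise(n_markers = sum(.data$is_marker), .groups = "drop")
}
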