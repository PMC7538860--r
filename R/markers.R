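#' Per-cluster mean raw UMI expression
#'
#' Entry (c, g) is the mean raw UMI of gene g over the cells of cluster c.
#' Raw UMI (not normalized) because the communication threshold downstream is
#' phrased in UMI units.
#'
#' @param x an [sn_counts()].
#' @param labels tibble with columns `barcode`, `cluster` covering every cell.
#' @return object of class `sn_cluster_expr`: `means` (clusters x genes
#'   matrix, columns named by gene symbol), `sizes` (named cluster sizes),
#'   `genes` (the annotation table).
#' @export
cluster_mean_expression <- function(x, labels) {
  stopifnot(inherits(x, "sn_counts"))
  labels <- as_tibble(labels)
  miss <- setdiff(x$barcodes, labels$barcode)
  if (length(miss) > 0) {
    abort(paste0("unlabelled cells: ", paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5)))
  }
  cl <- labels$cluster[match(x$barcodes, labels$barcode)]
  f <- factor(cl)
  ind <- sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                      dims = c(length(f), nlevels(f)))
  sizes <- as.numeric(table(f))
  means <- Matrix::t(x$counts %*% ind)
  means <- as.matrix(means) / sizes
  dimnames(means) <- list(levels(f), x$genes$symbol)
  structure(list(means = means, sizes = setNames(sizes, levels(f)),
                 genes = x$genes),
            class = "sn_cluster_expr")
}

#' @export
print.sn_cluster_expr <- function(x, ...) {
  cat(sprintf("<sn_cluster_expr> %d clusters x %d genes (cells: %d)\n",
              nrow(x$means), ncol(x$means), sum(x$sizes)))
  invisible(x)
}

# Vectorized one-vs-rest two-sided Wilcoxon rank-sum (normal approximation
# with tie correction, no continuity correction). Ranks are computed once per
# gene; per-cluster rank sums come from a single matrix product, so repeated
# label shuffles are cheap.
rank_sum_matrix <- function(ranks, tie_term, membership) {
  n_tot <- ncol(ranks)
  n1 <- colSums(membership)
  n2 <- n_tot - n1
  w <- ranks %*% membership                      # genes x clusters rank sums
  mu <- outer(rep(1, nrow(ranks)), n1 * (n_tot + 1) / 2)
  sig2 <- outer(tie_term, n1 * n2)               # genes x clusters
  sig2[sig2 < 0] <- 0                            # clamp floating-point jitter
  z <- (as.matrix(w) - mu) / sqrt(sig2)
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 1                          # constant gene: no evidence
  pmin(p, 1)
}

#' One-vs-rest cluster marker ranking
#'
#' For each cluster, a two-sided Wilcoxon rank-sum test of every gene's
#' log-normalized expression in the cluster against all other cells, with
#' Benjamini-Hochberg adjustment within the cluster. Markers are the genes
#' with `p_adj < alpha` and `log2fc > min_lfc`, where the fold change is
#' `log2((mean_in + 1) / (mean_out + 1))` on raw cluster means.
#'
#' @param x an [sn_counts()].
#' @param labels tibble with columns `barcode`, `cluster`; at least two
#'   clusters of size >= 2 (singleton clusters are skipped with a warning).
#' @param min_lfc log2 fold-change threshold for marker status (default 0.25).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param scale_total passed to [log_normalize()].
#' @return tibble of class `sn_markers` with one row per (cluster, gene):
#'   `cluster`, `gene_id`, `symbol`, `log2fc`, `p`, `p_adj`, `pct_in`,
#'   `pct_out`, `is_marker`, and `rank` (1-based, by decreasing `log2fc`
#'   among the cluster's markers; `NA` otherwise).
#' @export
rank_markers <- function(x, labels, min_lfc = 0.25, alpha = 0.05,
                         scale_total = 1e4) {
  stopifnot(inherits(x, "sn_counts"))
  labels <- as_tibble(labels)
  ce <- cluster_mean_expression(x, labels)
  clusters <- rownames(ce$means)
  if (length(clusters) < 2) abort("marker ranking needs at least 2 clusters")
  small <- clusters[ce$sizes < 2]
  if (length(small) > 0) {
    warn(paste0("skipping singleton cluster(s): ", paste(small, collapse = ", ")))
    clusters <- setdiff(clusters, small)
    if (length(clusters) < 2) abort("fewer than 2 clusters of size >= 2")
  }

  norm <- as.matrix(log_normalize(x, scale_total))
  ranks <- t(apply(norm, 1, rank, ties.method = "average"))
  n_tot <- ncol(norm)
  tie_term <- apply(norm, 1, function(v) {
    t3 <- tabulate(match(v, unique(v)))
    ((n_tot + 1) - sum(t3^3 - t3) / (n_tot * (n_tot - 1))) / 12
  })

  cl <- labels$cluster[match(x$barcodes, labels$barcode)]
  membership <- vapply(clusters, function(k) as.numeric(cl == k),
                       numeric(n_tot))
  pmat <- rank_sum_matrix(ranks, tie_term, membership)

  det <- x$counts > 0
  res <- purrr::map(clusters, function(k) {
    inside <- cl == k
    m_in <- ce$means[k, ]
    m_out <- colSums(ce$means[setdiff(rownames(ce$means), k), , drop = FALSE] *
                       ce$sizes[setdiff(rownames(ce$means), k)]) /
      sum(ce$sizes[setdiff(rownames(ce$means), k)])
    lfc <- log2((m_in + 1) / (m_out + 1))
    p <- pmat[, k]
    tibble(cluster = k,
           gene_id = x$genes$gene_id,
           symbol = x$genes$symbol,
           log2fc = unname(lfc),
           p = unname(p),
           p_adj = p.adjust(p, method = "BH"),
           pct_in = as.numeric(Matrix::rowSums(det[, inside, drop = FALSE])) / sum(inside),
           pct_out = as.numeric(Matrix::rowSums(det[, !inside, drop = FALSE])) / sum(!inside))
  }) |> bind_rows()

  res <- res |>
    mutate(is_marker = .data$p_adj < alpha & .data$log2fc > min_lfc) |>
    group_by(.data$cluster) |>
    mutate(rank = {
      r <- rep(NA_integer_, dplyr::n())
      idx <- which(.data$is_marker)
      r[idx] <- rank(-.data$log2fc[idx], ties.method = "first")
      r
    }) |>
    ungroup()
  class(res) <- c("sn_markers", class(res))
  attr(res, "universe") <- x$genes$symbol
  res
}

#' Extract ordered marker symbol lists per cluster
#'
#' @param markers an `sn_markers` tibble from [rank_markers()].
#' @return named list: cluster -> marker symbols ordered by decreasing
#'   log2 fold change.
#' @export
marker_lists <- function(markers) {
  stopifnot(inherits(markers, "sn_markers"))
  markers |>
    filter(.data$is_marker) |>
    arrange(.data$cluster, dplyr::desc(.data$log2fc)) |>
    (\(d) split(d$symbol, d$cluster))()
}
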