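#' Pool cells within clusters into averaged profiles
#'
#' Within each cluster, cells are shuffled with a seeded RNG and partitioned
#' into consecutive groups of `pool_size`; the remainder (fewer than
#' `pool_size` cells) is dropped so every pool averages the same number of
#' cells. A pool's profile is the per-gene mean of log-normalized expression
#' over its members (set `normalize = FALSE` to average raw UMI instead).
#'
#' @param x an [sn_counts()].
#' @param labels tibble with `barcode`, `cluster`.
#' @param pool_size cells per pool (default 30, >= 2).
#' @param seed RNG seed for the within-cluster shuffle.
#' @param normalize average log-normalized expression (default) or raw UMI.
#' @param scale_total passed to [log_normalize()].
#' @return object of class `sn_pools`: `profiles` (pools x genes matrix),
#'   `meta` (tibble: `pool_id`, `cluster`, `n_cells`, `members` list-column).
#' @export
pool_cells <- function(x, labels, pool_size = 30, seed = 1L,
                       normalize = TRUE, scale_total = 1e4) {
  stopifnot(inherits(x, "sn_counts"), pool_size >= 2)
  labels <- as_tibble(labels)
  cl <- labels$cluster[match(x$barcodes, labels$barcode)]
  if (anyNA(cl)) abort("every cell must be labelled")
  expr <- if (normalize) log_normalize(x, scale_total) else x$counts

  set.seed(as.integer(seed))
  assignments <- list()
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    if (length(idx) < pool_size) {
      warn(sprintf("cluster %s has %d cells (< pool_size %d); no pool formed",
                   k, length(idx), pool_size))
      next
    }
    idx <- sample(idx)
    n_pools <- length(idx) %/% pool_size
    for (pp in seq_len(n_pools)) {
      members <- idx[(pp - 1L) * pool_size + seq_len(pool_size)]
      assignments[[length(assignments) + 1L]] <-
        list(cluster = k, index = pp, members = members)
    }
  }
  if (length(assignments) == 0) abort("no cluster is large enough to pool")
  profiles <- t(vapply(assignments, function(a) {
    as.numeric(Matrix::rowMeans(expr[, a$members, drop = FALSE]))
  }, numeric(nrow(expr))))
  meta <- tibble(
    pool_id = map_chr(assignments, ~ sprintf("%s_p%02d", .x$cluster, .x$index)),
    cluster = map_chr(assignments, "cluster"),
    n_cells = pool_size,
    members = purrr::map(assignments, ~ x$barcodes[.x$members])
  )
  rownames(profiles) <- meta$pool_id
  colnames(profiles) <- x$genes$symbol
  structure(list(profiles = profiles, meta = meta), class = "sn_pools")
}

#' Pairwise Pearson correlation edges between pooled profiles
#'
#' Scores every unordered pair of pools with the Pearson correlation of
#' their gene vectors and keeps pairs with `r > r_threshold` (strict).
#' Zero-variance profiles (correlation undefined) are excluded with a
#' warning.
#'
#' @param pools an `sn_pools` from [pool_cells()] (>= 2 profiles).
#' @param r_threshold correlation threshold (default 0.95).
#' @return object of class `sn_corr`: `edges` (tibble `pool_i`, `pool_j`,
#'   `r`), `nodes` (the pool metadata of retained pools), `cor_matrix`,
#'   `r_threshold`.
#' @export
correlation_edges <- function(pools, r_threshold = 0.95) {
  stopifnot(inherits(pools, "sn_pools"))
  prof <- pools$profiles
  v <- apply(prof, 1, var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d zero-variance profile(s)", sum(v == 0)))
    prof <- prof[v > 0, , drop = FALSE]
  }
  if (nrow(prof) < 2) abort("need at least 2 profiles with nonzero variance")
  cm <- cor(t(prof))
  idx <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
  edges <- tibble(pool_i = rownames(cm)[idx[, 1]],
                  pool_j = rownames(cm)[idx[, 2]],
                  r = cm[idx]) |>
    arrange(.data$pool_i, .data$pool_j)
  nodes <- filter(pools$meta, .data$pool_id %in% rownames(cm))
  structure(list(edges = edges, nodes = nodes, cor_matrix = cm,
                 r_threshold = r_threshold),
            class = "sn_corr")
}

#' @export
print.sn_corr <- function(x, ...) {
  cat(sprintf("<sn_corr> %d pools, %d edges at r > %g\n",
              nrow(x$nodes), nrow(x$edges), x$r_threshold))
  invisible(x)
}

#' Export a correlation network to CSV and GraphML
#'
#' Writes `nodes.csv` (pool id, cluster, size), `edges.csv` (pool_i, pool_j,
#' r) and `network.graphml` (via igraph) into `dir`.
#'
#' @param net an `sn_corr` from [correlation_edges()].
#' @param dir output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, dir) {
  stopifnot(inherits(net, "sn_corr"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nodes.csv", "edges.csv", "network.graphml"))
  nodes <- select(net$nodes, "pool_id", "cluster", "n_cells")
  utils::write.csv(nodes, paths[1], row.names = FALSE)
  utils::write.csv(net$edges, paths[2], row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges) > 0) net$edges else
      data.frame(pool_i = character(), pool_j = character(), r = numeric()),
    directed = FALSE, vertices = as.data.frame(nodes))
  igraph::write_graph(g, paths[3], format = "graphml")
  invisible(paths)
}
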