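#' Read a ligand-receptor pair table
#'
#' Two- or three-column CSV: ligand symbol, receptor symbol, optional source
#' database tag. Duplicate (ligand, receptor) rows are dropped.
#'
#' @param path CSV file with a header row.
#' @return tibble with columns `ligand`, `receptor`, `db`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) abort(sprintf("pair table not found: '%s'", path))
  d <- utils::read.csv(path, colClasses = "character")
  if (ncol(d) < 2) abort("pair table needs at least ligand and receptor columns")
  out <- tibble(ligand = d[[1]], receptor = d[[2]],
                db = if (ncol(d) >= 3) d[[3]] else NA_character_)
  lr_pair_table(out)
}

lr_pair_table <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    abort("pair table needs 'ligand' and 'receptor' columns")
  }
  if (!"db" %in% names(pairs)) pairs$db <- NA_character_
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    abort("pair table contains empty symbols")
  }
  distinct(pairs, .data$ligand, .data$receptor, .keep_all = TRUE)
}

#' Per-cluster expressed ligand and receptor sets
#'
#' A molecule is expressed in a cluster iff its cluster-mean raw UMI exceeds
#' `threshold` (strictly, by default; the boundary semantics are exposed via
#' `inclusive` because "above" is ambiguous at exactly the threshold).
#' Ligand and receptor roles come from the pair table; a gene named in both
#' roles is counted in both. Pair symbols absent from the gene universe are
#' excluded and reported in the `skipped` attribute.
#'
#' @param ce an `sn_cluster_expr` from [cluster_mean_expression()] (raw UMI).
#' @param pairs tibble with `ligand`, `receptor` columns.
#' @param threshold mean-UMI expression threshold (default 1).
#' @param inclusive if `TRUE`, means exactly equal to `threshold` count as
#'   expressed.
#' @return named list per cluster with `ligands` and `receptors` character
#'   sets; attribute `skipped` lists pair symbols outside the universe.
#' @export
expressed_molecules <- function(ce, pairs, threshold = 1, inclusive = FALSE) {
  stopifnot(inherits(ce, "sn_cluster_expr"))
  pairs <- lr_pair_table(pairs)
  universe <- colnames(ce$means)
  lig <- unique(pairs$ligand)
  rec <- unique(pairs$receptor)
  skipped <- setdiff(c(lig, rec), universe)
  lig <- intersect(lig, universe)
  rec <- intersect(rec, universe)
  cmp <- if (inclusive) `>=` else `>`
  out <- lapply(rownames(ce$means), function(cl) {
    list(ligands = lig[cmp(ce$means[cl, lig], threshold)],
         receptors = rec[cmp(ce$means[cl, rec], threshold)])
  })
  names(out) <- rownames(ce$means)
  attr(out, "skipped") <- skipped
  out
}

#' Enumerate directed ligand-receptor communication edges
#'
#' Emits an edge (source, target, ligand, receptor) for every pair (L, R)
#' with L expressed in the source and R expressed in the target, over every
#' ordered cluster pair. Self-edges (source == target) are retained by
#' default: within-cluster signalling is part of the network.
#'
#' @param expressed output of [expressed_molecules()].
#' @param pairs tibble with `ligand`, `receptor` columns.
#' @param self_edges keep source == target edges (default `TRUE`).
#' @return tibble with columns `source`, `target`, `ligand`, `receptor`.
#' @export
build_comm_edges <- function(expressed, pairs, self_edges = TRUE) {
  pairs <- lr_pair_table(pairs)
  clusters <- names(expressed)
  lig_tbl <- purrr::imap(expressed, function(e, cl) {
    tibble(cluster = cl, ligand = e$ligands)
  }) |> bind_rows()
  rec_tbl <- purrr::imap(expressed, function(e, cl) {
    tibble(cluster = cl, receptor = e$receptors)
  }) |> bind_rows()
  edges <- pairs |>
    select("ligand", "receptor") |>
    inner_join(rename(lig_tbl, source = "cluster"), by = "ligand",
               relationship = "many-to-many") |>
    inner_join(rename(rec_tbl, target = "cluster"), by = "receptor",
               relationship = "many-to-many") |>
    select("source", "target", "ligand", "receptor") |>
    arrange(.data$source, .data$target, .data$ligand, .data$receptor)
  if (!self_edges) edges <- filter(edges, .data$source != .data$target)
  edges
}

#' Summarize a communication network
#'
#' @param edges edge tibble from [build_comm_edges()].
#' @param expressed output of [expressed_molecules()] (supplies the
#'   per-cluster expressed-molecule tallies and the cluster roster).
#' @return list: `pair_counts` (square source x target count matrix, rows =
#'   sources; chord-plot ready), `cluster_summary` (per cluster: distinct
#'   expressed ligands/receptors, outgoing and incoming edge counts).
#' @export
summarize_network <- function(edges, expressed) {
  clusters <- names(expressed)
  m <- matrix(0L, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  if (nrow(edges) > 0) {
    tab <- table(factor(edges$source, clusters), factor(edges$target, clusters))
    m[] <- as.integer(tab)
  }
  cs <- tibble(
    cluster = clusters,
    n_ligands = unname(map_int(expressed, ~ length(.x$ligands))),
    n_receptors = unname(map_int(expressed, ~ length(.x$receptors))),
    n_outgoing = as.integer(rowSums(m)),
    n_incoming = as.integer(colSums(m))
  )
  list(pair_counts = m, cluster_summary = cs)
}

#' Build the full cluster-level communication network
#'
#' Convenience wrapper: cluster means -> expressed sets -> edges -> summary.
#'
#' @param x an [sn_counts()] (raw UMI).
#' @param labels tibble with `barcode`, `cluster`.
#' @param pairs ligand-receptor pair tibble (see [read_lr_pairs()]).
#' @inheritParams expressed_molecules
#' @inheritParams build_comm_edges
#' @return object of class `sn_comm`: `edges`, `expressed`, `pair_counts`,
#'   `cluster_summary`, `skipped_symbols`, `threshold`.
#' @export
comm_network <- function(x, labels, pairs, threshold = 1, inclusive = FALSE,
                         self_edges = TRUE) {
  ce <- cluster_mean_expression(x, labels)
  expressed <- expressed_molecules(ce, pairs, threshold, inclusive)
  edges <- build_comm_edges(expressed, pairs, self_edges)
  s <- summarize_network(edges, expressed)
  structure(list(edges = edges, expressed = expressed,
                 pair_counts = s$pair_counts,
                 cluster_summary = s$cluster_summary,
                 skipped_symbols = attr(expressed, "skipped"),
                 threshold = threshold),
            class = "sn_comm")
}

#' @export
print.sn_comm <- function(x, ...) {
  cat(sprintf("<sn_comm> %d edges over %d clusters (mean-UMI threshold %g)\n",
              nrow(x$edges), nrow(x$pair_counts), x$threshold))
  if (length(x$skipped_symbols) > 0) {
    cat(sprintf("  %d pair symbols absent from the gene universe\n",
                length(x$skipped_symbols)))
  }
  invisible(x)
}
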