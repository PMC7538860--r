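#' Configuration for the synthetic snRNA-seq generator
#'
#' The generator emulates the structure a droplet single-nucleus experiment
#' hands to downstream analysis: negative-binomial UMI counts over ~10
#' clusters of a few hundred cells, a mitochondrial gene block, lognormal
#' library-size variation, a small debris fraction (high mito, low library),
#' cluster-restricted marker programs, an optional chromosome-21 dosage shift
#' in one cluster, and planted ligand-receptor pairs whose cluster-mean UMI
#' clears the communication threshold.
#'
#' @param n_clusters number of clusters.
#' @param cells_per_cluster cells per cluster.
#' @param n_genes total genes.
#' @param n_mito_genes genes flagged mitochondrial (symbols prefixed `MT-`).
#' @param nb_mean baseline per-gene negative-binomial mean UMI.
#' @param nb_dispersion negative-binomial size parameter (variance
#'   `mu + mu^2/size`; large values approach Poisson).
#' @param frac_chr21_genes fraction of genes annotated to chromosome 21;
#'   the count is `round(frac * n_genes)`, assigned to the lexicographically
#'   first non-mito symbols.
#' @param dosage_cluster cluster id (e.g. `"C4"`) whose chr21 genes get their
#'   mean multiplied by `dosage_fold`, or `NULL` for none.
#' @param dosage_fold multiplicative dosage shift, `>= 1`.
#' @param lr_pairs tibble of planted pairs with columns `ligand`, `receptor`,
#'   `source`, `target` (gene symbols and cluster ids), or `NULL` to plant
#'   the five default pairs C0->C1, C2->C3, ..., C8->C9.
#' @param n_marker_genes planted marker genes per cluster.
#' @param marker_fold mean fold elevation of a cluster's markers.
#' @param mito_mean_fold baseline elevation of mitochondrial genes (sets the
#'   clean-cell mito fraction around 3%).
#' @param lr_mean mean UMI given to a planted ligand in its source cluster and
#'   receptor in its target cluster.
#' @param libsize_sigma sdlog of the per-cell lognormal library factor.
#' @param debris_frac fraction of cells generated as debris.
#' @param debris_mito_fold mito mean inflation for debris cells.
#' @param debris_lib_factor library-size multiplier for debris cells.
#' @param seed integer seed; one RNG stream drives all draws.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 10,
                       cells_per_cluster = 300,
                       n_genes = 2000,
                       n_mito_genes = 13,
                       nb_mean = 0.5,
                       nb_dispersion = 2,
                       frac_chr21_genes = 0.02,
                       dosage_cluster = NULL,
                       dosage_fold = 1,
                       lr_pairs = NULL,
                       n_marker_genes = 20,
                       marker_fold = 4,
                       mito_mean_fold = 5,
                       lr_mean = 5,
                       libsize_sigma = 0.3,
                       debris_frac = 0.02,
                       debris_mito_fold = 10,
                       debris_lib_factor = 0.2,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) abort(sprintf("invalid sim_config field '%s': %s", field, why))
  }
  chk(cfg$n_clusters >= 1, "n_clusters", "must be >= 1")
  chk(cfg$cells_per_cluster >= 1, "cells_per_cluster", "must be >= 1")
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(cfg$n_mito_genes >= 0 && cfg$n_mito_genes < cfg$n_genes,
      "n_mito_genes", "must satisfy 0 <= n_mito_genes < n_genes")
  chk(cfg$nb_mean > 0, "nb_mean", "must be positive")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be positive")
  chk(cfg$frac_chr21_genes >= 0 && cfg$frac_chr21_genes <= 1,
      "frac_chr21_genes", "must lie in [0, 1]")
  chk(cfg$dosage_fold >= 1, "dosage_fold", "must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  clusters <- cluster_ids(cfg)
  if (!is.null(cfg$dosage_cluster)) {
    chk(cfg$dosage_cluster %in% clusters, "dosage_cluster",
        paste0("must be one of ", paste(clusters, collapse = ", ")))
  }
  ann <- generate_gene_annotations(cfg)
  if (is.null(cfg$lr_pairs)) cfg$lr_pairs <- default_lr_pairs(cfg, ann)
  cfg$lr_pairs <- as_tibble(cfg$lr_pairs)
  if (nrow(cfg$lr_pairs) > 0) {
    syms <- unique(c(cfg$lr_pairs$ligand, cfg$lr_pairs$receptor))
    chk(all(syms %in% ann$symbol), "lr_pairs",
        "planted pair genes must exist in the gene universe")
    chk(!any(syms %in% ann$symbol[ann$mito]), "lr_pairs",
        "planted pair genes collide with mitochondrial genes")
    chk(all(c(cfg$lr_pairs$source, cfg$lr_pairs$target) %in% clusters),
        "lr_pairs", "source/target clusters must exist")
  }
  cfg
}

cluster_ids <- function(cfg) paste0("C", seq_len(cfg$n_clusters) - 1L)

# Deterministic symbol layout: mito genes last; among non-mito symbols the
# lexicographically first round(frac * n_genes) become chr21, the next
# n_clusters * n_marker_genes become per-cluster marker blocks, then the
# default planted ligand/receptor genes.
generate_symbols <- function(cfg) {
  n_bg <- cfg$n_genes - cfg$n_mito_genes
  width <- max(5, nchar(as.character(cfg$n_genes)))
  c(sprintf(paste0("GENE%0", width, "d"), seq_len(n_bg)),
    sprintf("MT-%02d", seq_len(cfg$n_mito_genes)))
}

marker_block <- function(cfg) {
  n_chr21 <- round(cfg$frac_chr21_genes * cfg$n_genes)
  start <- n_chr21 + 1L
  syms <- generate_symbols(cfg)
  lapply(setNames(seq_len(cfg$n_clusters), cluster_ids(cfg)), function(k) {
    idx <- start + (k - 1L) * cfg$n_marker_genes + seq_len(cfg$n_marker_genes) - 1L
    if (max(idx) > cfg$n_genes - cfg$n_mito_genes) {
      abort("invalid sim_config field 'n_marker_genes': marker blocks exceed the non-mito gene pool")
    }
    syms[idx]
  })
}

default_lr_pairs <- function(cfg, ann) {
  n_pairs <- min(5L, cfg$n_clusters %/% 2L)
  if (n_pairs == 0) return(tibble(ligand = character(), receptor = character(),
                                  source = character(), target = character()))
  n_chr21 <- round(cfg$frac_chr21_genes * cfg$n_genes)
  after_markers <- n_chr21 + cfg$n_clusters * cfg$n_marker_genes
  syms <- generate_symbols(cfg)
  need <- 2L * n_pairs
  if (after_markers + need > cfg$n_genes - cfg$n_mito_genes) {
    abort("invalid sim_config field 'n_genes': too few genes to plant default ligand-receptor pairs")
  }
  pool <- syms[after_markers + seq_len(need)]
  cl <- cluster_ids(cfg)
  tibble(ligand = pool[seq_len(n_pairs) * 2L - 1L],
         receptor = pool[seq_len(n_pairs) * 2L],
         source = cl[seq_len(n_pairs) * 2L - 1L],
         target = cl[seq_len(n_pairs) * 2L])
}

#' Generate the gene annotation table for a simulation
#'
#' Deterministic (consumes no randomness): one row per gene with a unique id,
#' symbol, chromosome label and mitochondrial flag. Exactly
#' `round(frac_chr21_genes * n_genes)` genes are labelled `chr21` (the
#' lexicographically first non-mito symbols); mito genes get `chrM`; the rest
#' cycle through the remaining autosome labels.
#'
#' @param cfg a [sim_config()].
#' @return tibble with columns `gene_id`, `symbol`, `chromosome`, `mito`.
#' @export
generate_gene_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  syms <- generate_symbols(cfg)
  mito <- startsWith(syms, "MT-")
  n_chr21 <- round(cfg$frac_chr21_genes * cfg$n_genes)
  non_mito_sorted <- sort(syms[!mito])
  chr21 <- syms %in% non_mito_sorted[seq_len(n_chr21)]
  autosomes <- paste0("chr", c(1:20, 22))
  chromosome <- autosomes[(seq_along(syms) - 1L) %% length(autosomes) + 1L]
  chromosome[chr21] <- "chr21"
  chromosome[mito] <- "chrM"
  tibble(gene_id = sprintf("SIMG%06d", seq_along(syms)),
         symbol = syms, chromosome = chromosome, mito = mito)
}

#' Generate synthetic counts with planted ground truth
#'
#' Draws UMI counts from a negative binomial per gene per cell. The RNG
#' stream (keyed by `cfg$seed`) is consumed in a fixed order: (1) per-cell
#' lognormal library factors, (2) debris cell selection, (3) the count draws.
#'
#' @param cfg a [sim_config()].
#' @return A list with `counts` (an [sn_counts()]) and `truth`, a list
#'   carrying `cells` (barcode, cluster, debris flag), `markers` (per-cluster
#'   planted marker symbols), `comm_edges` (the planted ligand-receptor
#'   edges), `chr21_genes`, and `dosage_cluster`.
#' @export
generate_counts <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  ann <- generate_gene_annotations(cfg)
  clusters <- cluster_ids(cfg)
  markers <- marker_block(cfg)
  n_cells <- cfg$n_clusters * cfg$cells_per_cluster
  cell_cluster <- rep(clusters, each = cfg$cells_per_cluster)
  barcodes <- sprintf("BC%06d", seq_len(n_cells))

  # per-gene x per-cluster mean matrix
  mu <- matrix(cfg$nb_mean, nrow = cfg$n_genes, ncol = cfg$n_clusters,
               dimnames = list(ann$symbol, clusters))
  mu[ann$mito, ] <- mu[ann$mito, ] * cfg$mito_mean_fold
  for (cl in clusters) mu[markers[[cl]], cl] <- mu[markers[[cl]], cl] * cfg$marker_fold
  if (!is.null(cfg$dosage_cluster)) {
    chr21 <- ann$symbol[ann$chromosome == "chr21"]
    mu[chr21, cfg$dosage_cluster] <- mu[chr21, cfg$dosage_cluster] * cfg$dosage_fold
  }
  if (nrow(cfg$lr_pairs) > 0) {
    for (i in seq_len(nrow(cfg$lr_pairs))) {
      mu[cfg$lr_pairs$ligand[i], cfg$lr_pairs$source[i]] <- cfg$lr_mean
      mu[cfg$lr_pairs$receptor[i], cfg$lr_pairs$target[i]] <- cfg$lr_mean
    }
  }

  set.seed(as.integer(cfg$seed))
  lib <- rlnorm(n_cells, meanlog = 0, sdlog = cfg$libsize_sigma)
  n_debris <- round(cfg$debris_frac * n_cells)
  debris_idx <- if (n_debris > 0) sample.int(n_cells, n_debris) else integer(0)
  debris <- seq_len(n_cells) %in% debris_idx
  lib[debris] <- lib[debris] * cfg$debris_lib_factor

  mu_cells <- mu[, match(cell_cluster, clusters), drop = FALSE]
  mu_cells <- sweep(mu_cells, 2, lib, `*`)
  if (any(debris)) {
    mu_cells[ann$mito, debris] <- mu_cells[ann$mito, debris] * cfg$debris_mito_fold
  }
  x <- rnbinom(length(mu_cells), size = cfg$nb_dispersion, mu = as.vector(mu_cells))
  m <- Matrix::Matrix(matrix(x, nrow = cfg$n_genes, ncol = n_cells), sparse = TRUE)

  counts <- sn_counts(m, ann, barcodes)
  truth <- list(
    cells = tibble(barcode = barcodes, cluster = cell_cluster, debris = debris),
    markers = markers,
    comm_edges = cfg$lr_pairs[, c("source", "target", "ligand", "receptor")],
    chr21_genes = ann$symbol[ann$chromosome == "chr21"],
    dosage_cluster = cfg$dosage_cluster
  )
  list(counts = counts, truth = truth)
}
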