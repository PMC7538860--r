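# Small simulation configurations for unit tests. The mito baseline fold is
# reduced alongside the gene count: the clean-cell mito fraction scales with
# n_mito/n_genes, and the defaults are calibrated for 2000 genes.
small_cfg <- function(...) {
  defaults <- list(n_clusters = 3, cells_per_cluster = 80, n_genes = 300,
                   n_mito_genes = 5, mito_mean_fold = 2, n_marker_genes = 10,
                   frac_chr21_genes = 0.1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# mid-sized config for pipeline-level tests
reduced_cfg <- function(...) {
  defaults <- list(n_clusters = 5, cells_per_cluster = 100, n_genes = 400,
                   n_mito_genes = 5, mito_mean_fold = 2, n_marker_genes = 10,
                   frac_chr21_genes = 0.05)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

no_lr <- function() {
  data.frame(ligand = character(), receptor = character(),
             source = character(), target = character())
}

# Hand-built sn_counts from a dense matrix; rows become genes G1, G2, ...
# (symbols equal ids unless given), optionally flagging mito rows.
tiny_sn <- function(m, mito_rows = integer(0), symbols = NULL,
                    chromosome = NULL) {
  m <- as.matrix(m)
  ng <- nrow(m); nc <- ncol(m)
  symbols <- symbols %||% paste0("G", seq_len(ng))
  genes <- tibble::tibble(
    gene_id = paste0("ID", seq_len(ng)),
    symbol = symbols,
    chromosome = chromosome %||% rep("chr1", ng),
    mito = seq_len(ng) %in% mito_rows)
  sn_counts(m, genes, paste0("cell", seq_len(nc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

labels_of <- function(sim, x = NULL) {
  lab <- sim$truth$cells[, c("barcode", "cluster")]
  if (!is.null(x)) lab <- dplyr::filter(lab, barcode %in% x$barcodes)
  lab
}
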