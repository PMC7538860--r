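#' Sparse single-nucleus count container
#'
#' Bundles a sparse genes x cells UMI matrix with its gene annotation table
#' and cell barcodes. All downstream stages (`apply_qc()`, `log_normalize()`,
#' `cluster_mean_expression()`, ...) consume this object.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in rows,
#'   cells in columns. Coerced to `Matrix::dgCMatrix`.
#' @param genes tibble with one row per gene: columns `gene_id`, `symbol`,
#'   `chromosome`, `mito` (logical mitochondrial flag).
#' @param barcodes character vector of unique cell barcodes, one per column.
#'
#' @return An object of class `sn_counts`: a list with elements `counts`,
#'   `genes`, `barcodes`.
#' @export
sn_counts <- function(counts, genes, barcodes) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  genes <- as_tibble(genes)
  barcodes <- as.character(barcodes)
  required <- c("gene_id", "symbol", "chromosome", "mito")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) != nrow(counts)) {
    abort(sprintf("gene table has %d rows but matrix has %d gene rows",
                  nrow(genes), nrow(counts)))
  }
  if (length(barcodes) != ncol(counts)) {
    abort(sprintf("%d barcodes but matrix has %d cell columns",
                  length(barcodes), ncol(counts)))
  }
  if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
  if (anyDuplicated(barcodes)) abort("barcodes must be unique")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  if (any(counts@x != floor(counts@x))) abort("counts must be integral UMI")
  dimnames(counts) <- list(genes$gene_id, barcodes)
  structure(list(counts = counts, genes = genes, barcodes = barcodes),
            class = "sn_counts")
}

#' @export
print.sn_counts <- function(x, ...) {
  cat(sprintf("<sn_counts> %d genes x %d cells (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  cat(sprintf("  mito genes: %d; chromosomes: %d distinct\n",
              sum(x$genes$mito), length(unique(x$genes$chromosome))))
  invisible(x)
}

#' @export
dim.sn_counts <- function(x) dim(x$counts)

subset_sn <- function(x, genes_keep = NULL, cells_keep = NULL) {
  gi <- genes_keep %||% rep(TRUE, nrow(x$counts))
  ci <- cells_keep %||% rep(TRUE, ncol(x$counts))
  sn_counts(x$counts[gi, ci, drop = FALSE],
            x$genes[gi, , drop = FALSE],
            x$barcodes[ci])
}

#' Write a count matrix as a 10x-convention triplet fixture
#'
#' Writes `matrix.mtx` (MatrixMarket triplet), `features.tsv`
#' (gene_id, symbol, chromosome, mito_flag; no header) and `barcodes.tsv`
#' into `dir`. Round-trips exactly through [read_10x()].
#'
#' @param x an [sn_counts()] object, non-empty.
#' @param dir output directory; created if absent.
#' @return Invisibly, the paths of the three files written.
#' @export
write_10x <- function(x, dir) {
  stopifnot(inherits(x, "sn_counts"))
  if (prod(dim(x$counts)) == 0) abort("refusing to write an empty matrix")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", dir))
  }
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  feat <- data.frame(x$genes$gene_id, x$genes$symbol, x$genes$chromosome,
                     as.integer(x$genes$mito))
  utils::write.table(feat, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes, paths[3])
  invisible(paths)
}

#' Read a 10x-convention count directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir`.
#' A features file without a chromosome column is accepted with the
#' chromosome marked `"unknown"` (a warning is raised).
#'
#' @param dir directory holding the three files.
#' @return An [sn_counts()] object in file order.
#' @export
read_10x <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    abort(paste0("missing 10x file(s): ", paste(absent, collapse = ", ")))
  }
  complain <- function(c) {
    abort(sprintf("malformed MatrixMarket file '%s': %s",
                  paths[1], conditionMessage(c)))
  }
  # readMM only warns on a truncated triplet body; treat that as fatal too
  m <- withCallingHandlers(
    tryCatch(Matrix::readMM(paths[1]), error = complain),
    warning = complain
  )
  feat <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
  if (ncol(feat) < 2) abort("features.tsv needs at least gene_id and symbol")
  if (ncol(feat) < 3) {
    warn("features.tsv has no chromosome column; marking chromosome 'unknown'")
    feat$V3 <- "unknown"
  }
  if (ncol(feat) < 4) feat$V4 <- "0"
  genes <- tibble(gene_id = feat[[1]], symbol = feat[[2]],
                  chromosome = feat[[3]], mito = feat[[4]] == "1")
  barcodes <- readLines(paths[3])
  if (nrow(m) != nrow(genes) || ncol(m) != length(barcodes)) {
    abort(sprintf(
      "dimension mismatch: matrix.mtx declares %d x %d but sidecars carry %d genes and %d barcodes",
      nrow(m), ncol(m), nrow(genes), length(barcodes)))
  }
  sn_counts(m, genes, barcodes)
}

#' Library-size normalize and log-transform
#'
#' Scales every cell's counts to sum to `scale_total`, then applies
#' `log(1 + x)` (natural log). Sparsity is preserved.
#'
#' @param x an [sn_counts()] object (typically QC-filtered).
#' @param scale_total target per-cell total after scaling (default 1e4).
#' @return A sparse `dgCMatrix` of log-normalized expression, genes x cells,
#'   with the same dimnames as the input counts.
#' @export
log_normalize <- function(x, scale_total = 1e4) {
  stopifnot(inherits(x, "sn_counts"), scale_total > 0)
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    abort(paste0("cells with zero total UMI cannot be normalized: ",
                 paste(head(x$barcodes[totals == 0], 5), collapse = ", ")))
  }
  m <- x$counts
  # scale each column: divide @x entries by their column total
  percol <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x / percol * scale_total)
  m
}
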