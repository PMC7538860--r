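#' Quality-control parameters
#'
#' The three filters applied by [apply_qc()], in order: (1) drop genes
#' detected in fewer than `min_gene_prevalence` of all cells; (2) drop cells
#' whose mitochondrial UMI fraction exceeds `max_mito_fraction` (strict);
#' (3) drop cells whose total UMI falls outside
#' `[Q1 - iqr_multiplier * IQR, Q3 + iqr_multiplier * IQR]` (closed interval),
#' with quartiles taken over the cells surviving the mito filter unless
#' `bounds_on_all_cells` is set.
#'
#' @param min_gene_prevalence minimum fraction of cells a gene must be
#'   detected in (default 0.001, i.e. 0.1%).
#' @param max_mito_fraction maximum mitochondrial fraction (default 0.10).
#' @param iqr_multiplier half-width of the UMI window in IQR units (default 1).
#' @param bounds_on_all_cells compute UMI quartiles before the mito filter
#'   instead of after it.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_gene_prevalence = 0.001,
                      max_mito_fraction = 0.10,
                      iqr_multiplier = 1,
                      bounds_on_all_cells = FALSE) {
  stopifnot(min_gene_prevalence >= 0, min_gene_prevalence <= 1,
            max_mito_fraction > 0, max_mito_fraction <= 1,
            iqr_multiplier > 0)
  structure(list(min_gene_prevalence = min_gene_prevalence,
                 max_mito_fraction = max_mito_fraction,
                 iqr_multiplier = iqr_multiplier,
                 bounds_on_all_cells = bounds_on_all_cells),
            class = "qc_params")
}

#' Gene-prevalence filter
#'
#' Keeps gene `g` iff it is detected (raw count > 0) in at least
#' `min_gene_prevalence * n_cells` cells.
#'
#' @param x an [sn_counts()].
#' @param params a [qc_params()].
#' @return list with `counts` (filtered [sn_counts()]) and `genes`, a tibble
#'   of per-gene `n_cells_detected` and `keep`.
#' @export
filter_genes <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "sn_counts"))
  n_cells <- ncol(x$counts)
  detected <- Matrix::rowSums(x$counts > 0)
  keep <- detected >= params$min_gene_prevalence * n_cells
  if (!any(keep)) abort("gene filter removed every gene; review min_gene_prevalence")
  report <- tibble(gene_id = x$genes$gene_id, symbol = x$genes$symbol,
                   n_cells_detected = as.integer(detected), keep = unname(keep))
  list(counts = subset_sn(x, genes_keep = keep), genes = report)
}

#' Per-cell QC metrics
#'
#' @param x an [sn_counts()] with mito flags in the gene table.
#' @return tibble with `barcode`, `total_umi`, `n_genes_detected`,
#'   `mito_fraction` and a `degenerate` flag for zero-total cells (whose
#'   mito fraction is defined as 0).
#' @export
cell_metrics <- function(x) {
  stopifnot(inherits(x, "sn_counts"))
  total <- Matrix::colSums(x$counts)
  if (!any(x$genes$mito)) {
    warn("no mitochondrial genes in annotation; all mito fractions are 0")
    mito_total <- rep(0, ncol(x$counts))
  } else {
    mito_total <- Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE])
  }
  frac <- ifelse(total > 0, mito_total / total, 0)
  tibble(barcode = x$barcodes,
         total_umi = as.numeric(total),
         n_genes_detected = as.integer(Matrix::colSums(x$counts > 0)),
         mito_fraction = as.numeric(frac),
         degenerate = total == 0)
}

#' Interquartile-range bounds on per-cell UMI totals
#'
#' Quartiles use linear interpolation between the closest order statistics
#' (`stats::quantile` type 7); `lower = Q1 - k*IQR`, `upper = Q3 + k*IQR`.
#'
#' @param totals numeric vector of per-cell UMI totals (length >= 4).
#' @param params a [qc_params()]; `iqr_multiplier` is `k`.
#' @return named list: `q1`, `q3`, `iqr`, `lower`, `upper`.
#' @export
umi_iqr_bounds <- function(totals, params = qc_params()) {
  if (length(totals) < 4) {
    abort("need at least 4 cells for stable quartiles")
  }
  q <- unname(quantile(totals, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower = q[1] - params$iqr_multiplier * iqr,
       upper = q[2] + params$iqr_multiplier * iqr)
}

#' Apply the three-rule QC and the housekeeping reliability report
#'
#' Filters run in order: gene prevalence, mitochondrial fraction
#' (fail iff fraction > `max_mito_fraction`), then the UMI window (fail iff
#' total outside the closed `[lower, upper]`, bounds computed on the cells
#' surviving the mito filter). The housekeeping check is advisory only:
#' it reports the fraction of housekeeping symbols detected in at least half
#' of the retained cells and never removes anything.
#'
#' @param x an [sn_counts()].
#' @param params a [qc_params()].
#' @param housekeeping optional character vector of housekeeping gene symbols.
#' @return An object of class `sn_qc`: `filtered` (the retained
#'   [sn_counts()]), `cells` (per-cell metrics with per-filter pass flags and
#'   `fail_reasons`), `genes` (per-gene report), `bounds`, `params`,
#'   `housekeeping` (detection rate and per-symbol table, or `NULL`), and a
#'   `summary` of input/output tallies.
#' @export
apply_qc <- function(x, params = qc_params(), housekeeping = NULL) {
  stopifnot(inherits(x, "sn_counts"))
  gf <- filter_genes(x, params)
  xg <- gf$counts

  metrics <- cell_metrics(xg)
  pass_mito <- metrics$mito_fraction <= params$max_mito_fraction
  pool <- if (params$bounds_on_all_cells) metrics$total_umi else metrics$total_umi[pass_mito]
  bounds <- umi_iqr_bounds(pool, params)
  pass_umi <- metrics$total_umi >= bounds$lower & metrics$total_umi <= bounds$upper
  keep <- pass_mito & pass_umi

  if (!any(keep)) abort("QC removed every cell; review parameters")
  cells <- metrics |>
    mutate(pass_mito = pass_mito, pass_umi = pass_umi, keep = keep,
           fail_reasons = purrr::map2_chr(pass_mito, pass_umi, function(m, u) {
             paste(c(if (!m) "mito", if (!u) "umi_range"), collapse = ";")
           }))

  filtered <- subset_sn(xg, cells_keep = keep)

  hk <- NULL
  if (!is.null(housekeeping)) {
    present <- housekeeping %in% filtered$genes$symbol
    det_rate <- rep(0, length(housekeeping))
    if (any(present)) {
      rows <- match(housekeeping[present], filtered$genes$symbol)
      det_rate[present] <- Matrix::rowSums(filtered$counts[rows, , drop = FALSE] > 0) /
        ncol(filtered$counts)
    }
    hk <- list(
      table = tibble(symbol = housekeeping, present = present,
                     detection_rate = det_rate, detected_half = det_rate >= 0.5),
      rate = mean(det_rate >= 0.5)
    )
  }

  structure(list(
    filtered = filtered, cells = cells, genes = gf$genes,
    bounds = bounds, params = params, housekeeping = hk,
    summary = tibble(
      n_genes_in = nrow(x$counts), n_genes_out = nrow(filtered$counts),
      n_genes_removed = nrow(x$counts) - nrow(filtered$counts),
      n_cells_in = ncol(x$counts), n_cells_out = ncol(filtered$counts),
      n_cells_removed = ncol(x$counts) - ncol(filtered$counts))
  ), class = "sn_qc")
}

#' @export
print.sn_qc <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sn_qc> genes %d -> %d, cells %d -> %d\n",
              s$n_genes_in, s$n_genes_out, s$n_cells_in, s$n_cells_out))
  cat(sprintf("  UMI window [%.1f, %.1f] (Q1 %.1f, Q3 %.1f)\n",
              x$bounds$lower, x$bounds$upper, x$bounds$q1, x$bounds$q3))
  if (!is.null(x$housekeeping)) {
    cat(sprintf("  housekeeping detection rate: %.2f\n", x$housekeeping$rate))
  }
  invisible(x)
}
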