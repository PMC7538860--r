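#' Expression-bin-controlled module score
#'
#' Scores each cell for a gene program as the mean log-normalized expression
#' over the program's genes minus the mean over a matched control pool.
#' Controls are drawn by ranking all genes by mean expression across cells
#' into `n_bins` equal-frequency bins and sampling `n_ctrl` genes from the
#' bin of each program gene (without replacement within a bin when the bin is
#' large enough). This is the standard bin-matched control construction used
#' for cell-cycle scoring.
#'
#' @param norm log-normalized genes x cells matrix with gene symbols as
#'   rownames (see [log_normalize()]).
#' @param gene_set character vector of program gene symbols; at least one
#'   must be present in `norm`.
#' @param n_bins number of expression bins (>= 2; default 25).
#' @param n_ctrl control genes sampled per program gene (default 50).
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 25, n_ctrl = 50, seed = 1L) {
  stopifnot(n_bins >= 2, n_ctrl >= 1)
  if (is.null(rownames(norm))) abort("norm must carry gene symbols as rownames")
  present <- intersect(gene_set, rownames(norm))
  if (length(present) == 0) {
    abort(paste0("no gene-set member present in the matrix; missing: ",
                 paste(head(gene_set, 10), collapse = ", ")))
  }
  avg <- Matrix::rowMeans(norm)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- rownames(norm)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ctrl <- unlist(lapply(present, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    sample(pool, min(n_ctrl, length(pool)),
           replace = length(pool) < n_ctrl)
  }), use.names = FALSE)

  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

#' Assign a cell-cycle phase from signed module scores
#'
#' A cell is quiescent (`G1`) iff both its S score and its G2/M score are
#' negative; otherwise it is proliferative and assigned `G2M` if the G2/M
#' score exceeds the S score, `S` if the S score exceeds the G2/M score.
#' An exact non-negative tie goes to `G2M` (the G2/M condition is tested
#' first); override with `tie`.
#'
#' @param s_score,g2m_score finite numeric vectors of equal length.
#' @param tie phase returned when `s_score == g2m_score >= 0`.
#' @return factor with levels `G1`, `S`, `G2M`.
#' @export
assign_phase <- function(s_score, g2m_score, tie = c("G2M", "S")) {
  tie <- match.arg(tie)
  stopifnot(length(s_score) == length(g2m_score))
  if (any(!is.finite(s_score)) || any(!is.finite(g2m_score))) {
    abort("phase assignment requires finite scores")
  }
  phase <- ifelse(s_score < 0 & g2m_score < 0, "G1",
           ifelse(g2m_score > s_score, "G2M",
           ifelse(s_score > g2m_score, "S", tie)))
  factor(phase, levels = c("G1", "S", "G2M"))
}

#' Score cells for S and G2/M programs and assign phases
#'
#' @param x a QC-filtered [sn_counts()].
#' @param s_genes,g2m_genes character vectors of S-phase and G2/M-phase gene
#'   symbols (typically 42 and 53 genes); must be disjoint and non-empty.
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @param scale_total passed to [log_normalize()].
#' @inheritParams assign_phase
#' @return tibble of class `sn_cycle`: `barcode`, `s_score`, `g2m_score`,
#'   `phase`.
#' @export
score_cell_cycle <- function(x, s_genes, g2m_genes, n_bins = 25, n_ctrl = 50,
                             seed = 1L, scale_total = 1e4, tie = c("G2M", "S")) {
  stopifnot(inherits(x, "sn_counts"),
            length(s_genes) > 0, length(g2m_genes) > 0)
  if (length(intersect(s_genes, g2m_genes)) > 0) {
    abort("S and G2/M gene sets must be disjoint")
  }
  norm <- log_normalize(x, scale_total)
  rownames(norm) <- x$genes$symbol
  s <- module_score(norm, s_genes, n_bins, n_ctrl, seed)
  g2m <- module_score(norm, g2m_genes, n_bins, n_ctrl, seed + 1L)
  res <- tibble(barcode = x$barcodes, s_score = unname(s),
                g2m_score = unname(g2m),
                phase = assign_phase(s, g2m, tie = tie))
  class(res) <- c("sn_cycle", class(res))
  res
}
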