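#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts panel genes among `n` draws without
#' replacement from a universe of `N` genes containing `K` panel genes.
#' Computed through `stats::phyper` (stable in log space internally).
#'
#' @param k observed overlap (vectorized).
#' @param K panel size within the universe.
#' @param n draw (marker list) size.
#' @param N universe size.
#' @return probability in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(n, K)
  if (any(bad)) {
    abort(sprintf("hypergeometric bounds violated (need 0 <= k <= min(n, K), K <= N, n <= N); first offender: k=%g K=%g n=%g N=%g",
                  k[bad][1], K[bad][1], n[bad][1], N[bad][1]))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# minimal common-length recycling for scalar-or-vector args
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else abort("arguments must be length 1 or a common length")
  })
}

#' Build the chromosome-21 gene panel from annotations
#'
#' @param genes gene annotation tibble with a `chromosome` column; labels
#'   `"chr21"` and `"21"` are accepted case-insensitively.
#' @return character vector of chr21 gene symbols.
#' @export
build_chr21_panel <- function(genes) {
  if (!"chromosome" %in% names(genes)) {
    abort("annotation has no chromosome column")
  }
  lab <- tolower(trimws(genes$chromosome))
  panel <- genes$symbol[lab %in% c("chr21", "21")]
  if (length(panel) == 0) {
    abort("no genes annotated to chromosome 21; supply a panel explicitly")
  }
  unique(panel)
}

#' Hypergeometric enrichment of cluster markers against gene panels
#'
#' One upper-tail hypergeometric test per (cluster, panel): does the
#' cluster's marker list overlap the panel more than a random draw of the
#' same size from the universe would? The universe defaults to the genes
#' that survived QC (markers can only come from tested genes). Marker
#' symbols outside the universe are dropped (reported via the `dropped`
#' attribute); panels are intersected with the universe.
#' Benjamini-Hochberg adjustment is applied jointly across all tests; raw p
#' values are also reported.
#'
#' @param markers an `sn_markers` tibble from [rank_markers()] or a named
#'   list of cluster -> marker symbol vectors.
#' @param panels named list of panel symbol vectors (e.g. from [read_gmt()]),
#'   or a single character vector (named `"panel"`).
#' @param universe character vector of background gene symbols; defaults to
#'   the `sn_markers` universe attribute.
#' @return tibble of class `sn_enrichment`, sorted by `p_adj`: `cluster`,
#'   `panel`, `N`, `K`, `n`, `k`, `p`, `p_adj`, `overlap` (list-column of
#'   overlap symbols).
#' @export
enrich_clusters <- function(markers, panels, universe = NULL) {
  if (inherits(markers, "sn_markers")) {
    universe <- universe %||% attr(markers, "universe")
    markers <- marker_lists(markers)
  }
  stopifnot(is.list(markers))
  if (is.character(panels)) panels <- list(panel = panels)
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    abort("panels must be named")
  }
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")

  dropped <- purrr::map(markers, ~ setdiff(.x, universe))
  markers <- purrr::map(markers, ~ intersect(unique(.x), universe))
  panels <- purrr::map(panels, ~ intersect(unique(.x), universe))

  grid <- tidyr::expand_grid(cluster = names(markers), panel = names(panels))
  res <- grid |>
    mutate(
      N = length(universe),
      K = map_int(.data$panel, ~ length(panels[[.x]])),
      n = map_int(.data$cluster, ~ length(markers[[.x]])),
      overlap = purrr::map2(.data$cluster, .data$panel,
                            ~ intersect(markers[[.x]], panels[[.y]])),
      k = lengths(.data$overlap)
    ) |>
    mutate(p = hypergeom_upper_tail(.data$k, .data$K, .data$n, .data$N),
           p_adj = p.adjust(.data$p, method = "BH")) |>
    select("cluster", "panel", "N", "K", "n", "k", "p", "p_adj", "overlap") |>
    arrange(.data$p_adj, .data$p)
  class(res) <- c("sn_enrichment", class(res))
  attr(res, "dropped") <- dropped
  res
}

#' Type-I calibration of the enrichment pipeline under shuffled labels
#'
#' Repeatedly permutes the cluster labels, re-derives markers with the same
#' vectorized rank-sum machinery as [rank_markers()] (gene ranks are computed
#' once, so each repetition costs one matrix product), runs the panel
#' enrichment, and reports the fraction of (cluster, panel) tests with raw
#' `p < alpha`. With no planted structure this should not exceed the nominal
#' rate beyond binomial noise.
#'
#' @param x an [sn_counts()] (typically a null simulation after QC).
#' @param labels tibble with `barcode`, `cluster`.
#' @param panels named list of panel symbol vectors.
#' @param n_reps number of label permutations (default 200).
#' @param alpha nominal level (default 0.05).
#' @param min_lfc,scale_total as in [rank_markers()].
#' @param seed RNG seed for the permutations.
#' @return list: `rejection_rate`, `n_tests`, `n_rejections`, `alpha`,
#'   `se` (binomial standard error at `alpha`), and the per-rep rejection
#'   counts.
#' @export
calibrate_enrichment_null <- function(x, labels, panels, n_reps = 200,
                                      alpha = 0.05, min_lfc = 0.25,
                                      scale_total = 1e4, seed = 1L) {
  stopifnot(inherits(x, "sn_counts"))
  labels <- as_tibble(labels)
  cl0 <- labels$cluster[match(x$barcodes, labels$barcode)]
  clusters <- sort(unique(cl0))
  universe <- unique(x$genes$symbol)
  panels <- purrr::map(panels, ~ intersect(unique(.x), universe))

  norm <- as.matrix(log_normalize(x, scale_total))
  ranks <- t(apply(norm, 1, rank, ties.method = "average"))
  n_tot <- ncol(norm)
  tie_term <- apply(norm, 1, function(v) {
    t3 <- tabulate(match(v, unique(v)))
    ((n_tot + 1) - sum(t3^3 - t3) / (n_tot * (n_tot - 1))) / 12
  })

  set.seed(as.integer(seed))
  panel_mask <- vapply(panels, function(p) x$genes$symbol %in% p,
                       logical(nrow(ranks)))
  per_rep <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cl <- sample(cl0)
    membership <- vapply(clusters, function(k) as.numeric(cl == k),
                         numeric(n_tot))
    pmat <- rank_sum_matrix(ranks, tie_term, membership)
    sizes <- colSums(membership)
    msum <- as.matrix(x$counts %*% membership)          # gene x cluster sums
    m_in <- sweep(msum, 2, sizes, `/`)
    m_out <- sweep(sweep(-msum, 1, Matrix::rowSums(x$counts), `+`),
                   2, n_tot - sizes, `/`)
    lfc <- log2((m_in + 1) / (m_out + 1))
    rej <- 0L
    for (j in seq_along(clusters)) {
      padj <- p.adjust(pmat[, j], method = "BH")
      mk <- padj < alpha & lfc[, j] > min_lfc
      n_mk <- sum(mk)
      for (pn in seq_along(panels)) {
        k <- sum(mk & panel_mask[, pn])
        p <- hypergeom_upper_tail(k, sum(panel_mask[, pn]), n_mk,
                                  length(universe))
        if (p < alpha) rej <- rej + 1L
      }
    }
    per_rep[r] <- rej
  }
  n_tests <- n_reps * length(clusters) * length(panels)
  rate <- sum(per_rep) / n_tests
  list(rejection_rate = rate, n_tests = n_tests,
       n_rejections = sum(per_rep), alpha = alpha,
       se = sqrt(alpha * (1 - alpha) / n_tests), per_rep = per_rep)
}
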