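#' Pipeline configuration
#'
#' Orchestrates simulate (optional) -> qc -> cellcycle -> profile -> markers
#' -> commnet -> enrich -> corrnet with one explicit seed. Every stage seed
#' is derived as `seed * 97 + stage_index`, so each stage is independently
#' reproducible.
#'
#' @param out_dir output directory (created; one subdirectory per stage).
#' @param seed single integer master seed.
#' @param simulate a [sim_config()] to generate the input, or `NULL` to read
#'   an existing matrix.
#' @param matrix_dir 10x-convention input directory (required when
#'   `simulate` is `NULL`).
#' @param labels_file two-column TSV (barcode, cluster) with a header
#'   (required when `simulate` is `NULL`; simulated runs use the ground-truth
#'   labels).
#' @param lr_pairs_file ligand-receptor CSV (see [read_lr_pairs()]); `NULL`
#'   with `simulate` uses the planted pairs.
#' @param panels_file GMT of enrichment panels; `NULL` uses the chr21 panel
#'   built from the gene annotations.
#' @param cycle_sets_file GMT with sets `S_PHASE` and `G2M_PHASE`; `NULL`
#'   with `simulate` draws synthetic 42- and 53-gene sets from the
#'   background genes.
#' @param housekeeping_file optional one-symbol-per-line text file for the
#'   QC reliability report.
#' @param qc a [qc_params()].
#' @param comm_threshold mean-UMI expression threshold (default 1).
#' @param marker_alpha,marker_min_lfc marker thresholds (defaults 0.05, 0.25).
#' @param pool_size,r_threshold correlation-network parameters (30, 0.95).
#' @param scale_total log-normalization scale (1e4).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            simulate = sim_config(seed = seed),
                            matrix_dir = NULL,
                            labels_file = NULL,
                            lr_pairs_file = NULL,
                            panels_file = NULL,
                            cycle_sets_file = NULL,
                            housekeeping_file = NULL,
                            qc = qc_params(),
                            comm_threshold = 1,
                            marker_alpha = 0.05,
                            marker_min_lfc = 0.25,
                            pool_size = 30,
                            r_threshold = 0.95,
                            scale_total = 1e4) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    abort("pipeline_config: seed must be a single explicit integer")
  }
  if (is.null(cfg$simulate)) {
    for (f in c("matrix_dir", "labels_file")) {
      if (is.null(cfg[[f]])) {
        abort(sprintf("pipeline_config: '%s' is required when not simulating", f))
      }
    }
  }
  paths <- c(cfg$matrix_dir, cfg$labels_file, cfg$lr_pairs_file,
             cfg$panels_file, cfg$cycle_sets_file, cfg$housekeeping_file)
  absent <- if (length(paths) > 0) paths[!file.exists(paths)] else character(0)
  if (length(absent) > 0) {
    abort(paste0("pipeline_config references missing path(s): ",
                 paste(absent, collapse = ", ")))
  }
  if (!inherits(cfg$qc, "qc_params")) cfg$qc <- do.call(qc_params, cfg$qc)
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "sim_config")) {
    cfg$simulate <- do.call(sim_config, cfg$simulate)
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `simulate`
#' and `qc` are nested maps of their constructors' arguments.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: '%s'", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$qc)) y$qc <- do.call(qc_params, y$qc)
  do.call(pipeline_config, y)
}

sub_seed <- function(seed, k) as.integer(seed) * 97L + as.integer(k)

write_tsv_plain <- function(d, path) {
  d <- as.data.frame(purrr::map(d, function(col) {
    if (is.list(col)) map_chr(col, paste, collapse = ";") else col
  }))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order, writes each stage's tables under
#' `out_dir/<stage>/`, and finishes with `manifest.json` recording every
#' file's MD5 hash, the parameters, and per-stage row counts. A stage
#' failure aborts the run with the failing stage recorded in the manifest.
#' Reruns with an identical configuration produce byte-identical outputs
#' (the manifest carries no timestamps).
#'
#' @param cfg a [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(), files = list())
  files <- character(0)
  note <- function(stage, ...) {
    p <- unlist(list(...))
    files <<- c(files, p)
    p
  }
  current_stage <- "init"
  root <- normalizePath(cfg$out_dir)
  finish_manifest <- function(status, failed_stage = NULL) {
    manifest$status <<- status
    if (!is.null(failed_stage)) manifest$failed_stage <<- failed_stage
    rel <- vapply(files, function(p) {
      p <- normalizePath(p)
      if (startsWith(p, root)) substring(p, nchar(root) + 2L) else p
    }, character(1), USE.NAMES = FALSE)
    manifest$files <<- setNames(purrr::map2(files, rel, function(p, r) {
      list(path = r, md5 = unname(tools::md5sum(p)))
    }), rel)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }

  res <- tryCatch({
    # --- simulate / load -------------------------------------------------
    current_stage <- "simulate"
    if (!is.null(cfg$simulate)) {
      sim <- generate_counts(cfg$simulate)
      x <- sim$counts
      labels <- sim$truth$cells[, c("barcode", "cluster")]
      d <- file.path(cfg$out_dir, "simulate")
      dir.create(d, showWarnings = FALSE)
      note("simulate", write_10x(x, d))
      note("simulate", write_tsv_plain(sim$truth$cells, file.path(d, "truth_cells.tsv")))
      note("simulate", write_tsv_plain(sim$truth$comm_edges, file.path(d, "truth_comm_edges.tsv")))
      note("simulate", write_gmt(c(sim$truth$markers,
                                   list(chr21 = sim$truth$chr21_genes)),
                                 file.path(d, "truth_gene_sets.gmt")))
      pairs <- if (!is.null(cfg$lr_pairs_file)) read_lr_pairs(cfg$lr_pairs_file) else
        lr_pair_table(sim$truth$comm_edges[, c("ligand", "receptor")])
      manifest$stages$simulate <- list(n_genes = nrow(x$counts),
                                       n_cells = ncol(x$counts))
    } else {
      x <- read_10x(cfg$matrix_dir)
      lab_raw <- utils::read.table(cfg$labels_file, sep = "\t", header = TRUE,
                                   colClasses = "character")
      labels <- tibble(barcode = lab_raw[[1]], cluster = lab_raw[[2]])
      pairs <- read_lr_pairs(cfg$lr_pairs_file)
      sim <- NULL
    }

    # --- qc --------------------------------------------------------------
    current_stage <- "qc"
    housekeeping <- if (!is.null(cfg$housekeeping_file)) {
      readLines(cfg$housekeeping_file)
    } else NULL
    qc <- apply_qc(x, cfg$qc, housekeeping)
    xq <- qc$filtered
    labels_q <- filter(labels, .data$barcode %in% xq$barcodes)
    d <- file.path(cfg$out_dir, "qc")
    dir.create(d, showWarnings = FALSE)
    note("qc", write_10x(xq, d))
    note("qc", write_tsv_plain(qc$cells, file.path(d, "qc_cells.tsv")))
    note("qc", write_tsv_plain(qc$genes, file.path(d, "qc_genes.tsv")))
    summ <- c(as.list(qc$summary), qc$bounds,
              list(housekeeping_rate = if (is.null(qc$housekeeping)) NA else
                qc$housekeeping$rate))
    jsonlite::write_json(summ, file.path(d, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("qc", file.path(d, "qc_summary.json"))
    manifest$stages$qc <- qc$summary

    # --- cellcycle -------------------------------------------------------
    current_stage <- "cellcycle"
    if (!is.null(cfg$cycle_sets_file)) {
      sets <- read_gmt(cfg$cycle_sets_file)
      s_genes <- sets[["S_PHASE"]]; g2m_genes <- sets[["G2M_PHASE"]]
    } else if (!is.null(sim)) {
      pool <- setdiff(xq$genes$symbol,
                      c(unlist(sim$truth$markers), sim$truth$chr21_genes,
                        pairs$ligand, pairs$receptor))
      set.seed(sub_seed(cfg$seed, 1L))
      picked <- sample(pool, 42L + 53L)
      s_genes <- picked[1:42]; g2m_genes <- picked[43:95]
    } else {
      sets <- cycle_gene_sets()
      s_genes <- sets$s; g2m_genes <- sets$g2m
    }
    cyc <- score_cell_cycle(xq, s_genes, g2m_genes,
                            seed = sub_seed(cfg$seed, 2L),
                            scale_total = cfg$scale_total)
    d <- file.path(cfg$out_dir, "cellcycle")
    dir.create(d, showWarnings = FALSE)
    note("cellcycle", write_tsv_plain(cyc, file.path(d, "cycle_scores.tsv")))
    manifest$stages$cellcycle <- as.list(table(cyc$phase))

    # --- profile ---------------------------------------------------------
    current_stage <- "profile"
    ce <- cluster_mean_expression(xq, labels_q)
    d <- file.path(cfg$out_dir, "profile")
    dir.create(d, showWarnings = FALSE)
    means_tbl <- as_tibble(as.data.frame(ce$means), rownames = "cluster")
    note("profile", write_tsv_plain(means_tbl, file.path(d, "cluster_means.tsv")))
    manifest$stages$profile <- list(n_clusters = nrow(ce$means))

    # --- markers ---------------------------------------------------------
    current_stage <- "markers"
    mk <- rank_markers(xq, labels_q, min_lfc = cfg$marker_min_lfc,
                       alpha = cfg$marker_alpha,
                       scale_total = cfg$scale_total)
    d <- file.path(cfg$out_dir, "markers")
    dir.create(d, showWarnings = FALSE)
    note("markers", write_tsv_plain(mk, file.path(d, "markers.tsv")))
    manifest$stages$markers <- list(n_markers = sum(mk$is_marker))

    # --- commnet ---------------------------------------------------------
    current_stage <- "commnet"
    comm <- comm_network(xq, labels_q, pairs, threshold = cfg$comm_threshold)
    d <- file.path(cfg$out_dir, "commnet")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(comm$edges, file.path(d, "edges.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(comm$pair_counts),
                     file.path(d, "pair_counts.csv"))
    note("commnet", file.path(d, c("edges.csv", "pair_counts.csv")))
    note("commnet", write_tsv_plain(comm$cluster_summary,
                                    file.path(d, "cluster_summary.tsv")))
    manifest$stages$commnet <- list(n_edges = nrow(comm$edges))

    # --- enrich ----------------------------------------------------------
    current_stage <- "enrich"
    panels <- if (!is.null(cfg$panels_file)) read_gmt(cfg$panels_file) else
      list(chr21 = build_chr21_panel(xq$genes))
    enr <- enrich_clusters(mk, panels)
    d <- file.path(cfg$out_dir, "enrich")
    dir.create(d, showWarnings = FALSE)
    note("enrich", write_tsv_plain(enr, file.path(d, "enrichment.tsv")))
    manifest$stages$enrich <- list(n_tests = nrow(enr),
                                   n_significant = sum(enr$p_adj < 0.05))

    # --- corrnet ---------------------------------------------------------
    current_stage <- "corrnet"
    pools <- pool_cells(xq, labels_q, pool_size = cfg$pool_size,
                        seed = sub_seed(cfg$seed, 3L),
                        scale_total = cfg$scale_total)
    net <- correlation_edges(pools, r_threshold = cfg$r_threshold)
    d <- file.path(cfg$out_dir, "corrnet")
    note("corrnet", export_network(net, d))
    manifest$stages$corrnet <- list(n_pools = nrow(net$nodes),
                                    n_edges = nrow(net$edges))

    finish_manifest("ok")
  }, error = function(e) {
    finish_manifest("failed", failed_stage = current_stage)
    abort(sprintf("pipeline stage '%s' failed: %s", current_stage,
                  conditionMessage(e)), parent = e)
  })
  invisible(res)
}
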