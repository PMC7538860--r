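test_that("gene annotations honour configured counts and labels", {
  cfg <- small_cfg(n_genes = 100, n_mito_genes = 5, frac_chr21_genes = 0)
  ann <- generate_gene_annotations(cfg)
  expect_equal(nrow(ann), 100)
  expect_equal(sum(ann$mito), 5)
  expect_true(all(startsWith(ann$symbol[ann$mito], "MT-")))
  expect_false(anyDuplicated(ann$gene_id) > 0)

  cfg2 <- small_cfg(n_genes = 200, frac_chr21_genes = 0.1)
  ann2 <- generate_gene_annotations(cfg2)
  expect_equal(sum(ann2$chromosome == "chr21"), 20)
  # chr21 goes to the lexicographically first eligible non-mito symbols
  eligible <- sort(ann2$symbol[!ann2$mito])
  expect_setequal(ann2$symbol[ann2$chromosome == "chr21"], eligible[1:20])
})

test_that("identical config and seed give identical data and ground truth", {
  cfg <- small_cfg(seed = 7, dosage_cluster = "C1", dosage_fold = 1.5)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth, b$truth)
  ann <- generate_gene_annotations(cfg)
  expect_identical(ann, generate_gene_annotations(cfg))
})

test_that("planted effects appear in the counts by construction", {
  cfg <- sim_config(n_clusters = 3, cells_per_cluster = 500, n_genes = 300,
                    n_mito_genes = 5, mito_mean_fold = 2,
                    frac_chr21_genes = 0.1, dosage_cluster = "C2",
                    dosage_fold = 1.5, debris_frac = 0, seed = 3)
  sim <- generate_counts(cfg)
  x <- sim$counts
  chr21 <- x$genes$symbol %in% sim$truth$chr21_genes
  cl <- sim$truth$cells$cluster
  in_mean <- mean(as.matrix(x$counts[chr21, cl == "C2"]))
  out_mean <- mean(as.matrix(x$counts[chr21, cl != "C2"]))
  expect_gt(in_mean / out_mean, 1.3)
  expect_lt(in_mean / out_mean, 1.7)

  # planted ligand/receptor cluster means clear the UMI threshold of 1
  pairs <- sim$truth$comm_edges
  for (i in seq_len(nrow(pairs))) {
    lig_row <- x$genes$symbol == pairs$ligand[i]
    rec_row <- x$genes$symbol == pairs$receptor[i]
    expect_gt(mean(x$counts[lig_row, cl == pairs$source[i]]), 1)
    expect_gt(mean(x$counts[rec_row, cl == pairs$target[i]]), 1)
  }
})

test_that("large dispersion approaches the Poisson variance-mean ratio", {
  cfg <- sim_config(n_clusters = 1, cells_per_cluster = 2000, n_genes = 200,
                    n_mito_genes = 0, nb_dispersion = 1e6, libsize_sigma = 0,
                    debris_frac = 0, frac_chr21_genes = 0, lr_pairs = no_lr(),
                    seed = 4)
  sim <- generate_counts(cfg)
  m <- as.matrix(sim$counts$counts)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(small_cfg(n_mito_genes = 300), "n_mito_genes")
  expect_error(small_cfg(dosage_fold = 0.5), "dosage_fold")
  expect_error(small_cfg(frac_chr21_genes = 1.2), "frac_chr21_genes")
  expect_error(small_cfg(dosage_cluster = "C99"), "dosage_cluster")
  expect_error(
    small_cfg(lr_pairs = data.frame(ligand = "NOPE", receptor = "ALSO_NO",
                                    source = "C0", target = "C1")),
    "lr_pairs")
  # pair genes colliding with the mito block are a configuration error
  cfg <- small_cfg()
  mito_sym <- generate_gene_annotations(cfg)$symbol[1]
  mito_sym <- grep("^MT-", generate_gene_annotations(cfg)$symbol, value = TRUE)[1]
  expect_error(
    small_cfg(lr_pairs = data.frame(ligand = mito_sym, receptor = mito_sym,
                                    source = "C0", target = "C1")),
    "mito")
})

test_that("10x fixture writing round-trips exactly through the reader", {
  cfg <- small_cfg(seed = 2)
  sim <- generate_counts(cfg)
  d <- withr::local_tempdir()
  write_10x(sim$counts, d)
  expect_true(all(file.exists(file.path(d, c("matrix.mtx", "features.tsv",
                                             "barcodes.tsv")))))
  back <- read_10x(d)
  expect_identical(as.matrix(back$counts), as.matrix(sim$counts$counts))
  expect_identical(back$genes, sim$counts$genes)
  expect_identical(back$barcodes, sim$counts$barcodes)
})

test_that("MatrixMarket header declares genes, cells and nonzeros", {
  m <- matrix(0, 3, 2)
  m[1, 1] <- 1; m[2, 1] <- 2; m[3, 2] <- 1; m[1, 2] <- 4
  x <- tiny_sn(m)
  d <- withr::local_tempdir()
  write_10x(x, d)
  lines <- readLines(file.path(d, "matrix.mtx"))
  dims <- lines[!startsWith(lines, "%")][1]
  expect_equal(scan(text = dims, quiet = TRUE), c(3, 2, 4))
})

test_that("the reader rejects malformed or inconsistent fixtures", {
  cfg <- small_cfg(seed = 2)
  sim <- generate_counts(cfg)
  d <- withr::local_tempdir()
  write_10x(sim$counts, d)

  # truncated matrix body
  lines <- readLines(file.path(d, "matrix.mtx"))
  writeLines(head(lines, length(lines) - 5), file.path(d, "matrix.mtx"))
  expect_error(read_10x(d), "matrix.mtx")

  # sidecar dimension mismatch
  write_10x(sim$counts, d)
  bc <- readLines(file.path(d, "barcodes.tsv"))
  writeLines(head(bc, -3), file.path(d, "barcodes.tsv"))
  expect_error(read_10x(d), "mismatch")

  # features file without a chromosome column degrades with a warning
  write_10x(sim$counts, d)
  feat <- read.table(file.path(d, "features.tsv"), sep = "\t")
  write.table(feat[, 1:2], file.path(d, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_warning(back <- read_10x(d), "chromosome")
  expect_true(all(back$genes$chromosome == "unknown"))
})
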