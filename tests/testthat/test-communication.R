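# brute-force oracle: exhaustive triple loop over pairs and cluster pairs
brute_force_edges <- function(means, pairs, threshold = 1) {
  out <- list()
  clusters <- rownames(means)
  for (i in seq_len(nrow(pairs))) {
    L <- pairs$ligand[i]; R <- pairs$receptor[i]
    if (!(L %in% colnames(means)) || !(R %in% colnames(means))) next
    for (a in clusters) for (b in clusters) {
      if (means[a, L] > threshold && means[b, R] > threshold) {
        out[[length(out) + 1]] <- data.frame(source = a, target = b,
                                             ligand = L, receptor = R)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(source = character(), target = character(),
                      ligand = character(), receptor = character()))
  }
  do.call(rbind, out)
}

fake_ce <- function(means) {
  structure(list(means = means,
                 sizes = setNames(rep(1, nrow(means)), rownames(means)),
                 genes = tibble::tibble(gene_id = colnames(means),
                                        symbol = colnames(means),
                                        chromosome = "chr1", mito = FALSE)),
            class = "sn_cluster_expr")
}

test_that("expression thresholding is strict with an inclusive override", {
  means <- rbind(A = c(L1 = 1.5, R1 = 1.0), B = c(L1 = 0.2, R1 = 2))
  ce <- fake_ce(means)
  pairs <- tibble::tibble(ligand = "L1", receptor = "R1")
  ex <- expressed_molecules(ce, pairs, threshold = 1)
  expect_equal(ex$A$ligands, "L1")
  expect_equal(ex$A$receptors, character(0))   # exactly 1.0 is not "above"
  expect_equal(ex$B$receptors, "R1")
  ex_inc <- expressed_molecules(ce, pairs, threshold = 1, inclusive = TRUE)
  expect_equal(ex_inc$A$receptors, "R1")

  # empty pair table gives empty sets and no edges
  empty <- tibble::tibble(ligand = character(), receptor = character())
  ex0 <- expressed_molecules(ce, empty)
  expect_equal(lengths(purrr::map(ex0, "ligands")), c(A = 0L, B = 0L))
  expect_equal(nrow(build_comm_edges(ex0, empty)), 0)

  # symbols outside the universe are skipped and reported
  pairs2 <- tibble::tibble(ligand = c("L1", "GHOST"), receptor = c("R1", "R1"))
  ex2 <- expressed_molecules(ce, pairs2)
  expect_equal(attr(ex2, "skipped"), "GHOST")
})

test_that("the two-cluster worked example matches the hand enumeration", {
  means <- rbind(A = c(L1 = 2, R1 = 3), B = c(L1 = 0.5, R1 = 2))
  ce <- fake_ce(means)
  pairs <- tibble::tibble(ligand = "L1", receptor = "R1")
  ex <- expressed_molecules(ce, pairs)
  edges <- build_comm_edges(ex, pairs)
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$source, edges$target), c("A A", "A B"))
  s <- summarize_network(edges, ex)
  expect_equal(unname(s$pair_counts), rbind(c(1, 1), c(0, 0)))
  expect_equal(sum(s$pair_counts), nrow(edges))
  expect_equal(s$cluster_summary$n_ligands, c(1, 0))
  expect_equal(s$cluster_summary$n_receptors, c(1, 1))
})

test_that("edge sets equal exhaustive enumeration on random instances", {
  set.seed(41)
  for (rep in 1:25) {
    n_cl <- sample(2:5, 1)
    n_genes <- sample(4:12, 1)
    genes <- paste0("g", seq_len(n_genes))
    means <- matrix(runif(n_cl * n_genes, 0, 2), n_cl,
                    dimnames = list(paste0("K", seq_len(n_cl)), genes))
    n_pairs <- sample(1:8, 1)
    pairs <- unique(tibble::tibble(ligand = sample(genes, n_pairs, TRUE),
                                   receptor = sample(genes, n_pairs, TRUE)))
    ce <- fake_ce(means)
    got <- build_comm_edges(expressed_molecules(ce, pairs), pairs)
    ref <- brute_force_edges(means, pairs)
    expect_equal(nrow(got), nrow(ref))
    expect_setequal(paste(got$source, got$target, got$ligand, got$receptor),
                    paste(ref$source, ref$target, ref$ligand, ref$receptor))
  }
})

test_that("lowering the threshold never removes an edge; high threshold empties", {
  set.seed(42)
  means <- matrix(runif(4 * 8, 0, 2), 4,
                  dimnames = list(paste0("K", 1:4), paste0("g", 1:8)))
  pairs <- tibble::tibble(ligand = paste0("g", 1:4),
                          receptor = paste0("g", 5:8))
  ce <- fake_ce(means)
  key <- function(th) {
    e <- build_comm_edges(expressed_molecules(ce, pairs, th), pairs)
    paste(e$source, e$target, e$ligand, e$receptor)
  }
  expect_true(all(key(1.0) %in% key(0.5)))
  expect_true(all(key(0.5) %in% key(0.1)))
  expect_equal(length(key(max(means) + 1)), 0)
})

test_that("self-communication is kept by default and removable", {
  cfg <- small_cfg(seed = 15)
  sim <- generate_counts(cfg)
  comm <- comm_network(sim$counts, labels_of(sim),
                       sim$truth$comm_edges[, c("ligand", "receptor")])
  planted <- sim$truth$comm_edges
  hit <- dplyr::inner_join(planted, comm$edges,
                           by = c("source", "target", "ligand", "receptor"))
  expect_equal(nrow(hit), nrow(planted))

  no_self <- comm_network(sim$counts, labels_of(sim),
                          sim$truth$comm_edges[, c("ligand", "receptor")],
                          self_edges = FALSE)
  expect_true(all(no_self$edges$source != no_self$edges$target))
})
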