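# naive two-pass Pearson oracle
two_pass_r <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

test_that("pooling partitions clusters into fixed-size groups", {
  set.seed(3)
  m <- matrix(rpois(40 * 100, 3), nrow = 40)
  x <- tiny_sn(m)
  lab <- tibble::tibble(barcode = x$barcodes,
                        cluster = c(rep("A", 65), rep("B", 35)))
  pools <- pool_cells(x, lab, pool_size = 30, seed = 2)
  expect_equal(nrow(pools$profiles), 3)        # A: 2 pools (5 dropped), B: 1
  expect_equal(sum(pools$meta$cluster == "A"), 2)
  members <- unlist(pools$meta$members)
  expect_false(any(duplicated(members)))       # each cell in at most one pool
  expect_true(all(lengths(pools$meta$members) == 30))

  # determinism
  pools2 <- pool_cells(x, lab, pool_size = 30, seed = 2)
  expect_identical(pools$meta$members, pools2$meta$members)

  # undersized cluster contributes nothing, with a warning
  lab3 <- tibble::tibble(barcode = x$barcodes,
                         cluster = c(rep("A", 90), rep("tiny", 10)))
  expect_warning(p3 <- pool_cells(x, lab3, pool_size = 30, seed = 2), "tiny")
  expect_false("tiny" %in% p3$meta$cluster)
})

test_that("a pool of identical cells reproduces any member's profile", {
  m <- matrix(rep(c(2, 0, 5, 1), 30), nrow = 4)
  x <- tiny_sn(m)
  lab <- tibble::tibble(barcode = x$barcodes, cluster = "A")
  pools <- pool_cells(x, lab, pool_size = 30, seed = 1)
  norm <- log_normalize(x)
  expect_equal(unname(pools$profiles[1, ]), unname(norm[, 1]))
})

test_that("correlation edges follow the strict threshold rule", {
  prof <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 2, 3, 4),
                p3 = -c(1, 2, 3, 4) + 5)
  pools <- structure(list(
    profiles = prof,
    meta = tibble::tibble(pool_id = rownames(prof), cluster = "A",
                          n_cells = 2, members = list("a", "b", "c"))),
    class = "sn_pools")
  net <- correlation_edges(pools, r_threshold = 0.95)
  expect_equal(nrow(net$edges), 1)             # only the identical pair
  expect_equal(net$edges$r, 1)
  expect_equal(net$cor_matrix["p1", "p3"], -1) # negation: no edge

  # zero-variance profiles are excluded with a warning
  prof2 <- rbind(prof, p4 = c(2, 2, 2, 2))
  pools2 <- structure(list(
    profiles = prof2,
    meta = tibble::tibble(pool_id = rownames(prof2), cluster = "A",
                          n_cells = 2, members = as.list(letters[1:4]))),
    class = "sn_pools")
  expect_warning(net2 <- correlation_edges(pools2), "zero-variance")
  expect_false("p4" %in% rownames(net2$cor_matrix))
})

test_that("Pearson values agree with a naive two-pass oracle", {
  set.seed(9)
  prof <- matrix(rnorm(8 * 50), nrow = 8,
                 dimnames = list(paste0("p", 1:8), NULL))
  pools <- structure(list(
    profiles = prof,
    meta = tibble::tibble(pool_id = rownames(prof), cluster = "A",
                          n_cells = 2, members = as.list(letters[1:8]))),
    class = "sn_pools")
  net <- correlation_edges(pools, r_threshold = -2)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(net$cor_matrix[i, j], two_pass_r(prof[i, ], prof[j, ]),
                 tolerance = 1e-12)
  }

  # r is invariant to an affine rescale applied identically to both profiles
  scaled <- sweep(sweep(prof, 2, runif(50, 0.5, 2), `*`), 2, rnorm(50), `+`)
  pools_s <- pools; pools_s$profiles <- scaled
  net_s <- correlation_edges(pools_s, r_threshold = -2)
  expect_equal(net_s$cor_matrix, cor(t(scaled)))
})

test_that("network export round-trips through GraphML and handles no edges", {
  set.seed(10)
  prof <- matrix(rnorm(5 * 30), nrow = 5,
                 dimnames = list(paste0("p", 1:5), NULL))
  prof[2, ] <- prof[1, ] + rnorm(30, sd = 0.01)   # one near-duplicate pair
  pools <- structure(list(
    profiles = prof,
    meta = tibble::tibble(pool_id = rownames(prof),
                          cluster = c("A", "A", "B", "B", "B"),
                          n_cells = 2, members = as.list(letters[1:5]))),
    class = "sn_pools")
  net <- correlation_edges(pools, r_threshold = 0.95)
  expect_gte(nrow(net$edges), 1)
  d <- withr::local_tempdir()
  export_network(net, d)
  g <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  got <- igraph::as_data_frame(g, what = "edges")
  expect_setequal(paste(pmin(got$from, got$to), pmax(got$from, got$to)),
                  paste(pmin(net$edges$pool_i, net$edges$pool_j),
                        pmax(net$edges$pool_i, net$edges$pool_j)))

  # empty edge list still writes valid files
  net0 <- correlation_edges(pools, r_threshold = 1)
  expect_equal(nrow(net0$edges), 0)
  d0 <- withr::local_tempdir()
  export_network(net0, d0)
  expect_equal(nrow(read.csv(file.path(d0, "edges.csv"))), 0)
  expect_equal(nrow(read.csv(file.path(d0, "nodes.csv"))), 5)
  g0 <- igraph::read_graph(file.path(d0, "network.graphml"),
                           format = "graphml")
  expect_equal(igraph::ecount(g0), 0)
})

test_that("within-cluster pools correlate higher than between-cluster pools", {
  cfg <- small_cfg(seed = 18)
  sim <- generate_counts(cfg)
  pools <- pool_cells(sim$counts, labels_of(sim), pool_size = 20, seed = 4)
  cm <- correlation_edges(pools, r_threshold = -2)$cor_matrix
  same <- outer(pools$meta$cluster, pools$meta$cluster, `==`)
  ut <- upper.tri(cm)
  expect_gt(median(cm[ut & same]), median(cm[ut & !same]))
})
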