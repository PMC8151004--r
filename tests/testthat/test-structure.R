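test_that("duplicate documents merge first at height zero", {
  set.seed(3)
  m <- matrix(runif(14), 7, 2)
  m[2, ] <- m[5, ]  # exact duplicates
  D <- pairwise_distances(m)
  for (lk in c("average", "complete", "ward")) {
    hc <- hierarchical_cluster(D, linkage = lk)
    expect_equal(hc$height[1], 0)
    expect_setequal(abs(hc$merge[1, ]), c(2, 5))
  }
  expect_error(hierarchical_cluster(D, linkage = "single"))
})

test_that("the closest pair merges first, and average linkage matches a naive oracle", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  for (lk in c("average", "complete", "ward")) {
    hc <- hierarchical_cluster(D, linkage = lk)
    expect_setequal(abs(hc$merge[1, ]), c(1, 2))  # the distance-1 pair
  }

  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(runif(24), 8, 3)
    D8 <- pairwise_distances(m)
    hc <- hierarchical_cluster(D8, linkage = "average")
    expect_equal(hc$height, oracle_average_linkage_heights(unname(D8)),
                 tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
    expect_equal(nrow(hc$merge), 7)              # n - 1 merges
  }
})

test_that("MDS reproduces exactly embeddable configurations", {
  # any triangle embeds exactly: sides 3, 4, 5
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)
  emb <- mds_embed(D, seed = 1)
  got <- as.matrix(stats::dist(cbind(emb$x, emb$y)))
  expect_equal(unname(got), unname(D), tolerance = 1e-6)
  expect_lt(attr(emb, "stress"), 1e-6)

  # planar point sets are recovered up to rigid motion
  set.seed(21)
  pts <- matrix(rnorm(20), 10, 2)
  Dp <- pairwise_distances(pts)
  for (method in c("stress", "classical")) {
    e <- mds_embed(Dp, seed = 2, method = method)
    expect_lt(attr(e, "stress"), 1e-6)
    expect_equal(unname(as.matrix(stats::dist(cbind(e$x, e$y)))),
                 unname(Dp), tolerance = 1e-5)
  }
})

test_that("non-planar distances leave strictly positive stress", {
  # regular tetrahedron: all pairwise distances 1
  D <- matrix(1, 4, 4) - diag(4)
  emb <- mds_embed(D, seed = 3, n_init = 8)
  expect_gt(attr(emb, "stress"), 1e-4)
})

test_that("degenerate all-zero distances embed at the origin with zero stress", {
  Z <- matrix(0, 4, 4)
  emb <- mds_embed(Z, seed = 1)
  expect_equal(emb$x, rep(0, 4))
  expect_equal(attr(emb, "stress"), 0)
})

test_that("MDS is reproducible under a fixed seed and carries labels", {
  sim <- simulate_corpus(style_strength = 3, seed = 31)
  D <- pairwise_distances(ap_scores(sim$corpus))
  e1 <- mds_embed(D, seed = 10)
  e2 <- mds_embed(D, seed = 10)
  expect_equal(e1, e2)
  expect_true(all(c("textbook", "disease") %in% names(e1)))
})

test_that("the SVM boundary F1 reflects separability", {
  set.seed(12)
  blobs <- tibble::tibble(
    x = c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)),
    y = c(rnorm(20, 0, 0.3), rnorm(20, 0, 0.3)))
  labs <- rep(c("a", "b"), each = 20)
  f1 <- boundary_f1(blobs, labs)
  expect_equal(as.numeric(f1), 1)
  expect_s3_class(attr(f1, "boundary_grid"), "data.frame")

  # random labels on one blob at the coordinate scale of score embeddings
  # (pairwise distances ~0.3, where the fixed-gamma kernel cannot overfit):
  # F1 near the positive base rate
  rates <- vapply(1:5, function(s) {
    set.seed(s)
    one_blob <- tibble::tibble(x = rnorm(60, sd = 0.15),
                               y = rnorm(60, sd = 0.15))
    rl <- sample(rep(c("a", "b"), each = 30))
    as.numeric(boundary_f1(one_blob, rl))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.5), 0.15)

  # macro-F1 is invariant to swapping the class encoding
  set.seed(13)
  xy <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  labs2 <- rep(c(0, 1), 15)
  expect_equal(boundary_f1(xy, labs2, macro = TRUE),
               boundary_f1(xy, 1 - labs2, macro = TRUE))

  expect_error(boundary_f1(blobs, rep("a", 40)),
               class = "acustyle_input_error")
})

test_that("networks keep exactly the closest pairs and nest across sparsity", {
  sim <- simulate_corpus(seed = 17)
  D <- pairwise_distances(ap_scores(sim$corpus))
  n <- nrow(D)
  n_pairs <- choose(n, 2)

  full <- build_network(D, 1)
  expect_equal(nrow(full), n_pairs)

  single <- build_network(D, 1e-9)  # rounds to the single closest pair
  expect_equal(nrow(single), 1)
  cp_min <- which(D == min(D[upper.tri(D)]), arr.ind = TRUE)
  expect_equal(sort(c(single$from, single$to)),
               sort(rownames(D)[cp_min[1, ]]))

  edge_key <- function(net) paste(net$from, net$to)
  sweep_s <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1)
  nets <- lapply(sweep_s, build_network, D = D)
  for (k in seq_len(length(nets) - 1)) {
    expect_true(all(edge_key(nets[[k]]) %in% edge_key(nets[[k + 1]])))
    expect_equal(nrow(nets[[k]]), round(sweep_s[k] * n_pairs))
  }
  expect_error(build_network(D, 0), class = "acustyle_input_error")
  expect_error(build_network(D, 1.2), class = "acustyle_input_error")
})

test_that("within-group edge fractions match combinatorial expectations", {
  sim <- simulate_corpus(seed = 19)  # balanced 3 x 14 design
  D <- pairwise_distances(ap_scores(sim$corpus))
  full <- build_network(D, 1)
  # complete graph: 3 * C(14,2) same-textbook pairs of C(42,2)
  expect_equal(within_group_edge_fraction(full, "textbook"), 273 / 861)
  expect_equal(within_group_edge_fraction(full, "disease"),
               14 * choose(3, 2) / 861)

  # a network whose only edges join same-textbook documents
  lab <- attr(D, "doc_labels")
  same_tb <- build_network(D, 1)
  keep <- lab$textbook[match(same_tb$from, lab$doc_id)] ==
    lab$textbook[match(same_tb$to, lab$doc_id)]
  pruned <- same_tb[keep, ]
  attributes(pruned) <- c(attributes(pruned),
                          list(nodes = attr(same_tb, "nodes")))
  class(pruned) <- class(same_tb)
  expect_equal(within_group_edge_fraction(pruned, "textbook"), 1)

  sweep_res <- network_sweep(D)
  expect_named(sweep_res, c("sparsity", "n_edges", "textbook_fraction",
                            "disease_fraction"))
  expect_equal(nrow(sweep_res), 4)
})

test_that("a style-only corpus concentrates strict-sparsity edges within textbooks", {
  ok <- vapply(1:10, function(r) {
    sim <- simulate_corpus(style_strength = 2, seed = 400 + r)
    D <- pairwise_distances(ap_scores(sim$corpus))
    net <- build_network(D, 0.05)
    within_group_edge_fraction(net, "textbook") >
      within_group_edge_fraction(net, "disease")
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("network and embedding exports are readable", {
  sim <- simulate_corpus(seed = 23)
  D <- pairwise_distances(ap_scores(sim$corpus))
  net <- build_network(D, 0.1)
  csv <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, csv, graphml = gml)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(back, c("source", "target", "distance"))
  expect_equal(nrow(back), nrow(net))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net))
  expect_true("textbook" %in% igraph::vertex_attr_names(g))
})

test_that("plot builders return ggplot objects", {
  sim <- simulate_corpus(style_strength = 2, seed = 29)
  D <- pairwise_distances(ap_scores(sim$corpus))
  emb <- mds_embed(D, seed = 1)
  expect_s3_class(ggplot2::autoplot(emb), "ggplot")
  f1 <- boundary_f1(emb, emb$textbook == "TB1")
  expect_s3_class(ggplot2::autoplot(emb, boundary = f1), "ggplot")
  expect_s3_class(plot_network(build_network(D, 0.1)), "ggplot")
  expect_s3_class(plot_network_sweep(network_sweep(D)), "ggplot")
})
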