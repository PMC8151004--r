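#' Hierarchical clustering of documents
#'
#' Agglomerative clustering of the document distance matrix. Documents
#' with similar prescriptions merge early; the dendrogram shows whether
#' documents group by textbook (style) or by disease.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`
#'   (Ward's criterion on squared Euclidean distances, the only distance
#'   this package uses).
#' @return An object of class `hclust` (merge sequence, heights, leaf
#'   order), with the document labels carried over for plotting.
#' @export
hierarchical_cluster <- function(D, linkage = c("average", "complete",
                                                "ward")) {
  linkage <- match.arg(linkage)
  if (nrow(D) < 2) abort_input("Need at least two documents to cluster.")
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(stats::as.dist(D), method = method)
  hc$doc_labels <- attr(D, "doc_labels")
  hc
}

#' Metric multidimensional scaling to two dimensions
#'
#' Embeds the documents in the plane so that embedded pairwise distances
#' approximate the input distances. The default mode minimises raw
#' stress, sum over pairs of (d_ij - dhat_ij)^2, by SMACOF
#' majorisation, taking the best of `n_init` starts (the classical
#' eigendecomposition solution plus seeded random starts); `"classical"`
#' returns the eigendecomposition (principal-coordinates) solution
#' directly. Reported `stress` is normalised:
#' sqrt(raw stress / sum d_ij^2) (0 = perfect reconstruction).
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param seed Integer seed for the random restarts.
#' @param method `"stress"` (default) or `"classical"`.
#' @param n_init Number of starts for stress minimisation (default 8).
#' @param max_iter,tol SMACOF iteration controls.
#' @return A tibble with columns `doc_id`, `x`, `y` (plus `textbook`,
#'   `disease` when `D` carries labels); attributes `stress`, `seed`,
#'   `method`. Class `mds_embedding`.
#' @export
mds_embed <- function(D, seed = 1L, method = c("stress", "classical"),
                      n_init = 8, max_iter = 300, tol = 1e-10) {
  method <- match.arg(method)
  n <- nrow(D)
  if (n < 3) abort_input("Need at least three documents to embed.")
  if (!all(is.finite(D))) abort_input("Distances contain non-finite values.")
  denom <- sum(D^2) / 2
  if (denom == 0) {
    conf <- matrix(0, n, 2)
    stress <- 0
  } else if (method == "classical") {
    conf <- classical_start(D)
    stress <- norm_stress(D, conf, denom)
  } else {
    starts <- with_perm_seed(seed, {
      c(list(classical_start(D)),
        purrr::map(seq_len(max(0, n_init - 1)),
                   ~ matrix(stats::rnorm(n * 2), n, 2)))
    })
    fits <- purrr::map(starts, smacof_fit, D = D, max_iter = max_iter,
                       tol = tol)
    best <- which.min(purrr::map_dbl(fits, "raw_stress"))
    conf <- fits[[best]]$conf
    stress <- sqrt(fits[[best]]$raw_stress / denom)
  }
  lab <- attr(D, "doc_labels")
  out <- tibble::tibble(
    doc_id = rownames(D) %||% as.character(seq_len(n)),
    x = conf[, 1], y = conf[, 2])
  if (!is.null(lab)) out <- dplyr::left_join(out, lab, by = "doc_id")
  structure(out, stress = stress, seed = seed, method = method,
            class = c("mds_embedding", class(out)))
}

classical_start <- function(D) {
  conf <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 2))
  if (ncol(conf) < 2) conf <- cbind(conf, 0)[, 1:2, drop = FALSE]
  unname(conf)
}

## normalised stress sqrt(sum (d - dhat)^2 / sum d^2), sums over i<j
norm_stress <- function(D, conf, denom) {
  dhat <- as.matrix(stats::dist(conf))
  sqrt(sum((D - dhat)^2) / 2 / denom)
}

## one SMACOF run: monotone raw-stress decrease by Guttman transform
smacof_fit <- function(start, D, max_iter, tol) {
  n <- nrow(D)
  X <- start
  dhat <- as.matrix(stats::dist(X))
  raw <- sum((D - dhat)^2) / 2
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(dhat > 0, D / dhat, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    dhat_new <- as.matrix(stats::dist(X_new))
    raw_new <- sum((D - dhat_new)^2) / 2
    if (raw - raw_new < tol * max(raw, 1e-30)) {
      X <- X_new; dhat <- dhat_new; raw <- raw_new
      break
    }
    X <- X_new; dhat <- dhat_new; raw <- raw_new
  }
  list(conf = X, raw_stress = raw)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d documents, stress %.3g (%s)\n",
              nrow(x), attr(x, "stress"), attr(x, "method")))
  NextMethod()
}

#' Separability of a 2-D embedding by an RBF-SVM boundary
#'
#' Fits a support-vector classifier (radial-basis kernel, C = 10,
#' gamma = 1) to the embedded coordinates and returns the F1 score of
#' its predictions on those same points. This is the descriptive
#' separability of a decision boundary drawn through the embedding --
#' how cleanly two groups separate in the picture -- not a generalisation
#' estimate.
#'
#' @param embedding An `mds_embedding` (or data frame with `x`, `y`).
#' @param labels Vector with exactly two distinct values, aligned to the
#'   embedding rows.
#' @param positive Which label is the positive class for F1 (default:
#'   the second sorted level). `macro = TRUE` averages F1 over both
#'   classes instead.
#' @param macro Return macro-averaged F1 (invariant to relabeling).
#' @param grid_n Resolution of the exported decision-boundary grid.
#' @return The F1 score (single number) with the fitted grid in
#'   `attr(, "boundary_grid")`: a tibble `x`, `y`, `decision` sampling
#'   the classifier's decision values for contouring.
#' @export
boundary_f1 <- function(embedding, labels, positive = NULL,
                        macro = FALSE, grid_n = 60) {
  xy <- as.data.frame(embedding)[, c("x", "y")]
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    abort_input("`labels` must contain exactly two classes.")
  }
  fit <- e1071::svm(xy, labels, kernel = "radial", cost = 10, gamma = 1,
                    scale = FALSE)
  pred <- stats::predict(fit, xy)
  f1_one <- function(pos) {
    tp <- sum(pred == pos & labels == pos)
    fp <- sum(pred == pos & labels != pos)
    fn <- sum(pred != pos & labels == pos)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  f1 <- if (macro) {
    mean(vapply(levels(labels), f1_one, numeric(1)))
  } else {
    f1_one(positive %||% levels(labels)[2])
  }
  pad <- 0.05 * (max(xy$x) - min(xy$x) + max(xy$y) - min(xy$y) + 1e-9)
  grid <- tidyr::expand_grid(
    x = seq(min(xy$x) - pad, max(xy$x) + pad, length.out = grid_n),
    y = seq(min(xy$y) - pad, max(xy$y) + pad, length.out = grid_n))
  grid$decision <- as.numeric(attr(
    stats::predict(fit, grid, decision.values = TRUE), "decision.values"))
  structure(f1, boundary_grid = grid)
}

#' Document-similarity network at a sparsity level
#'
#' Builds an undirected network whose nodes are documents and whose
#' edges join the most similar document pairs: exactly
#' `round(sparsity * C(n,2))` edges, the pairs with the smallest
#' distances (ties at the cutoff broken by lexicographic index order).
#' Sweeping sparsity from strict to loose shows which group structure
#' (textbook or disease) survives the strictest thresholds.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param sparsity Fraction of all possible edges to retain, in (0, 1].
#' @return A `similarity_network`: a tibble of edges `from`, `to`,
#'   `distance`, with node metadata in `attr(, "nodes")` and the
#'   sparsity in `attr(, "sparsity")`.
#' @export
build_network <- function(D, sparsity) {
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      sparsity <= 0 || sparsity > 1) {
    abort_input("`sparsity` must be a single number in (0, 1].")
  }
  cp <- condensed_pairs(D)
  n_edges <- max(1L, round(sparsity * length(cp$d)))
  ord <- order(cp$d, cp$i, cp$j)
  keep <- ord[seq_len(n_edges)]
  ids <- rownames(D) %||% as.character(seq_len(cp$n))
  edges <- tibble::tibble(
    from = ids[cp$i[keep]], to = ids[cp$j[keep]],
    distance = cp$d[keep])
  nodes <- attr(D, "doc_labels") %||% tibble::tibble(doc_id = ids)
  structure(edges, nodes = nodes, sparsity = sparsity,
            class = c("similarity_network", class(edges)))
}

#' Fraction of network edges joining same-group documents
#'
#' Of the edges retained at a sparsity level, the fraction whose two
#' endpoint documents share the grouping label. At strict sparsity, a
#' high same-textbook fraction means style similarity dominates the
#' closest document pairs.
#'
#' @param net A `similarity_network` carrying node labels.
#' @param grouping `"textbook"` or `"disease"`.
#' @return A single number in \[0, 1\].
#' @export
within_group_edge_fraction <- function(net,
                                       grouping = c("textbook", "disease")) {
  grouping <- match.arg(grouping)
  nodes <- attr(net, "nodes")
  if (is.null(nodes) || !grouping %in% names(nodes)) {
    abort_input(sprintf("Network nodes carry no %s labels.", grouping))
  }
  g <- nodes[[grouping]][match(net$from, nodes$doc_id)]
  h <- nodes[[grouping]][match(net$to, nodes$doc_id)]
  mean(g == h)
}

#' Same-group edge retention across a sparsity sweep
#'
#' @param D Distance matrix with document labels.
#' @param sparsity_levels Sparsity fractions to sweep
#'   (default `c(0.02, 0.05, 0.10, 0.20)`).
#' @return A tibble `sparsity`, `n_edges`, `textbook_fraction`,
#'   `disease_fraction`.
#' @export
network_sweep <- function(D, sparsity_levels = c(0.02, 0.05, 0.10, 0.20)) {
  purrr::map(sparsity_levels, function(s) {
    net <- build_network(D, s)
    tibble::tibble(
      sparsity = s, n_edges = nrow(net),
      textbook_fraction = within_group_edge_fraction(net, "textbook"),
      disease_fraction = within_group_edge_fraction(net, "disease"))
  }) |> dplyr::bind_rows()
}

#' Export a similarity network
#'
#' Writes the edge list as CSV (`source`, `target`, `distance`) and, if
#' `graphml` is given, a GraphML file with textbook/disease node
#' attributes that opens in standard graph viewers.
#'
#' @param net A `similarity_network`.
#' @param path Edge-list CSV path.
#' @param graphml Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  readr::write_csv(
    tibble::tibble(source = net$from, target = net$to,
                   distance = net$distance), path)
  if (!is.null(graphml)) {
    nodes <- attr(net, "nodes")
    g <- igraph::graph_from_data_frame(
      as.data.frame(net[, c("from", "to", "distance")]),
      directed = FALSE, vertices = as.data.frame(nodes))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
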