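#' Run the full style-vs-disease analysis pipeline
#'
#' Executes every stage on one corpus -- scores, distances, the
#' similarity test suite, hierarchical clustering, MDS with boundary F1
#' scores, the network sparsity sweep, and the attribute attribution --
#' and writes all result tables plus a machine-readable JSON manifest
#' (configuration, seeds, corpus hash, and a content hash per output
#' file) to `out_dir`. Numeric outputs are a deterministic function of
#' the corpus and `config`. A failing stage raises a classed condition
#' naming the stage.
#'
#' @param corpus An `ap_corpus` (or a path to a corpus CSV).
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding pipeline defaults:
#'   `B` (permutation budget, default 1e5), `seed` (1), `sparsity_levels`
#'   (`c(0.02, 0.05, 0.1, 0.2)`), `linkage` (`"average"`),
#'   `n_trees` (500), `n_repeats` (50), `weighting` (`"multiplicity"`),
#'   `distant_mode` (`"region_heuristic"`), `attribute_table_path`
#'   (`"packaged"`), `mds_method` (`"stress"`), `importance`
#'   (`"impurity"`).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(corpus, out_dir, config = list()) {
  cfg <- utils::modifyList(list(
    B = 1e5, seed = 1L, sparsity_levels = c(0.02, 0.05, 0.1, 0.2),
    linkage = "average", n_trees = 500, n_repeats = 50,
    weighting = "multiplicity", distant_mode = "region_heuristic",
    attribute_table_path = "packaged", mds_method = "stress",
    importance = "impurity"), config)
  if (is.character(corpus)) corpus <- read_corpus(corpus, quiet = TRUE)
  stopifnot(inherits(corpus, "ap_corpus"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  table <- if (identical(cfg$attribute_table_path, "packaged")) {
    default_attribute_table()
  } else {
    read_attribute_table(cfg$attribute_table_path)
  }
  rule <- distant_rule(cfg$distant_mode)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "acustyle_stage_error", parent = e)
    })
  }

  scores <- stage("scores", ap_scores(corpus, weighting = cfg$weighting))
  attr_scores <- stage("attribute_scores",
                       attribute_scores(corpus, table = table, rule = rule,
                                        weighting = cfg$weighting))
  write_scores(scores, file.path(out_dir, "ap_scores.csv"),
               corpus = corpus)
  write_scores(attr_scores, file.path(out_dir, "attribute_scores.csv"),
               corpus = corpus, rule = rule)

  D <- stage("distances", pairwise_distances(scores))

  suite <- stage("permtest",
                 run_similarity_suite(corpus, B = cfg$B, seed = cfg$seed,
                                      weighting = cfg$weighting))
  write_suite(suite, file.path(out_dir, "similarity_suite.csv"),
              corpus = corpus, seed = cfg$seed)

  hc <- stage("cluster", hierarchical_cluster(D, linkage = cfg$linkage))
  merges <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    member_a = hc$merge[, 1], member_b = hc$merge[, 2],
    height = hc$height)
  readr::write_csv(merges, file.path(out_dir, "cluster_merges.csv"))

  emb <- stage("embed", mds_embed(D, seed = cfg$seed,
                                  method = cfg$mds_method))
  emb_out <- tibble::as_tibble(emb)
  emb_out$textbook_f1 <- NA_real_
  f1 <- if (dplyr::n_distinct(emb$textbook) == 2) {
    as.numeric(boundary_f1(emb, emb$textbook))
  } else NA_real_
  readr::write_csv(
    dplyr::select(emb_out, "doc_id", "x", "y",
                  dplyr::any_of(c("textbook", "disease"))),
    file.path(out_dir, "embedding.csv"))

  sweep <- stage("network", network_sweep(D, cfg$sparsity_levels))
  readr::write_csv(sweep, file.path(out_dir, "network_sweep.csv"))
  net <- build_network(D, max(cfg$sparsity_levels))
  write_network(net, file.path(out_dir, "network_edges.csv"),
                graphml = file.path(out_dir, "network.graphml"))

  contrib <- stage("attribution",
                   style_contributions(attr_scores, n_trees = cfg$n_trees,
                                       n_repeats = cfg$n_repeats,
                                       seed = cfg$seed,
                                       importance = cfg$importance))
  tbs <- sort(unique(attr_scores$textbook))
  tests <- if (length(tbs) >= 2) {
    stage("attribution",
          wilcoxon_attribute_tests(attr_scores, tbs[1],
                                   tbs[length(tbs)]))
  }
  write_attribution(contrib, tests, out_dir,
                    config = cfg[c("n_trees", "n_repeats", "seed",
                                   "importance")])

  files <- c("ap_scores.csv", "attribute_scores.csv",
             "similarity_suite.csv", "cluster_merges.csv",
             "embedding.csv", "network_sweep.csv", "network_edges.csv",
             "network.graphml", "contributions.csv",
             "attribution_config.json",
             if (!is.null(tests)) "attribute_tests.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("acustyle")),
    corpus_hash = corpus_hash(corpus),
    config = cfg,
    n_documents = nrow(scores),
    n_suite_tests = nrow(suite),
    mds_stress = attr(emb, "stress"),
    boundary_f1_textbook = f1,
    outputs = purrr::map(
      stats::setNames(files, files),
      ~ list(path = .x,
             md5 = unname(tools::md5sum(file.path(out_dir, .x)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
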