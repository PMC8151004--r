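#' Pairwise Euclidean distances between documents
#'
#' Distance between two documents is the Euclidean distance between
#' their score rows; low distance means similar prescriptions. This is
#' the similarity measure every downstream analysis (permutation test,
#' clustering, MDS, networks) consumes.
#'
#' @param scores An `ap_score_tbl`, or a numeric matrix with rows as
#'   documents.
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   doc_ids, and the document labels (if available) in
#'   `attr(, "doc_labels")`.
#' @export
pairwise_distances <- function(scores) {
  m <- if (is.matrix(scores)) scores else score_matrix(scores)
  if (nrow(m) < 2) abort_input("Need at least two documents.")
  if (!all(is.finite(m))) abort_input("Scores contain non-finite values.")
  D <- as.matrix(stats::dist(m, method = "euclidean"))
  if (is.data.frame(scores) &&
      all(c("textbook", "disease") %in% names(scores))) {
    attr(D, "doc_labels") <- tibble::tibble(
      doc_id = scores$doc_id, textbook = scores$textbook,
      disease = scores$disease)
  }
  D
}

## condensed upper-triangle view: pair indices + distances
condensed_pairs <- function(D) {
  n <- nrow(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L], d = D[upper.tri(D)], n = n)
}

#' Mean distance between same-label document pairs
#'
#' The test statistic: the mean Euclidean distance over all unordered
#' document pairs sharing a label (same textbook, or same disease).
#' Smaller values mean prescriptions within a group are more alike.
#'
#' @param D A square distance matrix (see [pairwise_distances()]).
#' @param labels A vector of group labels aligned to `D`'s row order.
#' @return A single number.
#' @export
same_label_mean_distance <- function(D, labels) {
  n <- nrow(D)
  if (length(labels) != n) {
    abort_input("`labels` length must match the distance matrix.")
  }
  cp <- condensed_pairs(D)
  same <- labels[cp$i] == labels[cp$j]
  if (!any(same)) abort_input("No pair of documents shares a label.")
  mean(cp$d[same])
}

#' Label-permutation test for within-group similarity
#'
#' Tests whether documents sharing a label (textbook or disease) have
#' more similar prescriptions than chance. The observed statistic is the
#' mean same-label pairwise distance; the null distribution is estimated
#' by uniformly permuting the label vector (preserving label
#' multiplicities) over the fixed distance matrix and recomputing the
#' statistic `B` times. The test is left-tailed -- smaller distance means
#' greater similarity -- so the empirical p-value is the fraction of null
#' statistics at most the observed one (ties count, conservatively).
#'
#' With `p_convention = "k_over_b"` (default) p = k/B and a zero count is
#' displayed as `<1/B` (e.g. `<1e-05`); `"add_one"` gives the
#' conservative (k+1)/(B+1). When the number of distinct permutations is
#' small (n! <= `exact_limit`, or `exact = TRUE`) the null is enumerated
#' exhaustively instead of sampled and the p-value is exact.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param labels Group labels aligned to `D`'s rows; must not be
#'   constant, and some label must repeat.
#' @param B Number of null samples (default 1e5).
#' @param seed Integer seed; results are reproducible for fixed
#'   (D, labels, B, seed).
#' @param p_convention `"k_over_b"` or `"add_one"`.
#' @param exact Force (or forbid, `FALSE`) exhaustive enumeration;
#'   `NULL` (default) switches automatically below `exact_limit`.
#' @param exact_limit Enumerate exhaustively when n! is at most this
#'   (default 40320 = 8!).
#' @return A `perm_test` object: a list with `observed`, `expected`
#'   (null mean), `p_empirical`, `p_display`, `B`, `seed`, `exact`,
#'   `null_sd`, plus the grouping metadata. `tidy()` gives a one-row
#'   tibble.
#' @examples
#' set.seed(1)
#' m <- matrix(runif(12), 6)
#' D <- pairwise_distances(m)
#' permutation_test(D, rep(c("a", "b"), each = 3), B = 1000, seed = 7)
#' @export
permutation_test <- function(D, labels, B = 1e5, seed = 1L,
                             p_convention = c("k_over_b", "add_one"),
                             exact = NULL, exact_limit = 40320) {
  p_convention <- match.arg(p_convention)
  n <- nrow(D)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort_input("Constant labels: the permutation test is degenerate.")
  }
  if (B < 1) abort_input("`B` must be at least 1.")
  observed <- same_label_mean_distance(D, labels)
  cp <- condensed_pairs(D)

  do_exact <- if (is.null(exact)) factorial(n) <= exact_limit else exact
  if (do_exact) {
    perms <- all_index_permutations(n)
    nulls <- apply(perms, 1L, function(ord) {
      pl <- labels[ord]
      mean(cp$d[pl[cp$i] == pl[cp$j]])
    })
    B_eff <- length(nulls)
  } else {
    nulls <- with_perm_seed(seed, {
      vapply(seq_len(B), function(b) {
        pl <- labels[sample.int(n)]
        mean(cp$d[pl[cp$i] == pl[cp$j]])
      }, numeric(1))
    })
    B_eff <- B
  }

  k <- sum(nulls <= observed + 1e-12)
  p <- switch(p_convention,
              k_over_b = k / B_eff,
              add_one = (k + 1) / (B_eff + 1))
  p_display <- if (k == 0 && p_convention == "k_over_b") {
    sprintf("<%g", 1 / B_eff)
  } else {
    format(p, digits = 3)
  }
  structure(list(
    observed = observed, expected = mean(nulls),
    p_empirical = p, p_display = p_display,
    B = B_eff, seed = seed, exact = do_exact,
    null_sd = stats::sd(nulls), n_documents = n,
    p_convention = p_convention
  ), class = "perm_test")
}

## all n! orderings of 1..n, one per row (small n only)
all_index_permutations <- function(n) {
  if (n > 9) abort_compute("Exhaustive enumeration limited to n <= 9.")
  e1071::permutations(n)
}

## run expr under a local RNG state seeded with `seed`
with_perm_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed %.4f vs expected %.4f (%s null samples%s)\n  p = %s\n",
    x$observed, x$expected, format(x$B, big.mark = ","),
    if (x$exact) ", exhaustive" else "", x$p_display))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname permutation_test
#' @param x A `perm_test`.
#' @param ... Unused.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, expected = x$expected,
    p_empirical = x$p_empirical, p_display = x$p_display,
    B = x$B, exact = x$exact, n_documents = x$n_documents)
}

#' @rdname permutation_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values:
#' monotone, clipped at 1, input order preserved.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort_input("p-values must be numbers in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

## significance stars at the customary thresholds
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "#",
    TRUE ~ ""
  )
}

#' Style-vs-disease similarity test suite
#'
#' Runs the full battery of within-group similarity tests on a corpus'
#' AP-scores: for the all-textbooks document set and for every textbook
#' pair (documents restricted to those two textbooks), both the
#' same-textbook and the same-disease test -- 2 + 2 C(T,2) results for T
#' textbooks (8 for the canonical three-textbook design). P-values are
#' Benjamini-Hochberg adjusted jointly across the suite.
#'
#' @param corpus An `ap_corpus` with at least 2 textbooks and 2 diseases.
#' @param B,seed,p_convention Passed to [permutation_test()]; each test
#'   in the suite gets a distinct seed derived from `seed`.
#' @param weighting Passed to [ap_scores()].
#' @return A tibble with one row per test: `subset`, `grouping`,
#'   `observed`, `expected`, `p_empirical`, `p_display`, `p_adjusted`,
#'   `stars`, `B`, `n_documents`.
#' @export
run_similarity_suite <- function(corpus, B = 1e5, seed = 1L,
                                 p_convention = c("k_over_b", "add_one"),
                                 weighting = c("multiplicity", "distinct")) {
  p_convention <- match.arg(p_convention)
  scores <- ap_scores(corpus, weighting = match.arg(weighting))
  tbs <- sort(unique(scores$textbook))
  if (length(tbs) < 2 || dplyr::n_distinct(scores$disease) < 2) {
    abort_input("The suite needs at least 2 textbooks and 2 diseases.")
  }
  subsets <- c(list(tbs), utils::combn(tbs, 2, simplify = FALSE))
  plan <- tidyr::expand_grid(
    subset_idx = seq_along(subsets),
    grouping = c("textbook", "disease"))
  res <- purrr::pmap(plan, function(subset_idx, grouping) {
    keep <- scores$textbook %in% subsets[[subset_idx]]
    sub <- scores[keep, , drop = FALSE]
    D <- pairwise_distances(score_matrix(sub))
    pt <- permutation_test(
      D, sub[[grouping]], B = B,
      seed = seed + 101L * subset_idx + match(grouping, c("textbook", "disease")),
      p_convention = p_convention, exact = FALSE)
    dplyr::mutate(tidy(pt),
                  subset = paste(subsets[[subset_idx]], collapse = " & "),
                  grouping = paste("same", grouping, sep = "_"),
                  .before = 1)
  }) |> dplyr::bind_rows()
  res$p_adjusted <- bh_adjust(res$p_empirical)
  res$stars <- p_stars(res$p_adjusted)
  res |>
    dplyr::select("subset", "grouping", "observed", "expected",
                  "p_empirical", "p_display", "p_adjusted", "stars",
                  "B", "n_documents")
}

#' Write a similarity-suite result table
#'
#' CSV with the suite's columns plus a JSON sidecar carrying `B`, the
#' base seed, and the corpus hash.
#'
#' @param suite Result of [run_similarity_suite()].
#' @param path Output CSV path (sidecar at `<path>.json`).
#' @param corpus Optional source corpus (for the hash).
#' @param seed Base seed used.
#' @return `path`, invisibly.
#' @export
write_suite <- function(suite, path, corpus = NULL, seed = NULL) {
  readr::write_csv(suite, path)
  meta <- list(B = unique(suite$B), seed = seed,
               corpus_hash = if (!is.null(corpus)) corpus_hash(corpus))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
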