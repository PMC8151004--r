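#' Random-forest contribution scores of point attributes
#'
#' Trains random-forest classifiers to separate two document groups by
#' their attribute scores and reports each attribute's *contribution
#' score*: its normalised feature importance, averaged over `n_repeats`
#' forests grown with distinct derived seeds (the repeat standard
#' deviation is reported for stability). Importances are normalised to
#' sum to 1 within every repeat, so contributions are directly
#' comparable across tasks.
#'
#' @param scores An attribute-score table from [attribute_scores()] (any
#'   data frame with `doc_id` plus numeric feature columns works).
#' @param labels Binary vector (two distinct values) aligned to the
#'   rows: the classification task, e.g. one textbook vs. the rest.
#' @param n_trees Trees per forest (default 500).
#' @param n_repeats Forests averaged (default 50).
#' @param seed Base seed; repeat r uses seed + r.
#' @param importance `"impurity"` (default, mean decrease in Gini) or
#'   `"permutation"`.
#' @return A `contribution_report` tibble: one row per attribute with
#'   `attribute`, `contribution_mean`, `contribution_sd`; the per-repeat
#'   score matrix in `attr(, "per_repeat")`, plus `task`, `n_trees`,
#'   `n_repeats`, `seed`, `degenerate` attributes. If every feature is
#'   constant the scores are uniform and `degenerate` is `TRUE` (with a
#'   warning).
#' @export
rf_contributions <- function(scores, labels, n_trees = 500,
                             n_repeats = 50, seed = 1L,
                             importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  if (n_trees < 1 || n_repeats < 1) {
    abort_input("`n_trees` and `n_repeats` must be at least 1.")
  }
  X <- score_matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    abort_input("`labels` must contain exactly two classes.")
  }
  ## canonicalise row order so results do not depend on how the caller
  ## happened to sort the documents
  if (!is.null(rownames(X)) && !anyDuplicated(rownames(X))) {
    ord <- order(rownames(X))
    X <- X[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  p <- ncol(X)
  degenerate <- all(apply(X, 2, function(col) diff(range(col)) == 0))
  if (degenerate) {
    rlang::warn("All features are constant; contributions set uniform.")
    per <- matrix(1 / p, n_repeats, p, dimnames = list(NULL, colnames(X)))
  } else {
    dat <- data.frame(X, .label = labels, check.names = FALSE)
    per <- t(vapply(seq_len(n_repeats), function(r) {
      fit <- ranger::ranger(
        dependent.variable.name = ".label", data = dat,
        num.trees = n_trees, importance = importance,
        seed = seed + r, num.threads = 1)
      imp <- pmax(fit$variable.importance, 0)
      if (sum(imp) == 0) rep(1 / p, p) else imp / sum(imp)
    }, numeric(p)))
    colnames(per) <- colnames(X)
  }
  out <- tibble::tibble(
    attribute = colnames(per),
    contribution_mean = unname(colMeans(per)),
    contribution_sd = unname(apply(per, 2, stats::sd)))
  structure(out, per_repeat = per,
            task = paste(levels(labels), collapse = " vs "),
            n_trees = n_trees, n_repeats = n_repeats, seed = seed,
            importance = importance, degenerate = degenerate,
            class = c("contribution_report", class(out)))
}

#' Contribution scores for the canonical style-contrast tasks
#'
#' Runs [rf_contributions()] on the two contrasts the style analysis
#' uses: each textbook against the rest (one-vs-rest), and every
#' textbook pair head-to-head.
#'
#' @inheritParams rf_contributions
#' @return A tibble stacking the per-task reports with a `task` column.
#' @export
style_contributions <- function(scores, n_trees = 500, n_repeats = 50,
                                seed = 1L,
                                importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  tbs <- sort(unique(scores$textbook))
  tasks <- c(
    purrr::map(tbs, ~ list(name = paste0(.x, " vs rest"),
                           keep = rep(TRUE, nrow(scores)),
                           labels = ifelse(scores$textbook == .x, .x, "rest"))),
    purrr::map(utils::combn(tbs, 2, simplify = FALSE),
               ~ list(name = paste(.x, collapse = " vs "),
                      keep = scores$textbook %in% .x,
                      labels = scores$textbook[scores$textbook %in% .x])))
  purrr::imap(tasks, function(tk, idx) {
    rep <- rf_contributions(scores[tk$keep, , drop = FALSE], tk$labels,
                            n_trees = n_trees, n_repeats = n_repeats,
                            seed = seed + 977L * idx,
                            importance = importance)
    dplyr::mutate(tibble::as_tibble(rep), task = tk$name, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Paired Wilcoxon signed-rank tests per attribute
#'
#' For each of the four attributes, tests whether two textbooks differ
#' in their attribute scores, pairing documents by disease (the design's
#' alignment key: each textbook contributes one document per disease).
#' Two-sided signed-rank test on the paired differences (A minus B);
#' exact distribution when n <= 25 with no ties or zeros, otherwise the
#' normal approximation with continuity correction; zero differences
#' are dropped (standard convention). P-values are Benjamini-Hochberg
#' adjusted across the four attributes and flagged at the 0.01 level.
#'
#' An unpaired Mann-Whitney mode (`paired = FALSE`) is available for
#' sensitivity analysis; the paired test is the default because disease
#' is the design's natural pairing key.
#'
#' @param scores An attribute-score table from [attribute_scores()].
#' @param textbook_a,textbook_b The two textbook labels to compare
#'   (differences are A minus B).
#' @param pair_key Column pairing the documents (default `"disease"`).
#' @param paired Use the signed-rank (paired) test (default `TRUE`).
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @return A tibble with one row per attribute: `attribute`,
#'   `median_difference`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`, `direction` (which textbook is enriched), `n_pairs`.
#' @export
wilcoxon_attribute_tests <- function(scores, textbook_a, textbook_b,
                                     pair_key = "disease", paired = TRUE,
                                     alpha = 0.01) {
  attrs <- intersect(ATTRIBUTES, names(scores))
  if (!length(attrs)) abort_input("No attribute columns found in `scores`.")
  a <- scores[scores$textbook == textbook_a, , drop = FALSE]
  b <- scores[scores$textbook == textbook_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    abort_input("Both textbooks must be present in `scores`.")
  }
  if (paired) {
    missing_d <- c(setdiff(a[[pair_key]], b[[pair_key]]),
                   setdiff(b[[pair_key]], a[[pair_key]]))
    if (length(missing_d) || anyDuplicated(a[[pair_key]]) ||
        anyDuplicated(b[[pair_key]])) {
      abort_input(sprintf(
        "Pairing by %s is incomplete%s.", pair_key,
        if (length(missing_d))
          paste0("; unmatched: ", toString(unique(missing_d))) else ""))
    }
    b <- b[match(a[[pair_key]], b[[pair_key]]), , drop = FALSE]
  }
  res <- purrr::map(attrs, function(att) {
    xa <- a[[att]]; xb <- b[[att]]
    if (paired && sum(xa != xb) < 5) {
      rlang::warn(sprintf(
        "Fewer than 5 non-zero paired differences for %s.", att))
    }
    wt <- if (paired && all(xa == xb)) {
      list(statistic = c(V = 0), p.value = 1)  # degenerate: no signal
    } else {
      suppressWarnings(stats::wilcox.test(
        xa, xb, paired = paired, correct = TRUE,
        exact = if (paired) length(xa) <= 25 else NULL))
    }
    tibble::tibble(
      attribute = att,
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      n_pairs = if (paired) length(xa) else NA_integer_)
  }) |> dplyr::bind_rows()
  res$median_difference <- purrr::map_dbl(attrs, function(att) {
    if (paired) stats::median(a[[att]] - b[[att]])
    else stats::median(a[[att]]) - stats::median(b[[att]])
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res$significant <- res$p_adjusted < alpha
  res$direction <- dplyr::case_when(
    !res$significant ~ "none",
    res$median_difference > 0 ~ textbook_a,
    res$median_difference < 0 ~ textbook_b,
    TRUE ~ "none")
  res$stars <- p_stars(res$p_adjusted)
  dplyr::select(res, "attribute", "median_difference", "statistic",
                "p_value", "p_adjusted", "significant", "direction",
                "stars", "n_pairs")
}

#' Write attribution reports
#'
#' CSVs per task -- contributions (`attribute`, `contribution_mean`,
#' `contribution_sd`) and attribute tests (`attribute`, `statistic`,
#' `p_value`, `p_adjusted`, `stars`) -- plus a JSON config sidecar.
#'
#' @param contributions Result of [style_contributions()].
#' @param tests Result of [wilcoxon_attribute_tests()] (optional).
#' @param dir Output directory.
#' @param config List serialised into the sidecar.
#' @return `dir`, invisibly.
#' @export
write_attribution <- function(contributions, tests = NULL, dir,
                              config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(contributions, file.path(dir, "contributions.csv"))
  if (!is.null(tests)) {
    readr::write_csv(tests, file.path(dir, "attribute_tests.csv"))
  }
  jsonlite::write_json(config, file.path(dir, "attribution_config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
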