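#' AP-score matrix
#'
#' The AP-score of a document is its relative-frequency vector over the
#' corpus vocabulary: entry (i, j) is the count of point j in document i
#' divided by the document's total mentions, so every row sums to 1.
#' With `weighting = "distinct"` each point contributes presence/absence
#' instead of its mention count (a sensitivity-analysis mode).
#'
#' @param corpus An `ap_corpus`.
#' @param weighting `"multiplicity"` (default; a point selected six times
#'   contributes 6) or `"distinct"` (binary presence).
#' @return A tibble with one row per document: `doc_id`, `textbook`,
#'   `disease`, then one numeric column per vocabulary point in canonical
#'   order. Class `ap_score_tbl`.
#' @examples
#' corp <- as_ap_corpus(data.frame(
#'   doc_id = "d1", textbook = "A", disease = "cough",
#'   ap_code = c("BL13", "GV14", "LU7"), count = c(6, 1, 2)))
#' ap_scores(corp)  # BL13 entry is 6/9
#' @export
ap_scores <- function(corpus, weighting = c("multiplicity", "distinct")) {
  stopifnot(inherits(corpus, "ap_corpus"))
  weighting <- match.arg(weighting)
  vocab <- corpus_vocabulary(corpus)
  long <- tibble::as_tibble(corpus)
  if (weighting == "distinct") long$count <- 1L
  wide <- long |>
    dplyr::mutate(ap_code = factor(.data$ap_code, levels = vocab)) |>
    dplyr::group_by(.data$doc_id, .data$textbook, .data$disease) |>
    dplyr::mutate(score = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("doc_id", "textbook", "disease", "ap_code", "score") |>
    tidyr::pivot_wider(names_from = "ap_code", values_from = "score",
                       values_fill = 0, names_expand = TRUE) |>
    dplyr::arrange(.data$doc_id)
  new_score_tbl(wide, vocabulary = vocab)
}

#' Distant-point rules
#'
#' Decides, per (disease, point), whether a selected point is *distant*
#' -- far from the disease site. The default `region_heuristic` calls a
#' point distant iff its region is `distal_limb` while the disease's
#' annotated site region is not `distal_limb`. `explicit_table` takes a
#' full (disease, ap_code) -> logical table; `disabled` scores the
#' distant attribute as 0 everywhere.
#'
#' @param mode One of `"region_heuristic"`, `"explicit_table"`,
#'   `"disabled"`.
#' @param disease_regions For `region_heuristic`: a tibble with columns
#'   `disease`, `region` covering every corpus disease
#'   (default [default_disease_regions()]).
#' @param pairs For `explicit_table`: a tibble with columns `disease`,
#'   `ap_code`, `distant` covering every corpus (disease, point) pair.
#' @return A `distant_rule` object.
#' @export
distant_rule <- function(mode = c("region_heuristic", "explicit_table",
                                  "disabled"),
                         disease_regions = default_disease_regions(),
                         pairs = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit_table") {
    if (is.null(pairs) ||
        !all(c("disease", "ap_code", "distant") %in% names(pairs))) {
      abort_input(
        "explicit_table mode needs `pairs` with disease, ap_code, distant.")
    }
    pairs$ap_code <- parse_ap_code(pairs$ap_code)
  }
  structure(list(mode = mode, disease_regions = disease_regions,
                 pairs = pairs),
            class = "distant_rule")
}

## logical vector: is each (disease, ap_code) pair distant?
resolve_distant <- function(rule, disease, ap_code, table) {
  switch(rule$mode,
    disabled = rep(FALSE, length(disease)),
    region_heuristic = {
      site <- rule$disease_regions$region[
        match(disease, rule$disease_regions$disease)]
      if (anyNA(site)) {
        abort_input(sprintf(
          "No site region annotated for disease(s): %s.",
          toString(unique(disease[is.na(site)]))))
      }
      pt_region <- table$region[match(ap_code, table$ap_code)]
      pt_region == "distal_limb" & site != "distal_limb"
    },
    explicit_table = {
      key <- paste(disease, ap_code)
      hit <- match(key, paste(rule$pairs$disease, rule$pairs$ap_code))
      if (anyNA(hit)) {
        abort_input(sprintf(
          "Distant-point table does not cover pair(s): %s.",
          toString(unique(key[is.na(hit)]))))
      }
      as.logical(rule$pairs$distant[hit])
    })
}

#' AP attribute-score matrix
#'
#' For each document, the fraction of its point-mention instances that
#' carry each of the four theoretical attributes, in fixed column order:
#' `distant` (per the active distant-point rule), `extra_meridian`
#' (governor/conception vessel), `five_transport` (any well / brook /
#' stream / river / sea class), and `source`. Values lie in \[0, 1\];
#' rows do not generally sum to 1 because the attributes overlap and are
#' not exhaustive.
#'
#' @inheritParams ap_scores
#' @param table A point attribute table covering every corpus point
#'   (default [default_attribute_table()]).
#' @param rule A [distant_rule()].
#' @return A tibble with columns `doc_id`, `textbook`, `disease`,
#'   `distant`, `extra_meridian`, `five_transport`, `source`. Class
#'   `ap_score_tbl`.
#' @export
attribute_scores <- function(corpus, table = default_attribute_table(),
                             rule = distant_rule(),
                             weighting = c("multiplicity", "distinct")) {
  stopifnot(inherits(corpus, "ap_corpus"))
  weighting <- match.arg(weighting)
  validate_attribute_table(table)
  long <- tibble::as_tibble(corpus)
  if (weighting == "distinct") long$count <- 1L
  missing_codes <- setdiff(long$ap_code, table$ap_code)
  if (length(missing_codes)) {
    abort_input(sprintf(
      "Point code(s) absent from the attribute table: %s.",
      toString(missing_codes)))
  }
  hit <- match(long$ap_code, table$ap_code)
  long$extra_meridian <- table$is_extra_meridian[hit]
  long$five_transport <- table$transport_class[hit] != "none"
  long$source <- table$is_source_point[hit]
  long$distant <- resolve_distant(rule, long$disease, long$ap_code, table)
  out <- long |>
    dplyr::group_by(.data$doc_id, .data$textbook, .data$disease) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(ATTRIBUTES),
      ~ sum(.data$count * .x) / sum(.data$count)), .groups = "drop") |>
    dplyr::arrange(.data$doc_id)
  new_score_tbl(out, vocabulary = ATTRIBUTES)
}

## fixed attribute column order for reproducible feature indices
ATTRIBUTES <- c("distant", "extra_meridian", "five_transport", "source")

new_score_tbl <- function(x, vocabulary) {
  structure(x, vocabulary = vocabulary,
            class = c("ap_score_tbl", class(x)))
}

#' Extract the numeric matrix of a score table
#'
#' @param scores An `ap_score_tbl` from [ap_scores()] or
#'   [attribute_scores()] (or any data frame with `doc_id` and numeric
#'   score columns).
#' @return A numeric matrix, rows named by `doc_id`, feature columns in
#'   the table's column order.
#' @export
score_matrix <- function(scores) {
  meta <- intersect(c("doc_id", "textbook", "disease"), names(scores))
  m <- as.matrix(as.data.frame(scores)[setdiff(names(scores), meta)])
  rownames(m) <- scores$doc_id
  storage.mode(m) <- "double"
  m
}

#' Write a score matrix with its metadata sidecar
#'
#' Writes the score table as CSV (doc_id index column first) plus a JSON
#' sidecar recording the feature order, the corpus hash, and -- for
#' attribute scores -- the distant-rule mode.
#'
#' @param scores An `ap_score_tbl`.
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @param corpus Optional corpus the scores came from (for the hash).
#' @param rule Optional [distant_rule()] used (for attribute scores).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, corpus = NULL, rule = NULL) {
  readr::write_csv(tibble::as_tibble(scores), path)
  meta <- list(
    features = attr(scores, "vocabulary"),
    corpus_hash = if (!is.null(corpus)) corpus_hash(corpus),
    distant_rule = if (!is.null(rule)) rule$mode
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
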