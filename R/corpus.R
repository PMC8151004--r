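#' Build a prescription corpus from tidy mention records
#'
#' A corpus is a tidy tibble of acupuncture-point mention counts, one row
#' per (document, point), where every document is a textbook chapter
#' labeled by `textbook` (the prescribing style) and `disease`. Repeated
#' (doc_id, ap_code) rows are summed -- mentions are a bag: a point
#' "selected six times" carries count 6.
#'
#' @param x A data frame with columns `doc_id`, `textbook`, `disease`,
#'   `ap_code`, and optionally `count` (default 1 per row).
#' @return An `ap_corpus` tibble with columns `doc_id`, `textbook`,
#'   `disease`, `ap_code`, `count`, aggregated and ordered by document
#'   then canonical point order, with the vocabulary (ordered union of
#'   codes present) in `attr(, "vocabulary")`.
#' @examples
#' as_ap_corpus(data.frame(
#'   doc_id = "d1", textbook = "A", disease = "cough",
#'   ap_code = c("BL13", "GV14", "LU7"), count = c(6, 1, 2)
#' ))
#' @export
as_ap_corpus <- function(x) {
  req <- c("doc_id", "textbook", "disease", "ap_code")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    abort_input(sprintf("Corpus records lack column(s): %s.",
                        toString(missing_cols)))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) abort_input("Corpus has no mention records.")
  if (!"count" %in% names(x)) x$count <- 1L
  x$count[is.na(x$count)] <- 1L
  if (any(x$count <= 0) || any(x$count != round(x$count))) {
    abort_input("`count` must be positive integers.")
  }
  x$ap_code <- parse_ap_code(x$ap_code)

  ## each doc_id must map to a single (textbook, disease)
  lab <- dplyr::distinct(x, .data$doc_id, .data$textbook, .data$disease)
  dup <- lab$doc_id[duplicated(lab$doc_id)]
  if (length(dup)) {
    abort_input(sprintf(
      "Document(s) %s carry inconsistent textbook/disease labels.",
      toString(sQuote(unique(dup), q = FALSE))
    ))
  }

  agg <- x |>
    dplyr::group_by(.data$doc_id, .data$textbook, .data$disease,
                    .data$ap_code) |>
    dplyr::summarise(count = as.integer(sum(.data$count)),
                     .groups = "drop")
  vocab <- sort_ap_codes(agg$ap_code)
  agg <- agg |>
    dplyr::arrange(.data$doc_id, match(.data$ap_code, vocab))
  structure(agg, vocabulary = vocab,
            class = c("ap_corpus", class(agg)))
}

#' Read a prescription corpus from CSV
#'
#' Expects UTF-8 CSV with header `doc_id,textbook,disease,ap_code,count`
#' (`count` optional, default 1); repeated (doc_id, ap_code) rows are
#' summed. Unparseable point codes are reported with their row numbers.
#'
#' @param path Path to the corpus CSV.
#' @param quiet If `FALSE` (default), print a design-completeness report
#'   (which textbook x disease cells are present) to the console.
#' @return An `ap_corpus` tibble; see [as_ap_corpus()].
#' @export
read_corpus <- function(path, quiet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           doc_id = readr::col_character(),
                           textbook = readr::col_character(),
                           disease = readr::col_character(),
                           ap_code = readr::col_character(),
                           .default = readr::col_double()
                         ))
  parsed <- tryCatch(parse_ap_code(raw$ap_code), error = function(e) e)
  if (inherits(parsed, "error")) {
    bad <- which(vapply(raw$ap_code, function(cc) {
      inherits(tryCatch(parse_ap_code(cc), error = function(e) e), "error")
    }, logical(1)))
    abort_input(sprintf(
      "Unparseable ap_code at data row(s) %s: %s.",
      toString(bad), toString(sQuote(unique(raw$ap_code[bad]), q = FALSE))
    ))
  }
  corpus <- as_ap_corpus(raw)
  if (!quiet) print(design_report(corpus))
  corpus
}

#' Write a corpus to CSV
#'
#' Writes the aggregated records in the standard corpus layout
#' (`doc_id,textbook,disease,ap_code,count`). `read_corpus()` of the
#' written file reproduces the corpus exactly.
#'
#' @param corpus An `ap_corpus`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ap_corpus"))
  readr::write_csv(
    corpus[c("doc_id", "textbook", "disease", "ap_code", "count")], path)
  invisible(path)
}

#' Design-completeness report
#'
#' Tabulates which textbook x disease cells of the study design have a
#' document, and flags missing cells. A balanced corpus of 3 textbooks
#' and 14 diseases has all 42 cells filled.
#'
#' @param corpus An `ap_corpus`.
#' @return A tibble with one row per textbook x disease cell and a
#'   logical `present` column.
#' @export
design_report <- function(corpus) {
  docs <- corpus_documents(corpus)
  tidyr::expand_grid(textbook = unique(docs$textbook),
                     disease = unique(docs$disease)) |>
    dplyr::left_join(dplyr::count(docs, .data$textbook, .data$disease),
                     by = c("textbook", "disease")) |>
    dplyr::mutate(n_documents = dplyr::coalesce(.data$n, 0L),
                  present = .data$n_documents > 0L) |>
    dplyr::select(-"n")
}

#' Per-document labels of a corpus
#'
#' @param corpus An `ap_corpus`.
#' @return A tibble with one row per document: `doc_id`, `textbook`,
#'   `disease`, `n_points` (distinct points), `n_mentions` (total count).
#' @export
corpus_documents <- function(corpus) {
  stopifnot(inherits(corpus, "ap_corpus"))
  corpus |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$doc_id, .data$textbook, .data$disease) |>
    dplyr::summarise(n_points = dplyr::n(),
                     n_mentions = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$doc_id)
}

#' @rdname as_ap_corpus
#' @param corpus An `ap_corpus`.
#' @export
corpus_vocabulary <- function(corpus) {
  stopifnot(inherits(corpus, "ap_corpus"))
  attr(corpus, "vocabulary")
}

#' Content hash of a corpus
#'
#' A stable hash of the aggregated records, recorded in result metadata
#' so downstream outputs can be traced to their input corpus.
#'
#' @param corpus An `ap_corpus`.
#' @return A character scalar.
#' @export
corpus_hash <- function(corpus) {
  rlang::hash(as.data.frame(
    corpus[c("doc_id", "textbook", "disease", "ap_code", "count")]))
}

#' @export
print.ap_corpus <- function(x, ...) {
  docs <- corpus_documents(x)
  cat(sprintf(
    "<ap_corpus> %d documents (%d textbooks x %d diseases), %d points, %d mentions\n",
    nrow(docs), dplyr::n_distinct(docs$textbook),
    dplyr::n_distinct(docs$disease), length(corpus_vocabulary(x)),
    sum(docs$n_mentions)))
  NextMethod()
}
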