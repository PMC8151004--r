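#' Simulate a prescription corpus with planted style and disease effects
#'
#' Generates a corpus with the statistical structure the analysis
#' assumes: one document per textbook x disease design cell, each a bag
#' of point mentions drawn from a tilted baseline distribution. A
#' baseline weight vector over the full 361-point vocabulary is drawn
#' once per corpus from a symmetric Dirichlet; the sampling weight of
#' point a in document (t, d) is
#'
#'   b_a (1 + s 1\[a carries textbook t's preferred attribute\])
#'       (1 + g 1\[a in disease d's signature set\])
#'
#' and the document's mentions are a multinomial draw of size
#' `mentions_per_doc`. `style_strength` s = 0 and `disease_strength`
#' g = 0 give exchangeable documents (an exact null); increasing either
#' plants a style or disease effect of known location, recorded in the
#' returned ground truth. The default preferred attributes mirror the
#' canonical three-style pattern: textbook 1 loads five-transport
#' points, textbook 2 extra-meridian points, textbook 3 source points.
#'
#' @param style_strength Nonnegative tilt s toward each textbook's
#'   preferred attribute (default 0).
#' @param disease_strength Nonnegative tilt g toward each disease's
#'   signature points (default 0).
#' @param n_textbooks,n_diseases Design size (defaults 3 and 14, the 42
#'   document design). Up to 14 diseases use the packaged disease panel
#'   (with annotated site regions); beyond that, generic labels.
#' @param mentions_per_doc Mentions per document (default 30).
#' @param signature_size Points per disease signature, sampled without
#'   replacement from the vocabulary; signatures of different diseases
#'   may overlap (default 8).
#' @param base_concentration Symmetric Dirichlet concentration of the
#'   baseline point distribution (default 0.5, mildly sparse).
#' @param preferred_attributes Character vector recycled over textbooks,
#'   values among `distant`, `extra_meridian`, `five_transport`,
#'   `source`.
#' @param seed Integer seed; the corpus is a deterministic function of
#'   the configuration and seed.
#' @param table Attribute table defining the vocabulary and attribute
#'   membership (default the packaged reference table).
#' @return A list with `corpus` (an `ap_corpus`) and `truth`
#'   (a `synth_truth` list: baseline weights, signature sets, preferred
#'   attributes, and the full configuration).
#' @examples
#' sim <- simulate_corpus(style_strength = 2, seed = 42)
#' sim$corpus
#' sim$truth$preferred_attributes
#' @export
simulate_corpus <- function(style_strength = 0, disease_strength = 0,
                            n_textbooks = 3, n_diseases = 14,
                            mentions_per_doc = 30, signature_size = 8,
                            base_concentration = 0.5,
                            preferred_attributes = c("five_transport",
                                                     "extra_meridian",
                                                     "source"),
                            seed = 1L,
                            table = default_attribute_table()) {
  if (style_strength < 0 || disease_strength < 0 ||
      !is.finite(style_strength) || !is.finite(disease_strength)) {
    abort_input("Effect strengths must be finite and nonnegative.")
  }
  if (mentions_per_doc < 1 || n_textbooks < 1 || n_diseases < 1 ||
      signature_size < 1 || base_concentration <= 0) {
    abort_input("Invalid simulation configuration.")
  }
  if (!all(preferred_attributes %in% ATTRIBUTES)) {
    abort_input(sprintf("preferred_attributes must be among: %s.",
                        toString(ATTRIBUTES)))
  }
  vocab <- table$ap_code
  textbooks <- sprintf("TB%d", seq_len(n_textbooks))
  diseases <- if (n_diseases <= length(DISEASE_PANEL)) {
    DISEASE_PANEL[seq_len(n_diseases)]
  } else {
    c(DISEASE_PANEL, sprintf("disease%02d",
                             seq_len(n_diseases - length(DISEASE_PANEL))))
  }
  pref <- rep_len(preferred_attributes, n_textbooks)
  names(pref) <- textbooks

  ## 0/1 attribute membership over the vocabulary (distant is resolved
  ## per disease via the packaged site regions)
  attr_ind <- attribute_indicators(table)

  rec <- with_perm_seed(seed, {
    base <- stats::rgamma(length(vocab), shape = base_concentration)
    base <- base / sum(base)
    signatures <- purrr::map(diseases, ~ sample(vocab, signature_size))
    names(signatures) <- diseases
    rule <- distant_rule()
    docs <- purrr::map(textbooks, function(tb) {
      purrr::map(diseases, function(ds) {
        carries <- if (pref[[tb]] == "distant") {
          resolve_distant(rule, rep(ds, length(vocab)), vocab, table)
        } else {
          attr_ind[, pref[[tb]]]
        }
        w <- base * (1 + style_strength * carries) *
          (1 + disease_strength * (vocab %in% signatures[[ds]]))
        counts <- as.integer(stats::rmultinom(1, mentions_per_doc,
                                              prob = w))
        keep <- counts > 0
        tibble::tibble(doc_id = paste(tb, ds, sep = "."),
                       textbook = tb, disease = ds,
                       ap_code = vocab[keep], count = counts[keep])
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    list(docs = docs, base = base, signatures = signatures)
  })

  truth <- structure(list(
    baseline = stats::setNames(rec$base, vocab),
    signatures = rec$signatures,
    preferred_attributes = pref,
    config = list(style_strength = style_strength,
                  disease_strength = disease_strength,
                  n_textbooks = n_textbooks, n_diseases = n_diseases,
                  mentions_per_doc = mentions_per_doc,
                  signature_size = signature_size,
                  base_concentration = base_concentration,
                  seed = seed)
  ), class = "synth_truth")
  list(corpus = as_ap_corpus(rec$docs), truth = truth)
}

## documents x 4 -> vocabulary x 4 0/1 indicator (distant excluded from
## precomputation; see simulate_corpus)
attribute_indicators <- function(table) {
  cbind(
    distant = as.numeric(table$region == "distal_limb"),
    extra_meridian = as.numeric(table$is_extra_meridian),
    five_transport = as.numeric(table$transport_class != "none"),
    source = as.numeric(table$is_source_point)
  )
}

#' Write a simulated corpus with its ground truth
#'
#' The corpus goes to the standard corpus CSV; the planted truth
#' (configuration, preferred attributes, signature sets) to a JSON
#' sidecar. Downstream stages consume the CSV exactly as real data.
#'
#' @param sim Result of [simulate_corpus()].
#' @param path Corpus CSV path; truth written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_corpus(sim$corpus, path)
  truth <- sim$truth
  jsonlite::write_json(
    list(config = truth$config,
         preferred_attributes = as.list(truth$preferred_attributes),
         signatures = truth$signatures),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Null rejection rate of the same-textbook test
#'
#' Calibration harness: simulates corpora with no planted effects
#' (s = g = 0), runs the same-textbook permutation test on each, and
#' returns the fraction rejecting at level `alpha`. For a calibrated
#' test this tracks `alpha`.
#'
#' @param n_reps Number of simulated corpora (>= 50 recommended).
#' @param alpha Rejection level.
#' @param B Null samples per test.
#' @param seed Base seed; replicate r uses derived seeds.
#' @param grouping `"textbook"` (default) or `"disease"`.
#' @param ... Passed to [simulate_corpus()] (design size etc.).
#' @return The rejection rate, with the per-replicate p-values in
#'   `attr(, "p_values")`.
#' @export
null_rejection_rate <- function(n_reps = 200, alpha = 0.05, B = 2000,
                                seed = 1L,
                                grouping = c("textbook", "disease"),
                                ...) {
  grouping <- match.arg(grouping)
  ps <- replicate_pvalues(n_reps = n_reps, B = B, seed = seed,
                          grouping = grouping,
                          style_strength = 0, disease_strength = 0, ...)
  structure(mean(ps < alpha), p_values = ps)
}

## same-group permutation p-values over simulated replicates
replicate_pvalues <- function(n_reps, B, seed, grouping,
                              style_strength, disease_strength, ...) {
  vapply(seq_len(n_reps), function(r) {
    sim <- simulate_corpus(style_strength = style_strength,
                           disease_strength = disease_strength,
                           seed = seed + 7919L * r, ...)
    scores <- ap_scores(sim$corpus)
    D <- pairwise_distances(scores)
    permutation_test(D, scores[[grouping]], B = B,
                     seed = seed + 104729L + r, exact = FALSE)$p_empirical
  }, numeric(1))
}
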