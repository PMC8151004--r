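# Small fixture builders used across test files.

# a corpus of n_docs random documents over a small vocabulary
random_corpus <- function(n_docs = 6, n_textbooks = 2, n_diseases = 3,
                          vocab = c("LU7", "LI4", "SP3", "BL13", "GV20",
                                    "CV4", "KI3", "HT7"),
                          max_count = 4, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_docs), function(i) {
    pts <- sample(vocab, sample(2:length(vocab), 1))
    data.frame(
      doc_id = sprintf("doc%02d", i),
      textbook = sprintf("T%d", 1 + (i - 1) %% n_textbooks),
      disease = sprintf("d%d", 1 + (i - 1) %/% n_textbooks %% n_diseases),
      ap_code = pts,
      count = sample(max_count, length(pts), replace = TRUE)
    )
  })
  as_ap_corpus(do.call(rbind, rows))
}

demo_corpus_path <- function() {
  system.file("extdata", "synthetic_cough_demo.csv", package = "acustyle")
}
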