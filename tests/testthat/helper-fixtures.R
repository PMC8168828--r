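# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except temporary files the tests themselves write.

# A tiny linearly separable corpus: every positive contains "randomized",
# no negative does. Abstracts are padded past the 400-char cutoff so the
# records are machine-eligible.
toy_separable_corpus <- function(n_pos = 8, n_neg = 24, seed = 42) {
  withr_seed <- function(code) { # local, avoids a withr dependency
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    filler <- function() paste(sample(sprintf("filler%02d", 1:40), 50,
                                      replace = TRUE), collapse = " ")
    n <- n_pos + n_neg
    lab <- c(rep(1L, n_pos), rep(0L, n_neg))
    abstract <- vapply(seq_len(n), function(i) {
      base <- filler()
      if (lab[i] == 1L) paste("randomized controlled trial", base) else base
    }, character(1))
    data.frame(record_id = sprintf("toy%03d", seq_len(n)),
               title = paste("study number", seq_len(n), "padding title"),
               abstract = abstract, label = lab,
               study_id = NA_character_, year = NA_integer_,
               stringsAsFactors = FALSE)
  })
}

toy_features <- function(corpus, n_range = c(1, 1), min_doc_freq = 1) {
  docs <- prepare_documents(corpus)
  vocab <- build_vocabulary(docs, n_range = n_range,
                            min_doc_freq = min_doc_freq)
  list(X = vectorize(docs, vocab), vocab = vocab, docs = docs)
}

# Small trained+calibrated bundle shared across pipeline tests; built once
# per test run.
small_bundle_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(small_bundle_cache$bundle)) {
    tr <- generate_training_corpus(
      generator_config(n_records = 1500, prevalence = 0.1, seed = 201))
    ca <- generate_calibration_corpus(
      generator_config(n_records = 1500, prevalence = 0.06,
                       suppress_fraction = 0.005, seed = 202))
    small_bundle_cache$bundle <- train_and_calibrate(tr, ca,
                                                     target_recall = 0.95,
                                                     seed = 203)
    small_bundle_cache$calibration <- ca
  }
  small_bundle_cache$bundle
}
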