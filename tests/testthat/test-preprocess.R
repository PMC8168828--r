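test_that("tokenization lowercases, splits on non-alphanumerics and keeps digits", {
  expect_equal(tokenize("Randomized, controlled trial."),
               c("randomized", "controlled", "trial"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("double-blind RCT"), c("double", "blind", "rct"))
  expect_equal(tokenize("n=120 patients (60%)"), c("n", "120", "patients", "60"))
  expect_equal(tokenize("--- ... ---"), character(0))
})

test_that("stopword removal is exact whole-token match, order preserved", {
  expect_equal(remove_stopwords(c("the", "trial", "and", "placebo"),
                                c("the", "and")),
               c("trial", "placebo"))
  expect_equal(remove_stopwords("trial", character(0)), "trial")
  expect_equal(remove_stopwords(c("the", "the"), "the"), character(0))
  # "theory" must survive a "the" stopword
  expect_equal(remove_stopwords(c("theory", "the"), "the"), "theory")
})

test_that("the packaged stopword list contains the canonical examples", {
  sw <- pubmed_stopwords()
  expect_true(all(c("and", "the", "of", "with") %in% sw))
  expect_gt(length(sw), 100)
  expect_equal(sw, tolower(sw))
})

test_that("vocabulary contains exactly the n-grams at or above the document frequency floor", {
  v <- build_vocabulary(list(c("randomized", "controlled", "trial")),
                        n_range = c(1, 3), min_doc_freq = 1)
  expect_setequal(v$ngrams,
                  c("randomized", "controlled", "trial",
                    "randomized controlled", "controlled trial",
                    "randomized controlled trial"))
  expect_equal(v$ngrams, sort(v$ngrams, method = "radix"))  # deterministic order

  v1 <- build_vocabulary(list(c("randomized", "controlled", "trial")),
                         n_range = c(1, 1), min_doc_freq = 1)
  expect_length(v1$ngrams, 3)

  # disjoint documents never reach doc freq 2: empty vocabulary + warning
  expect_warning(
    v0 <- build_vocabulary(list(c("alpha"), c("beta")), n_range = c(1, 1),
                           min_doc_freq = 2),
    "empty vocabulary")
  expect_length(v0$ngrams, 0)

  expect_error(build_vocabulary(list(), n_range = c(1, 1)),
               class = "rctscreen_validation_error")
})

test_that("vectorization is binary presence, ignores out-of-vocabulary n-grams", {
  vocab <- build_vocabulary(list("trial"), n_range = c(1, 1))
  X <- vectorize(list(c("trial", "trial")), vocab)
  expect_equal(as.numeric(X[1, ]), 1)  # presence, not count
  expect_equal(as.numeric(vectorize(list("unseen"), vocab)[1, ]), 0)
  expect_equal(as.numeric(vectorize(list(character(0)), vocab)[1, ]), 0)
})

test_that("duplicating a token never changes a document's unigram feature row", {
  set.seed(7)
  words <- sprintf("w%02d", 1:30)
  for (k in 1:20) {
    doc <- sample(words, sample(3:12, 1), replace = TRUE)
    vocab <- build_vocabulary(list(doc), n_range = c(1, 1))
    X1 <- vectorize(list(doc), vocab)
    dup <- c(doc, doc[sample(length(doc), 1)])
    expect_equal(as.numeric(vectorize(list(dup), vocab)[1, ]),
                 as.numeric(X1[1, ]))
  }
})

test_that("vocabulary built from a corpus yields no all-zero column on that corpus", {
  set.seed(8)
  docs <- replicate(25, sample(sprintf("w%02d", 1:15),
                               sample(4:10, 1), replace = TRUE),
                    simplify = FALSE)
  vocab <- build_vocabulary(docs, n_range = c(1, 3), min_doc_freq = 2)
  X <- vectorize(docs, vocab)
  expect_true(all(Matrix::colSums(X) > 0))
})

test_that("length routing uses inclusive minima on stripped code-point counts", {
  rec <- function(a, t) data.frame(record_id = "r", title = t, abstract = a,
                                   stringsAsFactors = FALSE)
  r <- assess_eligibility(rec(strrep("a", 400), strrep("t", 15)))
  expect_equal(r$route, "machine"); expect_equal(r$reason, "ok")

  r <- assess_eligibility(rec(strrep("a", 399), strrep("t", 20)))
  expect_equal(r$reason, "abstract_too_short")
  r <- assess_eligibility(rec(strrep("a", 500), strrep("t", 14)))
  expect_equal(r$reason, "title_too_short")
  r <- assess_eligibility(rec(strrep("a", 10), strrep("t", 5)))
  expect_equal(r$reason, "both_too_short")

  # surrounding whitespace is stripped before counting; unicode is counted
  # in code points, not bytes
  r <- assess_eligibility(rec(paste0("  ", strrep("é", 400), "  "),
                              strrep("t", 15)))
  expect_equal(r$route, "machine")
})

test_that("lengthening either field never flips machine to manual", {
  set.seed(9)
  for (k in 1:50) {
    a <- strrep("a", sample(0:450, 1)); t <- strrep("t", sample(0:20, 1))
    base <- assess_eligibility(data.frame(record_id = "r", title = t,
                                          abstract = a))$route
    longer <- assess_eligibility(data.frame(
      record_id = "r", title = paste0(t, "xx"),
      abstract = paste0(a, "yy")))$route
    if (base == "machine") expect_equal(longer, "machine")
  }
})
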