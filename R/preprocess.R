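#' The bundled PubMed stopword list
#'
#' Returns the standard PubMed stopword list shipped with the package
#' (one lowercase token per line), or reads a user-supplied file in the same
#' format.
#'
#' @param path optional path to a custom stopword file (UTF-8, one lowercase
#'   token per line). Defaults to the packaged PubMed list.
#' @return character vector of stopword tokens.
#' @export
pubmed_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pubmed_stopwords.txt",
                                package = "rctscreen", mustWork = TRUE)
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words[nzchar(words)]
}

#' Tokenize text
#'
#' Lowercases and splits on any maximal run of non-alphanumeric characters;
#' pure-punctuation fragments are dropped, digits are retained. This is the
#' only tokenization used anywhere in the package, so n-gram features are
#' reproducible.
#'
#' @param text character vector (each element one document).
#' @return a list of character vectors of tokens (a single character vector
#'   if `text` has length one).
#' @export
#' @examples
#' tokenize("Randomized, controlled trial.")
tokenize <- function(text) {
  pieces <- strsplit(tolower(as.character(text)), "[^[:alnum:]]+")
  pieces <- lapply(pieces, function(x) x[nzchar(x)])
  if (length(pieces) == 1L) pieces[[1]] else pieces
}

#' Remove stopwords from a token sequence
#'
#' Exact whole-token match against a lowercase stopword set; the order of
#' surviving tokens is preserved. Removal happens *before* n-gram
#' extraction, so bigrams may span a removed stopword.
#'
#' @param tokens character vector of lowercase tokens.
#' @param stopwords character vector of lowercase stopwords.
#' @return filtered character vector.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!(tokens %in% stopwords)]
}

doc_ngrams <- function(tokens, n_min, n_max, unique_only = TRUE) {
  L <- length(tokens)
  out <- vector("list", n_max - n_min + 1L)
  for (n in n_min:n_max) {
    if (L < n) next
    if (n == 1L) {
      out[[n - n_min + 1L]] <- tokens
    } else {
      m <- embed(tokens, n)  # columns reversed
      out[[n - n_min + 1L]] <- do.call(paste, rev(as.data.frame(
        m, stringsAsFactors = FALSE)))
    }
  }
  ng <- unlist(out, use.names = FALSE)
  if (is.null(ng)) ng <- character(0)
  if (unique_only) unique(ng) else ng
}

#' Build an n-gram vocabulary
#'
#' Collects every contiguous within-document n-gram (over the post-stopword
#' token sequence) whose document frequency reaches `min_doc_freq`. Column
#' order is lexicographic by n-gram string (C locale), so vocabularies are
#' deterministic across platforms.
#'
#' @param corpus list of token character vectors (post-stopword).
#' @param n_range integer pair `(min_n, max_n)`, with
#'   `1 <= min_n <= max_n <= 3`.
#' @param min_doc_freq minimum number of documents an n-gram must occur in.
#' @return an object of class `rct_vocabulary`: a list with `ngrams`
#'   (sorted character vector; column j of a feature matrix is
#'   `ngrams[j]`), `n_range` and `min_doc_freq`.
#' @export
#' @examples
#' build_vocabulary(list(c("randomized", "controlled", "trial")),
#'                  n_range = c(1, 3), min_doc_freq = 1)
build_vocabulary <- function(corpus, n_range = c(1L, 1L), min_doc_freq = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop_validation("corpus must be a nonempty list of token vectors")
  n_min <- as.integer(n_range[1]); n_max <- as.integer(n_range[2])
  if (n_min < 1L || n_max > 3L || n_min > n_max)
    stop_validation("n_range must satisfy 1 <= min_n <= max_n <= 3")
  min_doc_freq <- as.integer(min_doc_freq)
  if (min_doc_freq < 1L) stop_validation("min_doc_freq must be positive")

  per_doc <- lapply(corpus, doc_ngrams, n_min = n_min, n_max = n_max)
  dt <- data.table::data.table(ng = unlist(per_doc, use.names = FALSE))
  if (nrow(dt) == 0L) {
    keep <- character(0)
  } else {
    counts <- dt[, .N, by = "ng"]
    keep <- counts$ng[counts$N >= min_doc_freq]
  }
  if (length(keep) == 0L)
    warning("empty vocabulary: no n-gram reaches min_doc_freq = ",
            min_doc_freq)
  structure(list(ngrams = sort(keep, method = "radix"),
                 n_range = c(n_min, n_max),
                 min_doc_freq = min_doc_freq),
            class = "rct_vocabulary")
}

#' Binary bag-of-words featurization
#'
#' Maps documents onto a sparse binary presence matrix over a fixed
#' vocabulary: cell (i, j) is 1 iff n-gram j occurs at least once in
#' document i (never a count). Out-of-vocabulary n-grams are ignored.
#'
#' @param docs list of token character vectors (post-stopword).
#' @param vocab an `rct_vocabulary`.
#' @return a `Matrix::dgCMatrix` of 0/1 values, `length(docs)` rows and
#'   `length(vocab$ngrams)` columns.
#' @export
vectorize <- function(docs, vocab) {
  stopifnot(inherits(vocab, "rct_vocabulary"))
  if (!is.list(docs)) docs <- list(docs)
  n_min <- vocab$n_range[1]; n_max <- vocab$n_range[2]
  per_doc <- lapply(docs, doc_ngrams, n_min = n_min, n_max = n_max)
  lens <- lengths(per_doc)
  i <- rep.int(seq_along(per_doc), lens)
  j <- match(unlist(per_doc, use.names = FALSE), vocab$ngrams)
  ok <- !is.na(j)
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1,
                       dims = c(length(docs), length(vocab$ngrams)),
                       dimnames = list(NULL, NULL))
}

#' Tokenized documents from records
#'
#' Title and abstract are concatenated (title, single space, abstract) into
#' one text per record, tokenized, and stopword-filtered.
#'
#' @param records record `data.frame`.
#' @param stopwords stopword vector; defaults to the packaged PubMed list.
#' @return list of token character vectors, one per record.
#' @export
prepare_documents <- function(records, stopwords = pubmed_stopwords()) {
  texts <- paste(records$title, records$abstract)
  toks <- strsplit(tolower(texts), "[^[:alnum:]]+")
  lapply(toks, function(x) {
    x <- x[nzchar(x)]
    x[!(x %in% stopwords)]
  })
}

#' Length-based machine/manual routing
#'
#' Records whose abstract is shorter than `min_abstract_chars` or whose
#' title is shorter than `min_title_chars` carry too little text for
#' reliable machine classification and are referred for manual screening.
#' Lengths are Unicode code points after stripping leading/trailing
#' whitespace (internal whitespace counts); the cutoffs are inclusive
#' minima.
#'
#' @param records record `data.frame` (or a single-record list with
#'   `title` and `abstract`).
#' @param min_abstract_chars minimum abstract length (default 400).
#' @param min_title_chars minimum title length (default 15).
#' @return a `data.frame` with columns `route` (`"machine"`/`"manual"`) and
#'   `reason` (`"ok"`, `"abstract_too_short"`, `"title_too_short"`,
#'   `"both_too_short"`), one row per record.
#' @export
#' @examples
#' rec <- data.frame(record_id = "r1", title = strrep("t", 15),
#'                   abstract = strrep("a", 400))
#' assess_eligibility(rec)
assess_eligibility <- function(records, min_abstract_chars = 400L,
                               min_title_chars = 15L) {
  abs_len <- nchar(trimws(records$abstract), type = "chars")
  tit_len <- nchar(trimws(records$title), type = "chars")
  abs_short <- abs_len < min_abstract_chars
  tit_short <- tit_len < min_title_chars
  reason <- ifelse(abs_short & tit_short, "both_too_short",
            ifelse(abs_short, "abstract_too_short",
            ifelse(tit_short, "title_too_short", "ok")))
  data.frame(route = ifelse(reason == "ok", "machine", "manual"),
             reason = reason, stringsAsFactors = FALSE)
}
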