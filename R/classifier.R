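#' SVM training configuration
#'
#' @param ngram_range integer pair, n-gram range for this SVM's vocabulary;
#'   must lie within (1,1)..(1,3).
#' @param oversample logical; oversample the minority class to parity
#'   before training (the SVM2 strategy).
#' @param cost positive soft-margin cost C of the hinge loss (the inverse
#'   regularization strength of the L2 penalty).
#' @param tol dual convergence tolerance (maximum projected-gradient
#'   violation per epoch).
#' @param max_iter maximum training epochs.
#' @param min_doc_freq minimum document frequency for vocabulary entries;
#'   default 2 for multi-gram vocabularies, 1 for unigram (unbounded
#'   trigram vocabularies are memory-hostile).
#' @param seed integer seed driving oversampling draws and the solver's
#'   coordinate shuffles.
#' @return an `rct_svm_config` list.
#' @export
svm_config <- function(ngram_range = c(1L, 3L), oversample = FALSE,
                       cost = 1.0, tol = 1e-4, max_iter = 5000L,
                       min_doc_freq = NULL, seed = 1L) {
  ngram_range <- as.integer(ngram_range)
  if (ngram_range[1] != 1L || ngram_range[2] < 1L || ngram_range[2] > 3L)
    stop_validation("ngram_range must be within (1,1)..(1,3)")
  if (cost <= 0 || tol <= 0 || max_iter < 1L)
    stop_validation("cost, tol must be positive and max_iter >= 1")
  min_doc_freq <- min_doc_freq %||% (if (ngram_range[2] > 1L) 2L else 1L)
  structure(list(ngram_range = ngram_range, oversample = isTRUE(oversample),
                 cost = cost, tol = tol, max_iter = as.integer(max_iter),
                 min_doc_freq = as.integer(min_doc_freq),
                 seed = as.integer(seed)),
            class = "rct_svm_config")
}

#' Oversample the minority class to parity
#'
#' Returns all original row indices plus additional minority-class indices
#' sampled with replacement until the minority count equals the majority
#' count. Used for SVM2's training set only; calibration and validation
#' data are never resampled.
#'
#' @param labels binary 0/1 vector.
#' @param seed integer seed (draws are reproducible).
#' @return integer index vector of length `2 * max(class counts)`.
#' @export
#' @examples
#' idx <- oversample_minority(c(rep(1, 5), rep(0, 95)), seed = 1)
#' table(c(rep(1, 5), rep(0, 95))[idx])
oversample_minority <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_validation("cannot oversample without both classes")
  if (n1 == n0) return(seq_along(labels))
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  pool <- which(labels == minority)
  extra <- with_seed(seed, sample(pool, need, replace = TRUE))
  c(seq_along(labels), extra)
}

#' Train a linear SVM on binary bag-of-words features
#'
#' Fits the linear decision function f(x) = w.x + b minimizing hinge loss
#' plus an L2 penalty at the configured cost, by dual coordinate descent.
#' If `config$oversample` is set, training rows are first expanded via
#' [oversample_minority()]. Training is deterministic given data and
#' `config$seed`.
#'
#' @param features sparse binary `dgCMatrix` (documents x n-grams).
#' @param labels binary 0/1 vector, one per row.
#' @param config an [svm_config()].
#' @param vocab the `rct_vocabulary` the columns of `features` come from
#'   (stored in the model so new text can be featurized identically).
#' @return an `rct_svm` list: `weights`, `intercept`, `vocab`, `config`,
#'   `converged`, `epochs`.
#' @export
train_svm <- function(features, labels, config = svm_config(), vocab = NULL) {
  labels <- as.integer(labels)
  if (nrow(features) == 0L || nrow(features) != length(labels))
    stop_validation("features and labels must align and be nonempty")
  if (!is.null(vocab) && ncol(features) != length(vocab$ngrams))
    stop_validation("feature columns do not match vocabulary size")
  if (all(Matrix::rowSums(features != 0) == 0))
    stop_validation("degenerate input: all feature rows are zero")
  if (config$oversample) {
    idx <- oversample_minority(labels, seed = config$seed)
    features <- features[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  if (length(unique(labels)) < 2L)
    stop_validation("both classes must be present to train")

  Xt <- Matrix::t(features)
  Xt <- rbind(Xt, Matrix::Matrix(1, nrow = 1, ncol = ncol(Xt), sparse = TRUE))
  Xt <- methods::as(Xt, "CsparseMatrix")
  y <- ifelse(labels == 1L, 1.0, -1.0)
  fit <- dcd_svm_fit(Xt, y, C = config$cost, tol = config$tol,
                     max_epochs = config$max_iter, seed = config$seed)
  if (!fit$converged)
    warning("SVM solver did not converge within ", config$max_iter,
            " epochs (violation ", signif(fit$violation, 3), ")")
  p <- ncol(features)
  structure(list(weights = fit$w[seq_len(p)], intercept = fit$w[p + 1L],
                 vocab = vocab, config = config,
                 converged = fit$converged, epochs = fit$epochs),
            class = "rct_svm")
}

#' Margin scores of a trained SVM
#'
#' Returns the signed distance surrogate w.x + b per document, with no
#' transformation (calibration to probabilities is a separate step).
#'
#' @param model an `rct_svm`.
#' @param features sparse feature matrix with columns matching the model's
#'   vocabulary.
#' @return numeric vector of margin scores.
#' @export
svm_margin <- function(model, features) {
  stopifnot(inherits(model, "rct_svm"))
  if (ncol(features) != length(model$weights))
    stop_validation("feature columns (", ncol(features),
                    ") do not match model weights (", length(model$weights), ")")
  as.numeric(features %*% model$weights) + model$intercept
}

#' Margin scores of the two-SVM ensemble
#'
#' Featurizes records with each SVM's own vocabulary and returns an n x 2
#' matrix: column 1 the uni/bi/tri-gram SVM's margin, column 2 the
#' oversampled unigram SVM's margin.
#'
#' @param bundle an `rct_model_bundle` (or any list with `svm1`, `svm2`
#'   carrying vocabularies) from [train_and_calibrate()].
#' @param records record `data.frame`.
#' @param stopwords stopword list used at training time.
#' @return numeric matrix with columns `svm1`, `svm2`.
#' @export
ensemble_scores <- function(bundle, records,
                            stopwords = pubmed_stopwords()) {
  docs <- prepare_documents(records, stopwords = stopwords)
  s1 <- svm_margin(bundle$svm1, vectorize(docs, bundle$svm1$vocab))
  s2 <- svm_margin(bundle$svm2, vectorize(docs, bundle$svm2$vocab))
  cbind(svm1 = s1, svm2 = s2)
}
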