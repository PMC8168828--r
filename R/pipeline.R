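#' Train the SVM ensemble and calibrate the recall threshold
#'
#' End-to-end model building: trains SVM1 (uni/bi/tri-gram) and SVM2
#' (unigram, minority class oversampled to parity) on the labeled training
#' corpus, then fits the Platt calibrator on the two margin scores of the
#' labeled calibration corpus and selects the classification threshold as
#' the largest probability achieving `target_recall` there. All randomness
#' (oversampling draws, solver shuffles) flows from `seed` via fixed
#' offsets, so identical inputs give identical bundles.
#'
#' @param training labeled record `data.frame` (both classes present).
#' @param calibration labeled record `data.frame` (both classes present).
#' @param target_recall mandated recall on the calibration set
#'   (default 0.99).
#' @param stopwords stopword list; default the packaged PubMed list.
#' @param cost,tol,max_iter SVM solver settings, see [svm_config()].
#' @param seed integer master seed.
#' @return an `rct_model_bundle`: `svm1`, `svm2`, `calibrator`,
#'   `threshold` (numeric), `threshold_report` (`rct_threshold`),
#'   `target_recall`, `seed`, `version`.
#' @export
train_and_calibrate <- function(training, calibration, target_recall = 0.99,
                                stopwords = pubmed_stopwords(),
                                cost = 1.0, tol = 1e-4, max_iter = 5000L,
                                seed = 1L) {
  for (nm in c("training", "calibration")) {
    corp <- get(nm)
    if (anyNA(corp$label))
      stop_validation(nm, " corpus contains unlabeled records")
    if (length(unique(corp$label)) < 2L)
      stop_validation(nm, " corpus must contain both classes")
  }
  docs_tr <- prepare_documents(training, stopwords = stopwords)

  cfg1 <- svm_config(ngram_range = c(1L, 3L), oversample = FALSE,
                     cost = cost, tol = tol, max_iter = max_iter,
                     seed = seed)
  vocab1 <- build_vocabulary(docs_tr, n_range = cfg1$ngram_range,
                             min_doc_freq = cfg1$min_doc_freq)
  svm1 <- train_svm(vectorize(docs_tr, vocab1), training$label,
                    config = cfg1, vocab = vocab1)

  cfg2 <- svm_config(ngram_range = c(1L, 1L), oversample = TRUE,
                     cost = cost, tol = tol, max_iter = max_iter,
                     seed = seed + 1L)
  vocab2 <- build_vocabulary(docs_tr, n_range = cfg2$ngram_range,
                             min_doc_freq = cfg2$min_doc_freq)
  svm2 <- train_svm(vectorize(docs_tr, vocab2), training$label,
                    config = cfg2, vocab = vocab2)

  bundle <- structure(list(svm1 = svm1, svm2 = svm2, calibrator = NULL,
                           threshold = NULL, threshold_report = NULL,
                           target_recall = target_recall,
                           seed = as.integer(seed), version = "rctscreen-1"),
                      class = "rct_model_bundle")
  sc <- ensemble_scores(bundle, calibration, stopwords = stopwords)
  bundle$calibrator <- fit_platt(sc, calibration$label)
  p <- predict_probability(bundle$calibrator, sc)
  bundle$threshold_report <- select_threshold(p, calibration$label,
                                              target_recall)
  bundle$threshold <- bundle$threshold_report$threshold
  bundle
}

#' @export
print.rct_model_bundle <- function(x, ...) {
  cat(sprintf(paste0("RCT classifier bundle (%s)\n",
                     "  SVM1: %d uni/bi/tri-gram features\n",
                     "  SVM2: %d unigram features (oversampled)\n"),
              x$version, length(x$svm1$weights), length(x$svm2$weights)))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold %.6f at target recall %.2f\n",
                x$threshold, x$target_recall))
  invisible(x)
}

#' Classify records with a calibrated bundle
#'
#' Applies the length routing rule, scores machine-routed records with both
#' SVMs, calibrates the scores to a probability, and calls an RCT when the
#' probability is at or above the bundle's threshold (inclusive).
#' Manual-routed records get no probability or class call unless
#' `score_all = TRUE` (the secondary-analysis mode, where every record is
#' machine-classified regardless of routing).
#'
#' @param bundle a calibrated `rct_model_bundle`.
#' @param records record `data.frame`.
#' @param score_all score manual-routed records too (default `FALSE`).
#' @param stopwords stopword list.
#' @return prediction `data.frame`: `record_id`, `route`, `reason`,
#'   `svm1_margin`, `svm2_margin`, `probability`, `is_rct`, in input order.
#' @export
classify_records <- function(bundle, records, score_all = FALSE,
                             stopwords = pubmed_stopwords()) {
  stopifnot(inherits(bundle, "rct_model_bundle"))
  if (is.null(bundle$threshold))
    stop_validation("bundle has no threshold: calibrate before classifying")
  routing <- assess_eligibility(records)
  n <- nrow(records)
  out <- data.frame(record_id = as.character(records$record_id),
                    route = routing$route, reason = routing$reason,
                    svm1_margin = rep(NA_real_, n),
                    svm2_margin = rep(NA_real_, n),
                    probability = rep(NA_real_, n),
                    is_rct = rep(NA, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  score_rows <- if (score_all) rep(TRUE, n) else routing$route == "machine"
  if (any(score_rows)) {
    sc <- ensemble_scores(bundle, records[score_rows, , drop = FALSE],
                          stopwords = stopwords)
    p <- predict_probability(bundle$calibrator, sc)
    out$svm1_margin[score_rows] <- sc[, 1]
    out$svm2_margin[score_rows] <- sc[, 2]
    out$probability[score_rows] <- p
    out$is_rct[score_rows] <- p >= bundle$threshold
  }
  out
}

#' Study-level validation on an included-studies corpus
#'
#' Runs the classifier over a corpus of included-study reports and
#' delegates to [study_level_recall()] with the bundle's threshold. In
#' `primary` mode manual-routed (short) reports are assumed found by manual
#' screening; in `secondary` mode every report is machine-classified. When
#' years are present, per-year lost-per-1,000 rates are attached via
#' [lost_by_year()] (a study's year is its earliest report year).
#'
#' @param bundle a calibrated `rct_model_bundle`.
#' @param validation record `data.frame`; `study_id` required on every row.
#' @param mode `"primary"` or `"secondary"`.
#' @param stopwords stopword list.
#' @return an `rct_study_loss` report.
#' @export
validate_on_included_studies <- function(bundle, validation,
                                         mode = c("primary", "secondary"),
                                         stopwords = pubmed_stopwords()) {
  mode <- match.arg(mode)
  if (any(is.na(validation$study_id)))
    stop_validation("validation corpus must carry study_id on every record")
  preds <- classify_records(bundle, validation, score_all = TRUE,
                            stopwords = stopwords)
  routing <- data.frame(route = preds$route, reason = preds$reason,
                        stringsAsFactors = FALSE)
  # scores exist for every record (score_all); the primary-mode retention
  # rule in study_level_recall ignores them for manual-routed reports
  loss <- study_level_recall(validation, preds$probability, routing,
                             bundle$threshold,
                             mode = mode)
  if (!all(is.na(validation$year))) {
    per_study_year <- loss$study_years
    known <- per_study_year[!is.na(per_study_year)]
    published <- table(known)
    loss <- lost_by_year(loss, stats::setNames(as.numeric(published),
                                               names(published)))
  }
  loss
}

#' Serialize a model bundle to JSON
#'
#' Writes both vocabularies, weight vectors, the calibrator, the threshold
#' and the configuration to a single versioned JSON file (text, so bundles
#' survive any archive or diff tooling).
#'
#' @param bundle an `rct_model_bundle`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "rct_model_bundle"))
  ser_svm <- function(m) list(weights = m$weights, intercept = m$intercept,
                              ngrams = m$vocab$ngrams,
                              n_range = m$vocab$n_range,
                              min_doc_freq = m$vocab$min_doc_freq,
                              config = unclass(m$config),
                              converged = m$converged, epochs = m$epochs)
  obj <- list(version = bundle$version,
              svm1 = ser_svm(bundle$svm1), svm2 = ser_svm(bundle$svm2),
              calibrator = unclass(bundle$calibrator),
              threshold = bundle$threshold,
              threshold_report = unclass(bundle$threshold_report),
              target_recall = bundle$target_recall, seed = bundle$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model bundle written by [write_bundle()]
#'
#' @param path JSON bundle file.
#' @return an `rct_model_bundle`.
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "rctscreen-1"))
    stop_format("unsupported bundle version: ", obj$version %||% "<none>")
  de_svm <- function(s) {
    vocab <- structure(list(ngrams = as.character(s$ngrams),
                            n_range = as.integer(s$n_range),
                            min_doc_freq = as.integer(s$min_doc_freq)),
                       class = "rct_vocabulary")
    structure(list(weights = as.numeric(s$weights),
                   intercept = as.numeric(s$intercept), vocab = vocab,
                   config = structure(s$config, class = "rct_svm_config"),
                   converged = s$converged, epochs = s$epochs),
              class = "rct_svm")
  }
  thr <- structure(obj$threshold_report, class = "rct_threshold")
  structure(list(svm1 = de_svm(obj$svm1), svm2 = de_svm(obj$svm2),
                 calibrator = structure(obj$calibrator,
                                        class = "rct_calibrator"),
                 threshold = obj$threshold, threshold_report = thr,
                 target_recall = obj$target_recall,
                 seed = as.integer(obj$seed), version = obj$version),
            class = "rct_model_bundle")
}
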