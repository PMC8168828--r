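#' Confusion table at a probability threshold
#'
#' The classification rule is inclusive: probability >= threshold is called
#' an RCT.
#'
#' @param probabilities numeric vector.
#' @param labels binary 0/1 vector.
#' @param threshold probability cutoff.
#' @return an `rct_confusion` list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(probabilities, labels, threshold) {
  if (length(probabilities) != length(labels))
    stop_validation("probabilities and labels must align")
  labels <- as.integer(labels)
  pos_call <- probabilities >= threshold
  structure(list(tp = sum(pos_call & labels == 1L),
                 fp = sum(pos_call & labels == 0L),
                 fn = sum(!pos_call & labels == 1L),
                 tn = sum(!pos_call & labels == 0L)),
            class = "rct_confusion")
}

confusion_table <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "rct_confusion")
}

#' Recall (sensitivity): TP / (TP + FN)
#' @param cm an `rct_confusion`.
#' @return numeric scalar.
#' @export
recall <- function(cm) {
  if (cm$tp + cm$fn == 0)
    stop_undefined_metric("recall undefined: no positive labels")
  cm$tp / (cm$tp + cm$fn)
}

#' Precision (positive predictive value): TP / (TP + FP)
#' @inheritParams recall
#' @return numeric scalar.
#' @export
precision <- function(cm) {
  if (cm$tp + cm$fp == 0)
    stop_undefined_metric("precision undefined: no positive calls")
  cm$tp / (cm$tp + cm$fp)
}

#' Specificity: TN / (TN + FP)
#' @inheritParams recall
#' @return numeric scalar.
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0)
    stop_undefined_metric("specificity undefined: no negative labels")
  cm$tn / (cm$tn + cm$fp)
}

#' Brier score: mean squared difference between probability and outcome
#' @param probabilities numeric vector in \[0, 1\].
#' @param labels binary 0/1 vector.
#' @return numeric scalar in \[0, 1\].
#' @export
brier_score <- function(probabilities, labels) {
  if (length(probabilities) == 0L)
    stop_undefined_metric("Brier score undefined on empty input")
  if (length(probabilities) != length(labels))
    stop_validation("probabilities and labels must align")
  mean((probabilities - as.numeric(labels))^2)
}

#' C statistic (concordance, AUROC)
#'
#' Probability that a randomly chosen positive record outscores a randomly
#' chosen negative one, ties counted one half. Computed by the Wilcoxon
#' midrank formula (O(n log n)); the package test suite checks it against
#' direct pair enumeration.
#'
#' @inheritParams brier_score
#' @return numeric scalar in \[0, 1\].
#' @export
c_statistic <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_undefined_metric("C statistic undefined without both classes")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration curve points
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on \[0, 1\]
#' and reports, per nonempty bin, the mean predicted probability, the
#' observed positive fraction, and the bin size.
#'
#' @inheritParams brier_score
#' @param n_bins number of equal-width bins (>= 2; default 10).
#' @return `data.frame` with columns `mean_predicted`, `observed_fraction`,
#'   `count`, empty bins omitted.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  if (n_bins < 2L) stop_validation("n_bins must be at least 2")
  if (length(probabilities) == 0L)
    stop_validation("empty input")
  labels <- as.integer(labels)
  bin <- pmin(floor(probabilities * n_bins), n_bins - 1L)
  agg <- data.table::data.table(p = probabilities, y = labels, bin = bin)
  out <- agg[, list(mean_predicted = mean(p),
                    observed_fraction = mean(y),
                    count = .N), by = "bin"]
  out <- out[order(out$bin)]
  data.frame(mean_predicted = out$mean_predicted,
             observed_fraction = out$observed_fraction,
             count = out$count)
}

#' Bootstrap internal validation of the calibrate-and-threshold procedure
#'
#' Implements resample-refit-evaluate internal validation: each replicate
#' resamples the calibration records with replacement, refits the Platt
#' calibrator *and reselects the recall threshold* on the resample (the
#' whole procedure is the unit being validated), then evaluates recall,
#' precision, specificity, C statistic and Brier score of that replicate's
#' calibrator and threshold on the original data. Point estimates come from
#' the full-data fit; confidence intervals are the 2.5/97.5 percentiles of
#' the replicate metrics. Resamples that draw a single class are redrawn
#' (logged); more than 10% redraws aborts with a diagnostic.
#'
#' @param scores n x 2 margin-score matrix for the calibration records.
#' @param labels binary 0/1 gold labels.
#' @param target_recall mandated recall (default 0.99).
#' @param n_reps number of bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param n_bins calibration-curve bins.
#' @return an `rct_eval_report`: `metrics` (named point estimates),
#'   `ci` (matrix with rows low/high), `threshold` (full-data
#'   `rct_threshold`), `calibrator`, `calibration_points`, `replicates`
#'   (n_reps x 5 metric matrix), `n_bootstrap`, `n_redraws`, `seed`.
#' @export
bootstrap_validate <- function(scores, labels, target_recall = 0.99,
                               n_reps = 5000L, seed = 1L, n_bins = 10L) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (n_reps < 2L) stop_validation("n_reps must be at least 2")
  if (length(unique(labels)) < 2L)
    stop_validation("both classes must be present")
  n <- nrow(scores)

  cal <- suppressWarnings(fit_platt(scores, labels))
  p_full <- predict_probability(cal, scores)
  thr <- select_threshold(p_full, labels, target_recall)
  cm <- confusion(p_full, labels, thr$threshold)
  point <- c(recall = recall(cm), precision = precision(cm),
             specificity = specificity(cm),
             c_statistic = c_statistic(p_full, labels),
             brier = brier_score(p_full, labels))

  metric_names <- names(point)
  reps <- matrix(NA_real_, n_reps, length(metric_names),
                 dimnames = list(NULL, metric_names))
  n_redraws <- 0L
  max_redraws <- ceiling(0.1 * n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws)
          stop_validation("bootstrap aborted: more than 10% of resamples ",
                          "contained a single class (", n_redraws,
                          " redraws); the data are too small or too ",
                          "imbalanced for resampling")
      }
      cal_r <- suppressWarnings(fit_platt(scores[idx, , drop = FALSE],
                                          labels[idx]))
      p_r_cal <- predict_probability(cal_r, scores[idx, , drop = FALSE])
      thr_r <- select_threshold(p_r_cal, labels[idx], target_recall)
      p_r_orig <- predict_probability(cal_r, scores)
      cm_r <- confusion(p_r_orig, labels, thr_r$threshold)
      reps[r, ] <- c(recall(cm_r), precision(cm_r), specificity(cm_r),
                     c_statistic(p_r_orig, labels),
                     brier_score(p_r_orig, labels))
    }
  })
  if (n_redraws > 0L)
    message(n_redraws, " single-class resample(s) redrawn")
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975))
  rownames(ci) <- c("low", "high")

  structure(list(metrics = point, ci = ci, threshold = thr,
                 calibrator = cal,
                 calibration_points = calibration_curve(p_full, labels,
                                                        n_bins = n_bins),
                 replicates = reps, n_bootstrap = n_reps,
                 n_redraws = n_redraws, seed = as.integer(seed)),
            class = "rct_eval_report")
}

#' @export
print.rct_eval_report <- function(x, ...) {
  cat("Bootstrap internal validation (", x$n_bootstrap, " replicates)\n",
      sep = "")
  for (m in names(x$metrics))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", m, x$metrics[[m]],
                x$ci["low", m], x$ci["high", m]))
  invisible(x)
}

#' Study-level loss accounting
#'
#' One trial (study) may have several published reports; a study is "lost"
#' only if *all* of its reports fall below the threshold. In `primary`
#' mode, manual-routed reports (too short for machine classification) are
#' assumed to be found by manual screening, so any manual-routed report
#' retains its study; in `secondary` mode every report is machine-classified
#' regardless of routing and a study is retained only by a report with
#' probability >= threshold.
#'
#' @param records record `data.frame`; every row must carry `study_id`.
#' @param probabilities probability vector aligned with `records`; `NA`
#'   allowed only for manual-routed records in primary mode.
#' @param routing routing `data.frame` from [assess_eligibility()].
#' @param threshold probability threshold.
#' @param mode `"primary"` or `"secondary"`.
#' @return an `rct_study_loss`: counts (`n_studies`, `n_retained`,
#'   `n_lost`), `study_recall`, `lost_study_ids`, `study_years` (named
#'   earliest report year per study, `NA` when unknown), `mode`,
#'   `threshold`, and `per_year_rates` (`NULL` until [lost_by_year()]).
#' @export
study_level_recall <- function(records, probabilities, routing, threshold,
                               mode = c("primary", "secondary")) {
  mode <- match.arg(mode)
  if (any(is.na(records$study_id)))
    stop_validation("every record needs a study_id for study-level recall")
  if (length(probabilities) != nrow(records))
    stop_validation("probabilities must align with records")
  machine <- routing$route == "machine"
  if (mode == "secondary" && anyNA(probabilities))
    stop_validation("secondary mode scores every record: no NA allowed")
  if (mode == "primary" && anyNA(probabilities[machine]))
    stop_validation("machine-routed records must have probabilities")

  hit <- !is.na(probabilities) & probabilities >= threshold
  retained_flag <- if (mode == "primary") (!machine) | (machine & hit) else hit

  dt <- data.table::data.table(study_id = records$study_id,
                               year = if (is.null(records$year))
                                 NA_integer_ else records$year,
                               retained = retained_flag)
  per_study <- dt[, list(retained = any(retained),
                         year = if (all(is.na(year))) NA_integer_
                                else min(year, na.rm = TRUE)),
                  by = "study_id"]
  lost <- per_study[!per_study$retained, ]
  structure(list(n_studies = nrow(per_study),
                 n_retained = sum(per_study$retained),
                 n_lost = nrow(lost),
                 study_recall = sum(per_study$retained) / nrow(per_study),
                 lost_study_ids = lost$study_id,
                 study_years = stats::setNames(per_study$year,
                                               per_study$study_id),
                 mode = mode, threshold = threshold,
                 per_year_rates = NULL),
            class = "rct_study_loss")
}

#' @export
print.rct_study_loss <- function(x, ...) {
  cat(sprintf(paste0("Study-level loss report (%s mode)\n",
                     "  studies   : %d\n  retained  : %d (%.1f%%)\n",
                     "  lost      : %d (%.1f%%)\n"),
              x$mode, x$n_studies, x$n_retained, 100 * x$study_recall,
              x$n_lost, 100 * (1 - x$study_recall)))
  invisible(x)
}

#' Studies lost per 1,000 published, by year
#'
#' Rates are 1000 * lost(year) / published(year). A study's year is the
#' earliest year among its reports; lost studies with no known year are
#' excluded from the rate map and counted separately.
#'
#' @param loss an `rct_study_loss` from [study_level_recall()].
#' @param published_per_year named count vector (names = years) of studies
#'   published per year.
#' @return the `rct_study_loss` with `per_year_rates` filled in: a
#'   `data.frame` (`year`, `published`, `lost`, `rate_per_1000`) plus an
#'   `unknown_year_lost` count.
#' @export
lost_by_year <- function(loss, published_per_year) {
  stopifnot(inherits(loss, "rct_study_loss"))
  lost_years <- loss$study_years[loss$lost_study_ids]
  unknown <- sum(is.na(lost_years))
  lost_years <- lost_years[!is.na(lost_years)]
  years <- as.integer(names(published_per_year))
  lost_counts <- table(factor(lost_years, levels = years))
  outside <- setdiff(unique(lost_years), years)
  if (length(outside) > 0L)
    stop_validation("lost studies in year(s) with no published count: ",
                    paste(outside, collapse = ", "))
  published <- as.numeric(published_per_year)
  if (any(published == 0 & as.numeric(lost_counts) > 0))
    stop_validation("published count is zero in a year with lost studies")
  loss$per_year_rates <- data.frame(
    year = years,
    published = published,
    lost = as.numeric(lost_counts),
    rate_per_1000 = 1000 * as.numeric(lost_counts) / published)
  loss$unknown_year_lost <- unknown
  loss
}
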