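ridge_logistic <- function(X, y, lambda = 1e-8, max_iter = 100L,
                           tol = 1e-10) {
  # Newton-Raphson with a tiny ridge penalty (intercept included in the
  # penalty; at lambda = 1e-8 this is numerically irrelevant but guarantees
  # a finite maximizer under complete separation).
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    step <- drop(solve(H, g))
    # damp the step: once the likelihood saturates the Hessian is nearly
    # the tiny ridge alone and an undamped Newton step overshoots wildly
    too_big <- max(abs(step))
    if (too_big > 5) step <- step * (5 / too_big)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = drop(beta), vcov = solve(H))
}

#' Fit the Platt-scaling calibrator
#'
#' A single maximum-likelihood logistic regression of the gold labels on the
#' two SVM margin scores (plus intercept), unregularized. The fit serves two
#' purposes at once: it ensembles the two SVMs (learning their relative
#' weights) and it converts margins to calibrated probabilities. Under
#' complete separation the fit falls back to a tiny ridge penalty (1e-8)
#' with a warning.
#'
#' @param scores n x 2 numeric matrix of margin scores
#'   (see [ensemble_scores()]).
#' @param labels binary 0/1 vector.
#' @return an `rct_calibrator`: `coefficients` (length 2), `intercept`,
#'   `se` (standard errors, intercept first), `method`.
#' @export
fit_platt <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (ncol(scores) != 2L)
    stop_validation("scores must have exactly 2 columns")
  if (nrow(scores) != length(labels))
    stop_validation("scores and labels must align")
  if (nrow(scores) < 10L)
    stop_validation("need at least 10 records to calibrate")
  if (length(unique(labels)) < 2L)
    stop_validation("both classes must be present to calibrate")

  df <- data.frame(y = labels, s1 = scores[, 1], s2 = scores[, 2])
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ s1 + s2, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # complete separation can also pass through glm silently (the deviance
  # plateaus near zero before any warning fires): no finite MLE exists when
  # the fitted direction splits the classes with zero overlap
  eta <- fit$linear.predictors
  if (!separated && length(unique(round(eta, 12))) > 1L &&
      min(eta[labels == 1]) > max(eta[labels == 0]))
    separated <- TRUE
  if (separated) {
    warning("(quasi-)separation in Platt fit; refitting with ridge 1e-8")
    X <- cbind(1, scores)
    rf <- ridge_logistic(X, labels, lambda = 1e-8)
    cf <- rf$coefficients
    se <- sqrt(diag(rf$vcov))
  } else {
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0  # collinear/constant score columns drop to zero
    se <- sqrt(diag(stats::vcov(fit, complete = TRUE)))  # NA when aliased
  }
  structure(list(coefficients = unname(cf[2:3]), intercept = unname(cf[1]),
                 se = unname(se), method = "platt"),
            class = "rct_calibrator")
}

#' Calibrated probability of reporting an RCT
#'
#' Inverse-logit of the calibrator's linear predictor; values are strictly
#' inside (0, 1) and strictly monotone in the linear predictor.
#'
#' @param calibrator an `rct_calibrator`.
#' @param scores n x 2 margin-score matrix.
#' @return numeric probability vector.
#' @export
predict_probability <- function(calibrator, scores) {
  stopifnot(inherits(calibrator, "rct_calibrator"))
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L)
    stop_validation("scores must have exactly 2 columns")
  eta <- calibrator$intercept + drop(scores %*% calibrator$coefficients)
  pmin(pmax(plogis(eta), 1e-15), 1 - 1e-15)
}

#' Select the classification threshold for a mandated recall
#'
#' Orders the calibration records by probability and scans every observed
#' value as a candidate threshold; returns the *largest* threshold t such
#' that the rule "probability >= t is an RCT" still achieves recall at or
#' above `target_recall` on the calibration labels. Taking the largest such
#' value maximizes the number of records automatically discarded (the
#' workload saving) subject to the recall mandate. Ties at the threshold
#' are all retained (the rule compares values, not ranks).
#'
#' @param probabilities calibrated probability vector.
#' @param labels binary 0/1 gold labels.
#' @param target_recall mandated recall in (0, 1]; default 0.99.
#' @return an `rct_threshold`: `threshold`, `achieved_recall`,
#'   `achieved_precision`, `n_discarded`, `discard_fraction`,
#'   `target_recall`.
#' @export
#' @examples
#' select_threshold(c(0.9, 0.8, 0.6, 0.4, 0.3), c(1, 1, 1, 0, 1),
#'                  target_recall = 0.75)
select_threshold <- function(probabilities, labels, target_recall = 0.99) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels))
    stop_validation("probabilities and labels must align")
  if (target_recall <= 0 || target_recall > 1)
    stop_validation("target_recall must be in (0, 1]")
  npos <- sum(labels == 1L)
  if (npos == 0L)
    stop_validation("no positive labels: recall target is undefined")

  ord <- order(probabilities, decreasing = TRUE)
  p_sorted <- probabilities[ord]
  pos_cum <- cumsum(labels[ord] == 1L)
  # last position of each distinct probability value = the point where the
  # rule "p >= t" has absorbed all records tied at t
  n <- length(p_sorted)
  last_of_value <- c(which(p_sorted[-n] != p_sorted[-1]), n)
  recall_at <- pos_cum[last_of_value] / npos
  hit <- which(recall_at >= target_recall)[1]  # first = largest threshold
  thr <- p_sorted[last_of_value[hit]]

  keep <- probabilities >= thr
  tp <- sum(keep & labels == 1L)
  structure(list(threshold = thr,
                 achieved_recall = tp / npos,
                 achieved_precision = tp / sum(keep),
                 n_discarded = sum(!keep),
                 discard_fraction = mean(!keep),
                 target_recall = target_recall),
            class = "rct_threshold")
}

#' @export
print.rct_threshold <- function(x, ...) {
  cat(sprintf(paste0("Recall-calibrated threshold\n",
                     "  threshold          : %.6f\n",
                     "  target recall      : %.4f\n",
                     "  achieved recall    : %.4f\n",
                     "  achieved precision : %.4f\n",
                     "  discarded          : %d (%.1f%%)\n"),
              x$threshold, x$target_recall, x$achieved_recall,
              x$achieved_precision, x$n_discarded,
              100 * x$discard_fraction))
  invisible(x)
}
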