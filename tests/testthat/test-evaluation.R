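test_that("confusion counts follow the inclusive-threshold rule", {
  cm <- confusion(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  cm2 <- confusion(0.5, 1, 0.5)
  expect_equal(cm2$tp, 1L)  # >= is inclusive
  cm0 <- confusion(numeric(0), integer(0), 0.5)
  expect_equal(unlist(cm0[c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 0L, fn = 0L, tn = 0L))
  expect_error(confusion(c(0.1, 0.2), 1, 0.5),
               class = "rctscreen_validation_error")
})

test_that("ratio metrics match their definitions, including undefined cases", {
  cm <- function(tp = 0, fp = 0, fn = 0, tn = 0)
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "rct_confusion")
  expect_equal(recall(cm(tp = 43783, fn = 224)), 43783 / 44007)
  expect_equal(round(100 * recall(cm(tp = 43783, fn = 224)), 1), 99.5)
  expect_equal(round(100 * recall(cm(tp = 54683, fn = 3600)), 1), 93.8)
  expect_equal(round(precision(cm(tp = 1, fp = 11)), 3), 0.083)
  expect_equal(precision(cm(tp = 5)), 1.0)
  expect_equal(precision(cm(tp = 0, fp = 3)), 0.0)
  expect_equal(specificity(cm(tn = 3, fp = 1)), 0.75)
  expect_equal(specificity(cm(tn = 4)), 1.0)
  expect_equal(specificity(cm(fp = 2)), 0.0)
  expect_error(recall(cm(tn = 5)), class = "rctscreen_undefined_metric")
  expect_error(precision(cm(fn = 5)), class = "rctscreen_undefined_metric")
  expect_error(specificity(cm(tp = 5)), class = "rctscreen_undefined_metric")
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(rep(0.5, 4), c(1, 0, 1, 1)), 0.25)
  expect_equal(brier_score(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_error(brier_score(numeric(0), integer(0)),
               class = "rctscreen_undefined_metric")
})

c_stat_pairs <- function(p, y) {
  # O(n^2) pair-enumeration oracle
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("C statistic: closed cases and equivalence with the pair oracle", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(c_statistic(c(0.9, 0.7, 0.6, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(c_statistic(c(0.1, 0.9), c(1, 1)),
               class = "rctscreen_undefined_metric")

  set.seed(31)
  for (k in 1:300) {
    n <- sample(4:200, 1)
    p <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    expect_equal(c_statistic(p, y), c_stat_pairs(p, y))
  }
})

test_that("calibration curve bins are equal-width with empty bins omitted", {
  pts <- calibration_curve(c(0.11, 0.12, 0.13, 0.19), c(1, 0, 1, 0),
                           n_bins = 10)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$observed_fraction, 0.5)
  expect_equal(pts$count, 4)
  expect_equal(pts$mean_predicted, mean(c(0.11, 0.12, 0.13, 0.19)))
  expect_error(calibration_curve(c(0.5), c(1), n_bins = 1),
               class = "rctscreen_validation_error")

  # perfectly calibrated labels land near the diagonal in every bin
  set.seed(32)
  p <- runif(50000)
  y <- rbinom(50000, 1, p)
  pts <- calibration_curve(p, y, n_bins = 10)
  expect_equal(nrow(pts), 10)
  expect_lt(max(abs(pts$mean_predicted - pts$observed_fraction)), 0.05)
})

make_scores <- function(n, seed, delta = 2) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.15)
  s1 <- rnorm(n, delta * y, 1.3)
  s2 <- rnorm(n, delta * y, 1.6)
  list(scores = cbind(s1, s2), labels = y)
}

test_that("bootstrap validation is seed-deterministic and respects the recall target", {
  d <- make_scores(400, seed = 41)
  r1 <- bootstrap_validate(d$scores, d$labels, target_recall = 0.9,
                           n_reps = 60, seed = 7)
  r2 <- bootstrap_validate(d$scores, d$labels, target_recall = 0.9,
                           n_reps = 60, seed = 7)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$metrics, r2$metrics)
  expect_gte(r1$metrics[["recall"]], 0.9)  # by construction on full data
  expect_true(all(r1$ci["low", ] <= r1$ci["high", ]))
  expect_equal(r1$n_bootstrap, 60)
  expect_equal(eval(formals(bootstrap_validate)$n_reps), 5000L)
})

test_that("bootstrap intervals narrow with sample size", {
  small <- make_scores(300, seed = 43)
  big <- make_scores(3000, seed = 43)
  ci_small <- bootstrap_validate(small$scores, small$labels, 0.9,
                                 n_reps = 120, seed = 9)$ci
  ci_big <- bootstrap_validate(big$scores, big$labels, 0.9,
                               n_reps = 120, seed = 9)$ci
  width <- function(ci) ci["high", "brier"] - ci["low", "brier"]
  expect_lt(width(ci_big), width(ci_small))
})

test_that("bootstrap aborts when resampling keeps drawing a single class", {
  set.seed(44)
  y <- c(1L, rep(0L, 9))
  scores <- cbind(rnorm(10, y), rnorm(10))
  expect_error(
    suppressMessages(bootstrap_validate(scores, y, 0.9, n_reps = 50,
                                        seed = 3)),
    "10%", class = "rctscreen_validation_error")
})

study_fixture <- function() {
  records <- data.frame(
    record_id = sprintf("r%d", 1:6),
    title = "t", abstract = "a",
    study_id = c("A", "A", "B", "B", "C", "D"),
    year = c(1995L, 1996L, 2000L, 2001L, NA, 2010L),
    stringsAsFactors = FALSE)
  routing <- data.frame(
    route = c("machine", "machine", "machine", "manual", "machine", "machine"),
    reason = c("ok", "ok", "ok", "abstract_too_short", "ok", "ok"),
    stringsAsFactors = FALSE)
  probs <- c(0.2, 0.8, 0.2, 0.3, 0.5, 0.1)
  list(records = records, routing = routing, probs = probs)
}

test_that("a study is lost only when all its reports fall below threshold", {
  f <- study_fixture()
  # primary: manual-routed report retains study B; p == threshold retains C
  r <- study_level_recall(f$records, f$probs, f$routing, threshold = 0.5,
                          mode = "primary")
  expect_equal(r$n_studies, 4)
  expect_equal(sort(r$lost_study_ids), "D")
  expect_equal(r$study_recall, 3 / 4)

  # secondary: B's manual report is machine-classified (0.3 < 0.5) -> lost
  r2 <- study_level_recall(f$records, f$probs, f$routing, threshold = 0.5,
                           mode = "secondary")
  expect_equal(sort(r2$lost_study_ids), c("B", "D"))
  expect_lte(r2$study_recall, r$study_recall)

  # boundary: single-report study exactly at threshold is retained
  expect_false("C" %in% r2$lost_study_ids)

  # missing study_id is a contract violation
  bad <- f$records; bad$study_id[1] <- NA
  expect_error(study_level_recall(bad, f$probs, f$routing, 0.5, "primary"),
               class = "rctscreen_validation_error")
})

test_that("study-level recall never falls below record-level recall", {
  set.seed(51)
  for (k in 1:20) {
    n_studies <- 40
    reps <- 1L + rpois(n_studies, 0.6)
    n <- sum(reps)
    records <- data.frame(record_id = sprintf("r%d", 1:n), title = "t",
                          abstract = "a",
                          study_id = rep(sprintf("s%d", 1:n_studies), reps),
                          year = NA_integer_, stringsAsFactors = FALSE)
    probs <- runif(n)
    routing <- data.frame(route = rep("machine", n), reason = rep("ok", n),
                          stringsAsFactors = FALSE)
    thr <- runif(1, 0.2, 0.8)
    r <- study_level_recall(records, probs, routing, thr, "secondary")
    record_recall <- mean(probs >= thr)
    expect_gte(r$study_recall, record_recall)
  }
})

test_that("lost-per-1000 rates divide by the published counts, unknown years set aside", {
  f <- study_fixture()
  loss <- study_level_recall(f$records, f$probs, f$routing, threshold = 0.6,
                             mode = "secondary")
  # lost: A (max 0.8? no: 0.8 >= 0.6 retains A) ... compute: retained iff any p >= 0.6
  expect_setequal(loss$lost_study_ids, c("B", "C", "D"))
  published <- c("1995" = 10, "2000" = 20, "2010" = 5)
  loss <- lost_by_year(loss, published)
  rates <- loss$per_year_rates
  expect_equal(rates$rate_per_1000[rates$year == 2000], 1000 * 1 / 20)
  expect_equal(rates$rate_per_1000[rates$year == 1995], 0)
  expect_equal(rates$rate_per_1000[rates$year == 2010], 1000 * 1 / 5)
  expect_equal(loss$unknown_year_lost, 1L)  # study C has no year

  expect_error(lost_by_year(loss, c("1995" = 10)),
               class = "rctscreen_validation_error")
})
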