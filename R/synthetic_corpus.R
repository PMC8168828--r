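default_signal_terms <- function() {
  # A small CONSORT-style lexicon of RCT-indicative terms with
  # class-conditional presence probabilities (p_rct >= p_bg). "trial" and
  # "enrolled" are deliberately common in the background too, so the
  # classifier must learn a weighted combination rather than one keyword.
  data.frame(
    term  = c("randomized", "trial", "placebo", "doubleblind",
              "allocation", "enrolled"),
    p_rct = c(0.95, 0.90, 0.60, 0.45, 0.40, 0.55),
    p_bg  = c(0.03, 0.25, 0.04, 0.01, 0.03, 0.12),
    stringsAsFactors = FALSE)
}

#' Synthetic corpus generator configuration
#'
#' Fixes every distributional knob of the synthetic corpora. Text is
#' synthesized as token sequences rendered to space-joined strings: the
#' classifier only ever sees a bag of words, so realistic grammar adds
#' nothing. Background tokens follow a Zipf law over an artificial
#' vocabulary; class signal is carried by RCT-indicative terms whose
#' presence probability differs between classes and, for truncated
#' abstracts, scales with `min(1, abstract_chars / 400)` (a cut-down
#' abstract genuinely loses signal).
#'
#' @param n_records number of records (training/calibration corpora).
#' @param n_studies number of studies (validation corpus).
#' @param prevalence RCT fraction in (0, 1); default 0.073, a typical
#'   screening prevalence.
#' @param signal_terms `data.frame` with columns `term`, `p_rct`, `p_bg`
#'   (`p_rct >= p_bg` required).
#' @param background_vocab_size size of the artificial background
#'   vocabulary.
#' @param zipf_exponent Zipf exponent of background token frequencies.
#' @param abstract_length_mean,abstract_length_sd target abstract length in
#'   characters for full-length records (truncated normal, min 420).
#' @param short_abstract_fraction fraction of records whose abstract falls
#'   below the 400-character machine cutoff (a tenth of these also get a
#'   sub-15-character title).
#' @param suppress_fraction fraction of calibration-corpus RCTs whose
#'   signal terms are suppressed to background rates (title/abstract give
#'   no indication of the trial; emulates full-text-only labels).
#' @param reports_per_study_mean mean reports per study (validation);
#'   default 1.618, i.e. roughly 1.6 reports per included study.
#' @param year_range integer pair of publication years (validation).
#' @param year_signal_slope slope of the signal-strength-by-year scaling:
#'   RCT signal probabilities are multiplied by
#'   `plogis(slope * standardized year)` (floored at the background rate),
#'   so older reports are weaker-signalled when the slope is positive.
#' @param nonrct_companion_fraction fraction of validation reports that are
#'   non-RCT companion records (editorials, pooled analyses) with label 0.
#' @param seed integer seed; all generators are deterministic given it.
#' @return an `rct_generator_config` list.
#' @export
generator_config <- function(n_records = 10000L, n_studies = 5000L,
                             prevalence = 0.073,
                             signal_terms = default_signal_terms(),
                             background_vocab_size = 2000L,
                             zipf_exponent = 1.05,
                             abstract_length_mean = 1200,
                             abstract_length_sd = 300,
                             short_abstract_fraction = 0,
                             suppress_fraction = 0.2,
                             reports_per_study_mean = 1.618,
                             year_range = c(1970L, 2016L),
                             year_signal_slope = 1.5,
                             nonrct_companion_fraction = 0.02,
                             seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop_validation("prevalence must be strictly inside (0, 1)")
  if (any(signal_terms$p_rct < signal_terms$p_bg))
    stop_validation("signal terms require p_rct >= p_bg")
  if (short_abstract_fraction < 0 || short_abstract_fraction >= 1)
    stop_validation("short_abstract_fraction must be in [0, 1)")
  if (suppress_fraction < 0 || suppress_fraction > 1)
    stop_validation("suppress_fraction must be in [0, 1]")
  if (reports_per_study_mean < 1)
    stop_validation("reports_per_study_mean must be at least 1")
  structure(list(n_records = as.integer(n_records),
                 n_studies = as.integer(n_studies),
                 prevalence = prevalence, signal_terms = signal_terms,
                 background_vocab_size = as.integer(background_vocab_size),
                 zipf_exponent = zipf_exponent,
                 abstract_length_mean = abstract_length_mean,
                 abstract_length_sd = abstract_length_sd,
                 short_abstract_fraction = short_abstract_fraction,
                 suppress_fraction = suppress_fraction,
                 reports_per_study_mean = reports_per_study_mean,
                 year_range = as.integer(year_range),
                 year_signal_slope = year_signal_slope,
                 nonrct_companion_fraction = nonrct_companion_fraction,
                 seed = as.integer(seed)),
            class = "rct_generator_config")
}

# background word list: fixed pseudo-words so tokenization is trivial and
# none collides with a signal term or stopword
background_words <- function(v) sprintf("word%04d", seq_len(v))

# Draw one record's title/abstract. `signal_mult` scales p_rct (floored at
# p_bg); signal presence additionally scales with abstract truncation.
synth_texts <- function(n, is_rct, cfg, signal_mult = rep(1, n)) {
  words <- background_words(cfg$background_vocab_size)
  zp <- 1 / seq_len(cfg$background_vocab_size)^cfg$zipf_exponent
  zp <- zp / sum(zp)
  tok_chars <- 9  # "wordXXXX" + space

  short <- runif(n) < cfg$short_abstract_fraction
  target <- ifelse(short,
                   runif(n, 0, 399),
                   pmax(420, rnorm(n, cfg$abstract_length_mean,
                                   cfg$abstract_length_sd)))
  n_tok <- pmax(0L, as.integer(round(target / tok_chars)))
  # a tenth of short records also get a too-short title
  short_title <- short & runif(n) < 0.1

  title_tok <- 5L + as.integer(round(runif(n, 0, 4)))
  all_tok <- n_tok + title_tok
  draws <- sample.int(cfg$background_vocab_size, sum(all_tok),
                      replace = TRUE, prob = zp)
  doc_of <- rep.int(seq_len(n), all_tok)
  toks <- split(words[draws], factor(doc_of, levels = seq_len(n)))

  st <- cfg$signal_terms
  len_factor <- pmin(1, pmax(target, 1) / 400)
  for (k in seq_len(nrow(st))) {
    p <- ifelse(is_rct, pmax(st$p_bg[k], st$p_rct[k] * signal_mult), st$p_bg[k])
    present <- runif(n) < p * len_factor
    for (d in which(present)) {
      pos <- sample.int(length(toks[[d]]) + 1L, 1L) - 1L
      toks[[d]] <- append(toks[[d]], st$term[k], after = pos)
    }
  }

  title <- vapply(seq_len(n), function(d) {
    tt <- utils::head(toks[[d]], title_tok[d])
    paste(tt, collapse = " ")
  }, character(1))
  title[short_title] <- substr(title[short_title], 1, 10)
  abstract <- vapply(seq_len(n), function(d) {
    at <- toks[[d]][-seq_len(min(title_tok[d], length(toks[[d]])))]
    paste(at, collapse = " ")
  }, character(1))
  list(title = title, abstract = abstract)
}

#' Generate a labeled synthetic training corpus
#'
#' Labels are Bernoulli(prevalence); tokens are background Zipf draws plus
#' class-conditional signal terms. Deterministic given `config$seed`.
#'
#' @param config an [generator_config()].
#' @return labeled record `data.frame` (see [read_records()] for columns).
#' @export
generate_training_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "rct_generator_config"))
  with_seed(config$seed, {
    n <- config$n_records
    lab <- rbinom(n, 1L, config$prevalence)
    tx <- synth_texts(n, lab == 1L, config)
    as_record_frame(list(record_id = sprintf("tr%06d", seq_len(n)),
                         title = tx$title, abstract = tx$abstract,
                         label = lab))
  })
}

#' Generate a synthetic calibration corpus
#'
#' Like the training generator, but a `suppress_fraction` of the RCTs have
#' their signal terms suppressed to background rates: their titles and
#' abstracts carry no indication of the trial, emulating gold labels made
#' from full-text reading. This makes the calibration set genuinely harder
#' than the training set.
#'
#' @inheritParams generate_training_corpus
#' @return labeled record `data.frame`.
#' @export
generate_calibration_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "rct_generator_config"))
  with_seed(config$seed, {
    n <- config$n_records
    lab <- rbinom(n, 1L, config$prevalence)
    suppressed <- lab == 1L & runif(n) < config$suppress_fraction
    mult <- ifelse(suppressed, 0, 1)
    tx <- synth_texts(n, lab == 1L, config, signal_mult = mult)
    as_record_frame(list(record_id = sprintf("ca%06d", seq_len(n)),
                         title = tx$title, abstract = tx$abstract,
                         label = lab))
  })
}

#' Generate a synthetic validation corpus of included studies
#'
#' Emulates a corpus of studies included in systematic reviews: each study
#' has `1 + Poisson(reports_per_study_mean - 1)` title-abstract reports,
#' report years are uniform over `year_range`, and the RCT signal strength
#' scales with `plogis(year_signal_slope * standardized year)`, so older
#' reports are weaker-signalled. A small fraction of reports are non-RCT
#' companion records (label 0); a `short_abstract_fraction` of reports fall
#' below the machine-classification length cutoffs.
#'
#' @inheritParams generate_training_corpus
#' @return record `data.frame` with `study_id` and `year` on every row.
#' @export
generate_validation_corpus <- function(config = generator_config(
                                         short_abstract_fraction = 0.25)) {
  stopifnot(inherits(config, "rct_generator_config"))
  with_seed(config$seed, {
    ns <- config$n_studies
    reps <- 1L + rpois(ns, config$reports_per_study_mean - 1)
    n <- sum(reps)
    study <- rep.int(sprintf("s%06d", seq_len(ns)), reps)
    yr <- config$year_range
    year <- as.integer(round(runif(n, yr[1], yr[2])))
    z <- (year - mean(yr)) / ((yr[2] - yr[1]) / sqrt(12))
    mult <- plogis(config$year_signal_slope * z)
    lab <- ifelse(runif(n) < config$nonrct_companion_fraction, 0L, 1L)
    tx <- synth_texts(n, lab == 1L, config, signal_mult = mult)
    rep_no <- sequence(reps)
    as_record_frame(list(
      record_id = sprintf("%s_r%d", study, rep_no),
      title = tx$title, abstract = tx$abstract,
      label = lab, study_id = study, year = year))
  })
}
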