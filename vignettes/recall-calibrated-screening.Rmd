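---
title: "Recall-calibrated RCT screening: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recall-calibrated RCT screening: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
what the synthetic data emulate and do not, and the numerical choices that
were genuinely open.

## The classification model

A title–abstract record is represented as a **binary** bag-of-words vector:
title and abstract are concatenated (title, one space, abstract),
lowercased, split on any run of non-alphanumeric characters (so hyphens and
slashes split; digits survive), filtered against the PubMed stopword list,
and mapped to presence/absence indicators over an n-gram vocabulary. The
representation is deliberately spartan: no stemming, no TF–IDF, no
embeddings. Binary presence is the point — "randomized" appearing five
times is no stronger evidence than appearing once, and phrase features
("randomized controlled trial" as a trigram) carry the compositional
signal instead.

Two linear soft-margin SVMs are trained on this representation:

* **SVM1**: uni/bi/tri-gram vocabulary (document frequency ≥ 2), raw class
  balance;
* **SVM2**: unigram vocabulary (document frequency ≥ 1), with the minority
  RCT class oversampled with replacement until it matches the majority
  count. Oversampling to exact parity is one canonical choice among many
  ("increase the rare class" does not pin a ratio); it is fixed here so
  results are reproducible. Only the training set is ever resampled.

Both solve hinge loss + L2 penalty at cost `C = 1` (the standard default
for binary text features, where feature scales are already comparable).
The solver is the dual coordinate descent algorithm for linear SVMs,
implemented in C++ for the package: document-linear cost is what makes a
~40,000-row oversampled trigram problem train in seconds, where a kernel
SMO solver is quadratic in documents. One consequence of the
implementation: the intercept is obtained by augmenting each document with
a constant feature, so it is L2-penalized like the weights (the common
linear-SVM-library convention). The solver visits documents in a freshly
shuffled order each epoch using a private seeded generator, so training is
bit-reproducible given the configuration seed and never touches R's global
RNG stream.

Decision values `w·x + b` ("margins") are reported untransformed; on
realistic corpora they fall roughly in the −3 to +3 range. They are not
probabilities and are never thresholded directly.

## Calibration and threshold selection

A single unregularized logistic regression of the gold labels on the two
margins (Platt scaling) does two jobs at once: its coefficients are the
ensemble weights, and its output is a calibrated probability. Regularizing
this fit would shrink the probabilities toward the prevalence and distort
calibration — the one thing the fit exists to provide — so none is used.
Under complete separation the maximum-likelihood estimate does not exist;
the fit then falls back to a tiny ridge penalty (1e-8) with a warning.
Separation is detected both from the usual fitted-probability warnings and
directly (no overlap between the classes' fitted linear predictors),
because the deviance can plateau before any warning fires.

The threshold is chosen on the **calibrated probabilities** of a held-out
calibration corpus: every observed probability value is a candidate, and
the selected threshold is the largest value whose inclusive rule
(`p ≥ t` ⇒ RCT) still achieves the mandated recall. Largest-such-value is
the only choice consistent with the workflow's economics: any lower
threshold would discard fewer records for no additional recall guarantee.
Ties at the threshold are all retained — the rule compares values, not
ranks. With at least one positive present the target is always attainable
(the minimum probability gives recall 1), so the procedure cannot fail,
only return a uselessly low threshold when the calibration set is too hard.

That regime matters and is worth understanding: at a recall target of
0.99, the procedure may miss at most 1% of calibration positives. If more
than ~1% of positives are indistinguishable from background (in the
generator: "suppressed" positives; in reality: abstracts that give no hint
of the trial), the threshold is forced down into the bulk of the negative
score distribution and the discard fraction collapses. With hard-but-not-
hopeless calibration sets the threshold sits in the weak tail of the
positive distribution and fifty-odd percent of records are discarded.

## Routing, study-level loss and per-year rates

Records with abstracts under 400 characters or titles under 15 characters
(inclusive minima, Unicode code points, ends-stripped) are routed to
manual screening: too little text for the classifier to be trusted.
Character counting on the concatenated raw fields was the main open
detail; code points with internal whitespace counted is the simplest
portable reading and is pinned by tests.

Validation corpora of included studies are scored at the **study** level: a
study is lost only if all of its reports fall below threshold. In primary
mode a manual-routed report retains its study outright (manual screening
is assumed perfect); secondary mode machine-classifies everything. Primary
study recall therefore dominates secondary whenever short reports exist,
and both dominate record-level recall. The package reports the full-corpus
denominator in both modes. Lost-per-1,000-published rates use the earliest
report year as the study's year; lost studies with no known year are
excluded from the rate map and counted separately.

## Bootstrap internal validation

`bootstrap_validate()` follows the resample–refit–evaluate scheme: each
replicate resamples records with replacement, refits the Platt calibrator
*and reselects the threshold* on the resample, then evaluates on the
original data. Re-selecting the threshold inside each replicate is a
deliberate choice: the threshold is part of the procedure under
validation, and holding it fixed would understate the uncertainty that the
recall interval is meant to display. Intervals are percentile (2.5/97.5)
over replicates; 5,000 replicates is the conventional default, and the
package's own tests use a few hundred at small n, which is where the
percentile interval is already stable to the displayed precision.
Single-class resamples are redrawn and counted; more than 10% redraws
aborts, since at that point percentile intervals on a conditioned
resampling distribution are no longer trustworthy. The C statistic is
computed by the Wilcoxon midrank formula and checked in the test suite
against exhaustive pair enumeration, including ties; the calibration curve
uses 10 equal-width bins (deciles of the probability axis) with empty bins
omitted.

## The synthetic corpus generator

The generator emulates the *statistical shape* of screening corpora, not
their language. Documents are sequences of pseudo-words (`word0042`) drawn
from a Zipf(1.05) distribution over a 2,000-word background vocabulary;
class signal is injected through a six-term RCT lexicon
(`randomized`, `trial`, `placebo`, `doubleblind`, `allocation`,
`enrolled`) with class-conditional presence probabilities chosen once:
strong enough that under 0.1% of full-length RCT abstracts carry no signal
term at all (so a 99% recall threshold lands above the background bulk),
with two terms (`trial`, `enrolled`) deliberately common in the background
so the classifier must weigh a combination. Defaults of note, all
overridable in `generator_config()`:

* `prevalence` 0.073 — a typical screening prevalence; calibration corpora
  conventionally use 0.032.
* `abstract_length_mean/sd` 1200/300 characters, truncated at 420 —
  full-length records comfortably clear the 400-character cutoff.
* `short_abstract_fraction` — 0 for training/calibration (those corpora
  are length-filtered upstream), 0.25 for validation, matching the
  roughly one quarter of included studies whose records fall below the
  length cutoffs in real corpora.
* `suppress_fraction` 0.2 — fraction of calibration RCTs whose signal is
  suppressed to background rates, emulating labels assigned from full text
  with uninformative abstracts.
* `reports_per_study_mean` 1.618 — the empirical reports-per-study ratio
  of large included-study corpora; implemented as 1 + Poisson(0.618).
* `year_range` 1970–2016 and `year_signal_slope` 1.5 — RCT signal
  probabilities are multiplied by `plogis(slope × standardized year)`
  (floored at the background rate), emulating the steady improvement in
  trial reporting after CONSORT: older reports are weaker-signalled and
  more often lost, newer ones almost never.
* Signal presence additionally scales with `min(1, chars/400)`, so a
  truncated abstract genuinely loses signal rather than carrying it in
  miniature — without this, short records would classify as well as long
  ones and length routing would be pointless.
* 2% of validation reports are non-RCT companions (editorials, pooled
  analyses) with label 0, so validation corpora are not artificially pure.

What passing tests on these corpora do **not** show: performance on real
abstracts. The generator has no syntax, no topical correlation between
background words, no near-duplicate records, no multilingual noise, and
its signal lexicon is exactly the one the classifier must find. Synthetic
results validate the *machinery* — threshold logic, loss accounting,
bootstrap, determinism — not the achievable operating point on any real
corpus.

## Problem sizes and numerical choices

The package's test suite trains on corpora of 1,500–8,000 records and
validates on up to 30,000 synthetic studies; the acceptance script uses
20,000-record training and calibration corpora. These sizes put every
stage (trigram vocabulary of a few hundred thousand entries, oversampled
training set of ~37,000 rows) on the same code paths as full-scale corpora
while keeping a complete run in minutes on one CPU.

Remaining numerical details, fixed for reproducibility: solver tolerance
1e-4 (maximum projected-gradient violation per epoch) with a 5,000-epoch
cap and a logged non-convergence flag; vocabulary order is lexicographic
in the C locale; probabilities are clamped to the open interval at 1e-15
so downstream logs never see exact 0 or 1; all generator and resampling
randomness flows from explicit integer seeds through RNG-state-preserving
wrappers, with the C++ solver using its own seeded stream.

## Known limitations

* The two SVMs differ only in n-gram range and oversampling; any further
  "minor differences" between ensemble variants in deployed systems are
  not modelled.
* The penalized intercept (constant-feature convention) differs from the
  textbook unpenalized SVM intercept; with thousands of features the
  difference is far below the calibration layer's noise floor, and the
  test suite's cross-check against an independent SMO implementation
  bounds it on a small corpus.
* Platt scaling assumes the margin–log-odds relation is linear; the
  calibration-curve output exists precisely to check this assumption on
  each corpus.
* The generator's year effect applies a single global slope; real
  reporting quality varies by field and journal.
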