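---
title: "Statistical validation of keyword search filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical validation of keyword search filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrievalqc)
```

Health researchers increasingly collect social-media messages with
boolean keyword filters and treat the retrieved set as "the data".
retrievalqc implements the statistical machinery for asking how good
that data actually is: what fraction of what the filter caught is
on-topic (retrieval precision), and what fraction of the on-topic
universe the filter caught at all (retrieval recall). This vignette
explains the models, the assumptions they lean on, the tunable
parameters, and the numerical choices baked into the implementation.

## The cross-tabulation and the classical case

Everything starts from the 2x2 table of filter decision against coded
relevance: `a` retrieved/relevant, `b` retrieved/irrelevant, `c`
unretrieved/relevant, `d` unretrieved/irrelevant, with margins
`n1 = a + b` and `n2 = c + d`. Precision is `a / (a + b)`, recall
`a / (a + c)`, specificity `d / (b + d)`, NPV `d / (c + d)`, and the
F-score combines precision and recall with a weight `beta` (F1 at
`beta = 1`).

Because on-topic content is rare (often ~2% of an archive), coding
samples are stratified by retrieval status with the retrieved stratum
heavily oversampled. Two consequences:

* counts coded on the sampling scale must be rescaled before recall is
  read off the table — `adjust_for_sampling()` multiplies the retrieved
  stratum by the ratio of sampling fractions (round-half-to-even per
  cell, margins recomputed from cells);
* recall is more conveniently computed through Bayes' theorem
  (`recall_bayes()`): `P * P(retr) / [P * P(retr) + u * (1 - P(retr))]`
  where `u` is the relevant fraction of the unretrieved coded sample.
  On an internally consistent table this is algebraically identical to
  `a / (a + c)`; the test suite checks the identity on a thousand
  random tables.

Interval estimation: simple proportions get Wald intervals by default
(this matches how such assessments are usually printed), with Wilson
and exact Clopper-Pearson selectable; Wald degenerates at boundary
counts, where the exact interval is substituted with a warning. The
Bayes-theorem recall depends on two estimated proportions, so
`recall_bayes_ci()` propagates both sampling variances with a seeded
parametric bootstrap (binomial resampling of each stratum's relevant
count); a first-order delta-method variant exists as a cross-check.
`P(retr)` comes from archive-level counts and is treated as known,
since the filter runs over the whole archive rather than a sample.

## When human coding is imperfect

If coders have perfect specificity but recall `S2 < 1` (a "silver
standard": they miss relevant content but do not invent it), naive
precision is biased downward and `corrected_precision()` applies
`a / (S2 (a + b))`. Inconsistent inputs can push this above 1; the
value is clamped to 1 with an explicit warning rather than silently
truncated. The assumption of near-perfect coder specificity is
plausible for topics where irrelevant messages are obviously
irrelevant, and it is the user's responsibility to say so in the
report.

## When the unretrieved messages were never archived

Many collections store only what the filter retrieved, so `c` and `d`
are unobservable and only `n1` and (approximately) `n2` are known.
`gibbs_unarchived()` treats the false-negative count as latent under
the single-classifier latent-class model: prevalence `pi`, filter
recall `S` and specificity `C` carry beta priors, and each Gibbs cycle

1. draws precision uniformly on its coded-sample confidence interval
   and sets `a = round(precision * n1)`;
2. draws `c ~ Binomial(n2, q)` where
   `q = (1 - S) pi / [(1 - S) pi + C (1 - pi)]`;
3. updates `pi`, `S`, `C` from their conjugate beta conditionals;
4. records NPV and the F1 of the cycle's precision and recall.

Redrawing precision every cycle is a deliberate choice where the
procedure could be read two ways: it propagates the precision
uncertainty into all posteriors, and it makes the posterior precision
interval reproduce the uniform's support. A flag
(`precision_redraw = FALSE`) gives the draw-once variant; a zero-width
interval fixes precision entirely.

This model is only weakly identified: the data constrain `a` and the
order of magnitude of `pi`, but `pi` and `S` trade off along a ridge
(more latent false negatives mean higher prevalence and lower recall).
Two practical consequences, both visible in the tests:

* the recall posterior is wide, and its mean is sensitive to the
  prevalence prior's upper tail;
* the latent count mixes slowly (a near-neutral random walk along the
  ridge), so posterior means from a single 100,000-cycle chain carry
  visible seed-to-seed Monte-Carlo error (a few hundredths for
  recall). The test suite therefore pins the sampler to an exact
  reference: by conjugacy the parameter integrals are analytic, so the
  exact posterior is a weighted sum over the latent count, computable
  by enumeration. The sampler is required to agree with this
  enumeration on small instances, which separates implementation
  defects from honest sampler noise.

Defaults mirror the standard configuration: 100,000 cycles, 10,000
burn-in, no thinning, single seeded chain.

## When neither classifier is a standard

With both the filter and human coding imperfect, each observed cell
splits into a latent count of truly relevant messages (`y1..y4`).
`gibbs_two_classifier()` samples these splits binomially and the five
parameters (`pi`, `S1`, `C1`, `S2`, `C2`) from conjugate betas,
assuming the two classifiers err independently given true relevance.
That conditional-independence assumption is the identifiability crutch
of this whole model family and is stated in every report; it is
plausible here because the filter errs on wording while coders err on
meaning, but it is untestable from the 2x2 table alone. Derived
precision, NPV and F1 for both classifiers are recorded per cycle from
the parameter draws. With informative data (thousands of messages) this
model is far better identified than the unarchived one and its
posterior means are stable across seeds. The same exact-enumeration
idea (now over the four latent splits) provides the test oracle.

## Prior elicitation

Published analyses often report priors only as a mean and a 95%
interval. `elicit_beta()` recovers `(alpha, beta)` by bounded least
squares on `(log alpha, log beta)`, weighting the mean heavily (it is
usually attainable exactly) and letting the endpoints absorb whatever
mismatch the beta family forces. Intervals are read as equal-tailed by
default even when a source labels them highest-density: HD targets are
non-unique for flat or one-sided densities, and for the interior
densities used here the two readings give similar shapes (both are
supported via `interval_kind`). Some printed prior rows are not
attainable by any beta distribution — e.g. a mean of 0.019 with a 95%
interval of (1e-6, 0.031) requires more left mass than any beta with
that mean can carry; the fit then returns the least-squares compromise
and warns. The resolved shapes are echoed in every report so a reader
can rerun the analysis without re-eliciting. `ecig_priors()` packages
the elicitations for the bundled e-cigarette case study.

HPD intervals are computed on the draws themselves (shortest window of
order statistics covering the requested mass), not on a fitted density
— matching the way MCMC summaries are customarily computed, and tested
against a density-grid oracle on known betas.

## Planning the coding budget

`design_scenario()` + `simulate_recall_ci()` answer "how many messages
must we code?" The scenario fixes archive size, assumed precision,
recall and retrieved proportion — prevalence is derived from those
three, so scenarios cannot be internally inconsistent — and simulates
stratified coded samples over a grid of unretrieved sample sizes `k`,
reporting the average recall-interval limits per `k`. Mean interval
length decreases in `k` with diminishing returns; the default scenario
(4M messages, precision 0.95, recall 0.84, retrieved proportion
0.0208, 3000 retrieved messages coded) reproduces the familiar shape
of that trade-off, and `recommend_sample_sizes()` picks the smallest
grid point meeting a target length. Strata are sampled binomially when
the sampling fraction is below 2% and hypergeometrically otherwise;
intervals inside the simulation use the same parametric bootstrap as
`recall_bayes_ci()`. Defaults (200 replicates, 200 bootstrap draws per
interval) are desk-scale: the per-`k` means are stable to a few
thousandths, which is enough to rank grid points.

## The filter engine and keyword screening

`search_filter()` compiles keyword lists (word, phrase, hashtag and
handle match modes) with optional boolean rules (AND/OR/NOT with
parentheses and quoted phrases) and co-occurrence vetoes.
Matching is case-insensitive at word boundaries (letters, digits and
underscore are word characters, so `e-cig` and `#vapelife` match as
units); hashtag mode matches with and without the sigil; handle-mode
keywords match messages authored by or mentioning the account and are
immune to vetoes. There is no stemming: filters in this domain
enumerate inflected forms explicitly, and silent stemming would change
the retrieved set in ways a report could not describe. Proximity
matching beyond exact phrases is deliberately out of scope.
`screen_keywords()` implements the two development-time discard rules:
fewer than 10 matches per calendar month, or coded precision below
0.30.

## The synthetic corpus generator

`generate_labeled_corpus()` and `simulate_outcomes()` make every
estimator testable without platform data: messages are relevant with a
configured prevalence, relevant texts embed topic terms, a configurable
fraction of irrelevant texts embed decoy phrases (the "smoking hot"
problem) so naive filters show false positives, and classifier
outcomes are drawn from conditionally independent Bernoulli mechanisms
with planted error rates. Text generation is bag-of-terms on purpose —
the statistical structure is the contract, not linguistic realism. What
passing tests show, therefore, is that the estimators recover planted
rates under the model's own assumptions; they cannot show robustness
to correlated classifier errors, topic drift, or adversarial language,
all of which real corpora contain.

## Numerical choices and degenerate inputs

* Binomial conditional probabilities of the form `x / (x + y)` are
  epsilon-guarded: both terms zero yields 0 (and 1 when only the
  denominator's second term vanishes), so degenerate parameter corners
  cannot produce NaN.
* `a = round(precision * n1)` uses round-half-to-even, as does the
  sampling-fraction adjustment.
* F at `P = R = 0` is defined as the limit value 0.
* All proportions are kept at full precision internally; rounding to
  printed decimals happens only in report formatting and in
  reproduction scripts that feed printed (rounded) constants on
  purpose.
* Chains are stored dense in memory (a 100,000-cycle run of the
  two-classifier model is ~10 MB); both samplers are bit-reproducible
  given a seed.

## Problem sizes used in the test suite

Unit tests run the samplers at reduced cycle counts (2,000-30,000)
on small instances where exact enumeration is available; the
full-configuration runs (100,000 cycles) appear once each in the
acceptance tests. Parameter-recovery tests use 20 seeded synthetic
datasets of 500,000 messages (two-classifier) and 200,000 messages
(unarchived) with reduced chains, checking recovery within three
posterior standard deviations. The design simulation runs 100
replicates per grid point. These sizes keep the full suite under a few
minutes while leaving every statistical claim tested at a scale where
its Monte-Carlo error is understood.

## Known limitations

* The unarchived model's recall estimate is prior-sensitive by
  construction; report priors alongside estimates (the report schema
  enforces this).
* Conditional independence of filter and coder is assumed, not tested.
* The filter engine tokenizes on word boundaries only; languages
  without spaces, emoji-carried meaning, and images are out of scope.
* `P(retr)` is treated as known; if the archive itself is a biased
  sample of the platform, both `P(retr)` and the unretrieved relevant
  fraction shift in opposite directions and recall estimates inherit
  that selection bias.
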