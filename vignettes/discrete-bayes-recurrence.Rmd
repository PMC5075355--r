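---
title: "Predicting early liver-cancer recurrence with a discrete Bayes decision rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting early liver-cancer recurrence with a discrete Bayes decision rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurbayes)
```

## The problem

After surgical resection of hepatocellular carcinoma, a large fraction of
patients recur within the first year. Predicting which patients will recur
lets clinicians target adjuvant therapy and surveillance. The available
predictors are routine laboratory and pathology markers — serum albumin,
indocyanine green retention, vascular invasion, platelet count, tumor
burden, and so on — a mix of continuous values and native categories.
Classical staging scores (Tokyo Score, Modified JIS, TNM) handle this mix
by summing physician-assigned points, but their marker combinations are
products of clinical trial and error, and a score cannot be computed at
all when one of its required markers is missing.

`recurbayes` implements an alternative: discretize every marker into
physician-defined *divisions*, represent a patient as the categorical
pattern of divisions, and classify by a discrete Bayes decision rule whose
fitted state is nothing but a table of per-class division counts. Around
the classifier it provides the full experimental protocol: resampling-based
optimal marker selection under a specificity constraint, holdout
evaluation, nested-subset learning curves, ROC operating points by marker
count, a diagnostic metric suite, and a summed-score staging engine for
comparisons.

## The model

Each marker $x_j$ is partitioned into $R_j \ge 2$ mutually exclusive,
jointly exhaustive divisions. A patient using $d$ selected markers is the
pattern $\mathbf{x} = [x_{1(r_1)}, \dots, x_{d(r_d)}]$, where $r_j$ is the
division their value falls into. With $n^i_{j(r_j)}$ the number of
class-$\omega_i$ training patients in division $r_j$ of marker $j$
($\omega_1$ = recurrence within one year, $\omega_2$ = nonrecurrence),
the single-division class-conditional probability is

$$P(x_{j(r_j)} \mid \omega_i) \;=\;
  \frac{n^i_{j(r_j)}}{\sum_{k=1}^{d} n^i_{k(r_k)}}.$$

The denominator deserves emphasis: it is the sum of the counts of the
divisions *this pattern occupies* across the $d$ selected markers — not
the class total $n^i$ that standard naive Bayes would use. This
pattern-dependent normalization makes the $d$ conditionals of each class
sum to one by construction, and it is what the package implements
throughout (the test suite checks the identity and cross-checks every
posterior against an independent direct evaluation). One behavioural
consequence worth knowing: at $d = 1$ the conditional is $1$ for any
division with a positive count, so both classes tie and the decision falls
to the tie-break — single-marker models are only informative when a
division count is zero in one class. This is a property of the rule as
defined, not an implementation artifact.

Divisions are assumed mutually independent given the class, so

$$P(\mathbf{x} \mid \omega_i) = \prod_{k=1}^{d} P(x_{k(r_k)} \mid \omega_i),
\qquad
P(\omega_i \mid \mathbf{x}) =
  \frac{P(\omega_i)\,P(\mathbf{x} \mid \omega_i)}
       {\sum_m P(\omega_m)\,P(\mathbf{x} \mid \omega_m)},$$

and a pattern is assigned to the class with maximal posterior. Priors
default to $0.5$ each, treating the classes equally.

```{r}
fit <- dbayes(hcc_training_counts(), markers = c("ALB", "tumor_burden"))
posterior(fit, c(ALB = 1, tumor_burden = 3))
```

## Tunable parameters

* **Priors** (`prior`, default `c(0.5, 0.5)`): per-class prior
  probabilities; set them to cohort prevalences if unequal class weighting
  is wanted.
* **Smoothing** (`smoothing`, default `0`): additive constant on every
  division count. The reference analysis uses raw counts; the default
  follows it. With raw counts a zero-count division annihilates its class
  (the joint conditional becomes 0), and a pattern with zero counts in
  *both* classes is degenerate — the posteriors are undefined and the
  prediction falls back to the tie-break. A small positive value (0.5 is
  conventional for count smoothing) removes both effects at the cost of
  biasing the conditionals toward uniformity.
* **Tie-break** (`tie_break`, default `"recurrence"`): the class predicted
  on exact posterior ties and degenerate patterns. The default errs toward
  not missing a recurrence, matching the clinical priority that motivates
  the whole design; it is configurable for applications with the opposite
  asymmetry.
* **Cutoff scheme**: divisions are physician-determined and shipped as
  editable YAML ([`hcc_marker_scheme()`] is the packaged reference).
  Boundary conventions follow the printed labels literally: "ALB > 3.5" is
  strict, so 3.5 falls in "ALB ≤ 3.5"; the tumor-burden band "4~9" is the
  closed interval $[4, 9]$ because its neighbours are "< 4" and "> 9". No
  automatic cutoff optimization is attempted. Marker units are implicit in
  the labels (the platelet cutoff "≥ 10", for instance, is stored
  verbatim); values are treated as unitless numbers.

Posteriors are evaluated in log space, so products over many markers do
not underflow; at small $d$ this agrees with the direct product to within
$10^{-12}$ relative tolerance (tested). Exact posterior ties are detected
by equality of the finished floating-point posteriors; with integer counts
and identical arithmetic on both sides, symmetric inputs tie exactly.

## Marker selection by resampling

Selecting which $d$ of the $M$ candidate markers to use is a feature-
selection problem, and with ~100 training records overfitting is the
danger. The package follows the virtual-sample strategy: for each subset
size, every combination of candidate markers is scored by $N$ resampling
trials. A trial splits the training set, stratified by class, into virtual
training and virtual test halves; the classifier is fitted on the former
and its sensitivity and specificity measured on the latter; means are
taken over the $N$ trials. Among combinations whose mean specificity meets
the constraint (default $\ge 0.5$), the one with maximal mean sensitivity
is the size's candidate, and the overall optimum is the candidate with
maximal mean sensitivity, ties to fewer markers.

Defaults and choices:

* **N = 100** trials per size, the reference protocol.
* **Virtual split fraction 0.5**, stratified, larger half to virtual
  training on odd class counts (so 29 + 89 training records split
  15 + 45 / 14 + 44). The same halving convention drives the holdout
  split, where it is forced by the reference cohort arithmetic
  (57 → 29/28, 177 → 89/88).
* **Search sizes 3..M−1** by default, the published search range;
  configurable down to singletons (see the $d = 1$ caveat above).
* **Constraint operator** `mean specificity >= threshold - 1e-9`: the
  tolerance keeps combinations whose mean is exactly the threshold from
  being dropped by floating-point representation.
* **Per-size ties** go to higher mean specificity, then to the
  lexicographically earlier marker set — deterministic and documented, as
  the reference procedure is silent.
* **Common random numbers**: all combinations of one size are scored on
  the *same* $N$ virtual splits. Each combination's score has the
  distribution the independent-trials procedure gives it, while
  between-combination comparisons are freed of split-to-split noise; it
  also lets the exhaustive search precompute each trial's count lookups
  once. `evaluate_combination()` with a size's derived seed reproduces the
  search's numbers exactly (tested).
* **Exhaustive enumeration only**: with $M = 10$ candidates the largest
  per-size search is $\binom{10}{5} = 252$ subsets; no heuristic search is
  needed or provided.

The whole search is deterministic given its master seed: per-size seeds,
and per-trial seeds within a size, are derived from it, and no package
operation touches the global RNG state (seeds are mandatory arguments
everywhere randomness occurs).

## Evaluation protocol

`holdout_split()` halves each class at random (larger half to training);
`metrics()` reports sensitivity, specificity, accuracy, Youden index
(sensitivity + specificity − 1), F1, and the diagnostic odds ratio
$(TP \cdot TN)/(FN \cdot FP)$, with DOR = ∞ when $FN \cdot FP = 0$ and
$TP \cdot TN > 0$. Raw values are kept; printing rounds to 2 decimals
half-up, the convention of published clinical tables (base R's
round-half-even would disagree with them on exact halves).

`reconstruct_confusion()` inverts a printed operating point: with 28
positives and 88 negatives, $TP = \mathrm{round}(0.86 \cdot 28)$ and
$TN = \mathrm{round}(0.49 \cdot 88)$ recover the integer matrix, and the
derived metrics of every published comparison column reproduce exactly
after 2-decimal rounding — the package's acceptance tests verify all four
systems and all four derived metrics, and an exhaustive check over all
29 × 89 matrices confirms the rounding round-trip is the identity on
operating points.

`learning_curve()` studies sample-size effects with nested training
subsets $S_1 \subset \dots \subset S_6$: per trial, each class's training
indices are permuted once and subsets are prefixes, so nesting holds by
construction. The reference protocol prints only $S_1 = (5, 15)$,
$S_2 = (6, 17)$ and the nesting relation; the default schedule linearly
interpolates from $S_2$ to the full training set in four further steps
(for 29/89 that is (12,35), (18,53), (23,71), (29,89)) and is fully
configurable. Trials default to 30. Confidence intervals are a normal
approximation across trial means (percentile intervals are available via
`ci = "percentile"`); the reference figures state a 95% level but not a
method, so the method is the package's choice and is stated here rather
than inferred.

`roc_points()` traces the classifier's ROC by marker count — the rule has
no score threshold to sweep — fitting one model per supplied combination
(either the per-size selection candidates or refit models; the caller
chooses what to pass) and adding the (0,0) and (1,1) anchors. Coincident
points are retained: marker counts with identical test performance are a
real phenomenon, not a plotting defect.

`evaluate_balanced()` implements the class-balanced re-evaluation: each of
100 repetitions subsamples `n_per_class` records per test class without
replacement and recomputes the metric suite. When the positive class has
exactly `n_per_class` members every repetition contains all of them, so
sensitivity is constant across repetitions while accuracy and F1 acquire
intervals — matching how the balanced comparison is reported. Subsampling
(rather than bootstrap) is the package's reading of "derived by the
resampling method"; the choice is documented here and localized in one
function.

## The synthetic-cohort generator

No patient-level data are distributed, and none are needed:

* `generate_cohort()` draws each record's division per marker
  independently from per-class categorical distributions — exactly the
  independence structure the classifier assumes — and emits raw values
  uniformly within each division's numeric interval, so discretization
  round-trips. It emulates the reference cohort's *structure* (two
  classes, categorical marginals); real cohorts have correlated markers
  (tumor burden and vascular invasion are certainly not independent), so
  passing tests on generated cohorts validates the machinery and the
  rule's behaviour under its own assumptions, not the clinical performance
  claims. Performance numbers on real data also depend on the joint
  distribution the generator deliberately does not model (copulas and
  correlated-marker generation are out of scope because the method itself
  assumes independence).
* `materialize_exact_counts()` realizes a division-count table exactly:
  per class and marker, the division multiset is laid out and shuffled
  independently across records. Marginal counts carry no joint
  information, so any consistent joint is a valid realization; the shuffle
  picks one at random. Recounting a materialized cohort reproduces the
  table identically (tested on the packaged reference table and on random
  tables), which is what makes the packaged counts a complete, shippable
  substitute for training data.

Generator defaults mirror the reference cohort: class sizes 29/89
(training) or 57/177 (full), and the packaged count table's frequencies
when probabilities are not supplied explicitly. The end-to-end recovery
test uses three markers at $(0.9, 0.1)$ vs $(0.1, 0.9)$ with 500 records
per class — well-separated but noisy marginals at a cohort size where
empirical frequencies are stable — and the selection recovery experiment
uses one such marker among nine uninformative ones at the reference
training size (29/89), $N = 100$, sizes 3–9, 20 generator seeds.

## Numerical and degenerate-input choices

* Division rules must be mutually exclusive and exhaustive; `discretize()`
  verifies both on the data it sees and errors (naming the value and
  marker) rather than guessing.
* Records with a missing value for a counted marker are excluded from that
  fit with a warning; classification of a record missing a *selected*
  marker is an error naming the marker. Staging scores are stricter still:
  all their markers are required, which is precisely their practical
  weakness relative to the classifier.
* A resampling trial whose virtual training half would lack a class
  cannot arise under the stratified splitter (each class needs at least
  one record on each side, enforced up front).
* `round_half_up()` is exported because half-up rounding at 2 decimals is
  part of reproducing published tables.

## Known limitations

* The independence assumption is untested on real data here, as it is in
  the reference analysis; Bayesian-network extensions are out of scope.
* Two-class only. The rule extends to more classes naturally, but this
  package does not.
* Division cutoffs are taken as given; optimizing them changes the
  method's degrees of freedom and is deliberately excluded.
* The packaged reference count table supports fitting and worked
  examples, but holdout/test performance of the reference cohort cannot
  be recomputed from counts alone — those experiments run on synthetic
  cohorts instead.

## Problem sizes used in the tests

The test suite fits models on cohorts of tens to hundreds of records,
runs the equation cross-check on 1000 random small count tables, the
exhaustive metric check on all 2581 matrices with 28 positives and 88
negatives, the selection consistency checks at $N$ = 12–30 trials, and
the full selection recovery experiment at $N = 100$ over 20 generator
seeds — sizes chosen to exercise every code path at the reference
protocol's own scale while keeping a full run of the suite to a couple of
minutes on one core.
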