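---
title: "Weighted tandems of classifiers: model, search protocol, and confidence triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted tandems of classifiers: model, search protocol, and confidence triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemfuse)
```

## The problem

Automated grading of histopathological slides is a four-class ordinal
problem: healthy tissue (G0) and carcinoma of grades G1–G3, with G2/G1
boundaries notoriously hard even for pathologists.  Individual classifiers
trained on CNN-extracted image features reach accuracies in the high
80s to mid 90s, but their errors are partly redundant: five of the six
learners in the reference stack consume the same 1024 CNN features, so a
simple majority would be dominated by their correlated mistakes.

`tandemfuse` implements the tandem approach: keep every classifier's full
*probability* output (four class-membership probabilities per sample
rather than a hard label), fuse the probabilities with one non-negative
weight per classifier, and let an evolutionary search find the weighting
that minimizes an ordinal misclassification penalty on validation data.
A second stage turns the fused probabilities into a triage rule that
splits predictions into a *trusted* set a pathologist can largely accept
and an *unreliable* remainder needing human review.

## The fusion model

With `M` classifiers, `K` classes and weights `w_1..w_M`, the fused score
of sample `i` for class `k` is the weight-normalized average

    s[i, k] = sum_j w_j p[j, i, k] / sum_j w_j

and the determined class `dc_i` is the argmax over `k`, ties broken toward
the lowest class index (the least severe grade).  Only relative weights
matter for the argmax, so the weights are not forced to sum to one;
instead each `w_j` is boxed to `[0, 1]` and the total is constrained to
`[0.5, 2]`, which rules out the all-zero corner and uniformly saturated
vectors while leaving the relative geometry free.  Dividing by `sum(w)`
does not change the argmax but keeps the fused rows on the unit simplex,
which the confidence stage needs: its threshold is interpreted as a
probability.  (The alternative — thresholding raw weighted sums — would
make the confidence grid meaningless whenever `sum(w) != 1`; this is the
package's resolution of a point the protocol leaves open, and it is the
only reading under which a threshold grid ending at 1.0 is sensible.)

The weight search minimizes the ordinal squared-distance fitness

    f(w) = sum_i | dc_i(w) - ac_i |^2

where `ac_i` is the actual grade on the integer scale 0..K−1.  Squaring
the grade distance makes an off-by-two error cost four times an
off-by-one error: confusing healthy tissue with grade-2 carcinoma is a
categorically worse failure than confusing adjacent grades.  When every
error is off-by-one the fitness reduces to the plain error count, and in
a two-class problem it *is* the error count.

## The differential-evolution search

The fitness is integer-valued and piecewise constant in `w`, so
gradient-based optimizers are useless here; a population metaheuristic is
the natural tool.  The package uses the canonical DE/rand/1/bin scheme:

* population of 50 candidate weight vectors, initialized uniformly in the
  box and repaired onto the feasible region;
* mutation `v = x_r1 + F (x_r2 - x_r3)` with distinct random members and
  differential weight `F = 0.6`;
* binomial crossover with probability `CR = 0.5` and one guaranteed
  coordinate;
* greedy one-to-one selection, ties kept by the parent;
* at most 1000 generations.

Constraint handling is repair-by-projection (`repair_weights()`):
coordinates are clipped to the box, then the vector is rescaled
multiplicatively onto the nearest violated sum bound and re-clipped,
iterated to a fixed point (at most 10 rounds; the all-zero vector maps to
the uniform vector at the lower sum bound).  Repairing rather than
penalizing keeps the fitness exactly as defined — the search only ever
evaluates feasible vectors, and the evaluator asserts this on every call.
"Convergence sooner" is made precise as: the best fitness unchanged for
50 consecutive generations *while* the population fitness spread is below
1e−8 (for this integer-valued fitness that effectively means the whole
population has collapsed to one fitness level).  Runs are bitwise
reproducible from a seed; the hot loop is compiled (Rcpp) with the R RNG,
the same split DEoptim uses.

For testing there is an exhaustive lattice oracle (`grid_oracle()`): the
fitness evaluated at every point of `{0, step, .., 1}^M` meeting the sum
constraint, with a 10^7-point guard.  The DE result must never be worse
than the lattice minimum; on panels whose optimum lies on the lattice the
two should tie.

## The Monte-Carlo protocol

Evaluation uses Monte-Carlo cross-validation: 40 independent uniform
random splits, each holding 2/3 of the samples for training (`floor`, so
357 samples give exactly 238 train / 119 held out and a pooled held-out
total of 4760 — which is why the fraction is the exact ratio 2/3, not a
rounded 0.67).  Splits are unstratified because the protocol calls for
plain random splits; a stratified option exists but defaults off.

The weight search runs 100 times.  Each run draws a random 20-of-40
subset of trials, pools their held-out samples, and optimizes the weights
there; the run's weighting is then scored by its plain misclassification
count on the pooled complementary 20 trials, and the overall winner is
the weighting with the lowest complementary error — i.e. the one that
extrapolates best beyond the trials it was tuned on.  Ties are broken by
the run's own-subset fitness, then by run index, so selection is
deterministic.  Complementary error is a plain error *count* (not the
squared-distance fitness) because that is what the selection rule calls
for; the squared penalty shapes the search, not the selection.  One
protocol ambiguity is resolved here: the validation/test distinction is
realized at the *trial* level (20 optimization trials vs 20 complementary
trials), not by halving samples within each trial; the per-sample reading
would shrink every optimization set to ~60 samples and make the
complementary counts incomparable across runs.

## Confidence triage

Applying the selected weighting to all 40 trials' held-out panels yields
pooled fused scores.  For a confidence threshold `T_conf`, a sample is
*trusted* when its top fused probability reaches the threshold
(`p_max >= T_conf`) and *unreliable* otherwise (strict `<`) — the
definitions overlap at equality if both are written with non-strict
inequalities, and the strict-`<` side is chosen for the unreliable set so
the two sets always partition the data.  A *failure* in either set is a
misclassified sample.  The sweep covers the inclusive grid 0.50, 0.55,
…, 1.00 (11 thresholds) on the pooled scores (one denominator, 4760 at
the default design), and the Pareto front keeps the nondominated
(percent trusted, percent trusted-but-wrong) points.  No calibration is
applied to the fused scores; the triage operates on the raw weighted
averages.

## The synthetic study conditions

The generator (`synthetic_spec()`, `generate_labels()`,
`generate_panel()`) emulates the features of the real study that the
method's behaviour depends on, with these defaults:

* grade composition 62 / 96 / 99 / 100 (G0..G3), 357 samples;
* six classifiers at the individual test accuracies observed for the
  RF / kNN / SVM / LR / NB / FTT+PCA stack (90.5, 93.89, 95.04, 94.2,
  86.76, 90.46 percent);
* error correlation `rho = 0.3`: each sample carries a latent difficulty
  `z_i ~ N(0,1)`; classifier `j` is correct when
  `sqrt(rho) z_i + sqrt(1-rho) e_ij` exceeds the normal quantile of
  `1 - a_j`, so marginal accuracy is exactly `a_j` while errors co-occur
  on difficult samples.  Wrong predictions land on a shared per-sample
  decoy grade with probability `rho`, so highly correlated stacks also
  agree on the wrong label.  The default 0.3 represents a stack of
  learners sharing one feature representation — correlated, but far from
  redundant; `rho = 0` gives the conditionally independent limit used by
  the ensemble-gain tests, and values near 1 reproduce the
  dominated-majority failure mode the weighting exists to fix;
* row sharpness `conc = 12`: probability rows are Dirichlet-style draws
  concentrated on the chosen class (expected top probability about 0.81
  for a correct call at K = 4; wrong calls use half the concentration,
  errors being less confident).  The swap trick — exchanging the maximum
  entry into the chosen class when a draw peaks elsewhere — makes the
  argmax exact, so realized accuracies match their targets to binomial
  noise.

What the generator does **not** emulate: the real stack's calibration
(per-classifier sharpness differences and overconfidence), class-specific
confusion structure (real G1/G2 confusions are asymmetric), and any
feature-space geometry — panels are sampled directly, not predicted from
images.  Passing tests therefore demonstrate the *mechanics* (fusion
arithmetic, search behaviour, protocol bookkeeping, triage invariants)
and the *statistical mechanism* of the ensemble gain, not the real-data
accuracy levels; in particular the fraction of samples trusted at a given
threshold depends directly on `conc` and should not be compared to the
real study's coverage numbers.

`planted_optimum_panel()` is the search oracle: it constructs a panel on
which a designated weighting classifies everything correctly while equal
weights fail on at least 10% of samples, by planting blocks where a
low-weight majority of classifiers is confidently wrong and the
high-weight minority is right.  The construction verifies its own margins
at build time and fails loudly if the requested weighting admits no
minority-by-count, majority-by-weight subset.

## Base-classifier adapters

The adapters exist so the full pipeline can run end-to-end on tabular
features; they stand on standard implementations (randomForest with 200
trees, `caret::knn3` with k = 2 and Euclidean distance, `e1071::svm` with
Platt-calibrated probabilities, ridge multinomial regression via glmnet
with the L2 = 10 total-loss penalty mapped to `lambda = 10/n`, Gaussian
naive Bayes) and every adapter's output must pass panel validation (rows
on the simplex within 1e−6).  The sixth classifier is a *stand-in*, not a
reproduction: a discrete Fourier cosine/sine transform of each feature
vector, principal-component reduction, and nearest-class-centroid scoring
softmaxed into probabilities.  The original trig-transform classifier is
specified elsewhere; what matters for the tandem is its role as a
decorrelated sixth view, which the stand-in provides.  CNN feature
extraction is out of scope — the adapters accept any fixed-width numeric
feature table.

## Numerical choices and degenerate inputs

* Probability rows off the simplex by at most 1e−6 are accepted as-is;
  by (1e−6, 1e−2] renormalized with a warning (tolerating two-decimal
  print round-off in upstream tools); beyond 1e−2 rejected with the row
  identified.
* Argmax ties break toward the lowest class index, everywhere (fusion,
  per-classifier predictions, the C++ evaluator), so results are
  reproducible and a tie never escalates a grade.
* Grid-oracle ties break lexicographically on the weight vector.
* Percent rounding is half-up to two decimals and applied only at
  presentation (65.273% of 4760 prints as 65.27).
* Pairwise agreement: Pearson on the flattened (sample x class)
  probability vectors; Cohen's kappa, unweighted, on predicted labels
  between classifier pairs (the agreement-between-classifiers reading;
  per-classifier kappa against ground truth is a different statistic and
  is not what the off-diagonal structure is needed for).  Zero-variance
  probability outputs and degenerate marginals yield `NA` with a warning
  rather than a fabricated coefficient.
* Patient-level recognition weights every patient equally (mean of
  per-patient correct fractions), so it equals image-level accuracy
  exactly when each patient contributes one image.

## Problem sizes used by the tests and the bundled script

The test suite exercises the full protocol at reduced sizes (3–5 trials,
2–3 weight-search runs, panels of 16–200 samples) and the statistical
contracts at the sizes where they are sharp: accuracy targets at n = 2000
per seed, ensemble gain at n = 5000 over 20 seeds, agreement limits at
n = 5000–10000, planted-optimum recovery over 100 seeded searches on a
200-sample, 6-classifier panel.  `scripts/acceptance.R` runs the complete
design — 40 trials, 100 weight-search runs at the full DE settings — on
the default synthetic conditions; it completes in a few minutes because
the evaluator is compiled and the search typically converges in 300–500
generations.

## Known limitations

* The synthetic generator's single sharpness parameter means coverage
  fractions in the confidence sweep are generator artifacts; only their
  monotone structure and the partition invariants carry over to real
  data.
* DE control parameters are fixed at the protocol values; no
  self-adaptive variants or restarts are provided.
* Per-classifier probability cutoffs (zeroing small probabilities before
  fusion) are deliberately not implemented; that family of variants was
  explored and abandoned upstream in favour of weights-only evolution.
* Model handles of trained adapters are in-memory only; the package
  serializes panels, labels, weights, plans and reports, not fitted
  models.
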