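---
title: "Classifying acute coronary syndrome subtypes: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying acute coronary syndrome subtypes: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsclass)
```

`acsclass` implements a complete four-class classification study for acute
coronary syndrome (ACS): STEMI, NSTEMI, unstable angina (UA), and a
residual "Other" group. This vignette is the package's own account of the
science inside it: the data model, the synthetic study conditions, the
eight classifiers, the wrapper feature selection, the validation protocol,
the probability metrics, and the numerical and design choices made where
the design was genuinely open. It states no empirical claim that the test
suite or `scripts/acceptance.R` does not itself recompute.

## The data model

A dataset is an n-by-40 matrix of coded clinical features plus one class
label per patient. The bundled schema (`default_schema()`) declares each
feature's measurement scale:

- **nominal / ordinal** features carry small integer codes (e.g. sex 1/2,
  Killip class 1–4, troponin elevation −1/+1) and are used *as those codes*
  in every downstream distance and arithmetic computation. No one-hot
  expansion is applied: the integer coding is the working representation
  throughout, so distances between ordinal codes respect their order and
  binary codes contribute 0/1 squared differences.
- **ratio** features (age, BMI, heart rate, systolic blood pressure,
  cholesterol, creatinine, glucose, hemoglobin) are measured on their raw
  clinical scales and min-max normalized to [−1, 1]:
  x′ = 2·(x − min)/(max − min) − 1. The transform is affine and never
  clipped, so values outside the fitted range map outside [−1, 1] and the
  order and relative spacing of raw measurements are preserved. A constant
  feature is flagged degenerate and maps to 0 with a warning — small
  synthetic fixtures stay usable instead of erroring.

Two normalization scopes are supported. The default, `"split"`, fits the
min/max statistics on each repetition's training part only, avoiding
leakage of test-set extremes into training. `"global"` fits once on the
full dataset; a study that normalizes a registry once before any analysis
behaves this way, so both are one flag apart in `repeated_evaluation()`.
Missing values are rejected at read time; no imputation is offered.

## The synthetic study conditions

Registry data of this kind cannot be redistributed, so
`default_acs_config()` defines the study conditions the package is
developed and tested against:

- n = 809 with class priors (0.2769, 0.1582, 0.5155, 0.0494) for
  (STEMI, NSTEMI, UA, Other); an exact-count mode reproduces given
  per-class counts deterministically (labels laid out, then the row order
  shuffled by the seed).
- Seven planted informative features — BMI (4), chronic lung disease (10),
  calcium-channel blockers (27), systolic blood pressure (30), troponin I
  elevation (31), hemoglobin (36) and ECG ST-T changes (40). Each carries a
  class-conditional law: Gaussian location shifts with a common spread on
  the raw scale for ratio features, explicit per-class code distributions
  for categorical ones. Everything else is class-independent noise
  (uniform over codes; a common Gaussian for ratio features).
- Features are conditionally independent given the class. Real clinical
  data has correlated features (BMI with blood pressure, age with
  creatinine); this generator deliberately does not. Passing recovery
  tests therefore shows the search behaves correctly under clean planted
  signal — not that it would recover the same subset from a real registry,
  where redundancy makes "the" informative subset ill-defined.

The effects encode the clinical signature of each subtype: troponin
elevation with ST elevation for STEMI, troponin elevation with ST
depression for NSTEMI, normal markers for UA, and an "Other" class that
overlaps UA in the markers but differs in hemoglobin and comorbidities.
Effect sizes were calibrated once, before freezing, to two requirements:
a tuned classifier reaches roughly 0.8 test accuracy at n ≈ 800, and each
planted feature's marginal contribution exceeds the Monte-Carlo resolution
of the wrapper search (about ±0.005 accuracy at 20 repetitions), so that
backward elimination can in principle retain it. They are a design choice
defining the synthetic conditions, not an estimate of any registry's
effect sizes.

All randomness flows through R's default Mersenne-Twister stream, seeded
once per generation call; draws happen in a fixed order (labels first, then
features in schema order), so output is bit-identical across platforms for
the same seed.

## The classifiers

All eight learners share one contract: `acs_fit(classifier_spec(...),
train, validation)` returns a classed model whose `predict()` emits hard
labels in 1..4. Metrics in this study are label-based, so no probability
outputs are exposed. Where the classical method descriptions leave
architecture or training details open, the package fixes them as follows
(all config-exposed):

- **GLM** — one regression per class against one-hot targets (one-vs-rest),
  fitted by iteratively reweighted least squares with the four
  distribution/link pairs: normal/identity, inverse-Gaussian/1/μ²,
  Poisson/log, gamma/1/μ; classification is the argmax of fitted means.
  For the identity link IRLS reduces to plain least squares in one step.
  One-hot targets sit on the boundary of the log and reciprocal links, so
  fitted means are clamped to [10⁻⁶, 1−10⁻⁶] before every link evaluation,
  and weights are floored at 10⁻⁸ of their maximum so boundary-clamped
  observations cannot drive the weighted design rank-deficient. An
  alternative encoding regresses the integer class label and rounds.
- **k-NN** — Euclidean distance on the coded/normalized features, default
  k = 7. All tie-breaks are deterministic: distance ties at the k-th
  neighbour resolve by training-row order; vote ties by the smaller mean
  neighbour distance, then the lower class index. The distance search runs
  in compiled code.
- **Naive Bayes** — empirical priors; categorical conditionals smoothed as
  (count + α)/(n_c + α·|codes|) with α = 1; per-class Gaussians with a
  10⁻⁹ variance floor for ratio features; log-space argmax.
- **ID3** — information gain in bits; multiway splits over categorical
  codes, binary midpoint thresholds for ratio features; growth stops at
  pure nodes, fewer than 2 samples, or zero gain. A categorical code unseen
  at a node during training falls through to that node's majority class.
- **Bagged ID3** — B = 50 seeded bootstrap resamples (size n, with
  replacement), plurality vote, ties to the lower class index. An identity
  resample hook makes B = 1 reduce exactly to plain ID3, which the tests
  exploit.
- **MLP** — one hidden layer, logistic sigmoids in both layers, one-hot
  targets, squared-error loss, full-batch backpropagation with momentum
  (classic settings: lr 0.5, momentum 0.9). Softmax/cross-entropy is
  deliberately not used; the sigmoid-plus-squared-error pairing matches
  the classic backpropagation formulation this study family uses. With
  early stopping (default) a validation set is required, the best
  validation-error weights are kept, and training halts after 30
  non-improving epochs. The hidden-node grid for model selection is 2–13,
  default 9.
- **RBF** — two-step hybrid: m = 7 Gaussian centers by seeded k-means,
  each center's spread set to the distance to its nearest other center (a
  single center falls back to the overall feature spread) — the method
  prescribes only "centers and spreads", so this standard heuristic was
  chosen for being parameter-free; then ridge least squares (λ = 10⁻⁸)
  from the activations to one-hot targets, with no bias unit so that
  centers at every distinct training point with λ = 0 interpolate exactly.
- **ANFIS-type neuro-fuzzy system** — a first-order Sugeno system on a
  grid partition (2 Gaussian membership functions per input, m^p rules,
  capped at 512 — beyond the cap the fit refuses and advises a feature
  subset). It is trained by the classic hybrid: ridge least squares for
  the consequents with premises fixed, then a normalized gradient step on
  the premise centers/spreads (numeric central differences), alternating
  per epoch with validation-based stopping. The single output regresses
  the integer class label; prediction decodes to the nearest label with
  ties to the lower one. Regressing an arbitrary label order is a known
  structural handicap — this learner is expected to trail the others, and
  does.

## Feature selection

The selector is sequential backward elimination wrapped around k-NN,
jointly optimized over the subset S and the neighbour count k:

1. For each k in the grid (default odd 3–13): start from the full feature
   set.
2. Each round, evaluate every leave-one-out candidate S \ {f} by the mean
   k-NN test accuracy over repeated stratified 0.7/0.3 splits (default 100
   repetitions), set S to the argmax candidate, and record every candidate,
   its accuracy, and the choice.
3. Stop when |S| = 1; report the global accuracy argmax over all (k,
   candidate) pairs evaluated, each k's full set included. Ties break
   toward the smaller subset, then the smaller k, then the earlier round.

Two design points matter. First, the split seeds derive only from the
master seed, never from the subset, so every candidate is scored on the
*same* splits — common random numbers remove split noise from subset
comparisons and make the whole search exactly replayable, which is also
what lets the tests compare the greedy path against exhaustive re-ranking.
Second, selection uses the whole dataset. Downstream accuracy estimates on
the same data therefore carry selection bias; this mirrors the
small-sample practice the pipeline reproduces and is deliberate. The
per-round trace keeps both the global argmax and the per-k bests, so a
"best subset per k, then best k" reading is recoverable from the same
search; the global argmax was chosen as the reported result because the
procedure's stated aim is joint optimization over (S, k).

The elimination loop evaluates all leave-one-out candidates of a round in
one compiled pass, computing each candidate's distances by subtracting the
removed feature's contribution from the full-subset distances.

## Validation and model selection

Repeated random sub-sampling: each repetition draws a fresh stratified
split, fits the normalizer on the training part, trains, and scores the
test part into a confusion matrix. Split fractions are 0.7/0.3 (two-way)
and 0.6/0.2/0.2 (three-way); the fractions are a package default, exposed
in `split_scheme()`. Stratification (largest-remainder apportionment of
class counts across parts, exact to ±1 sample) is on by default so the
4.9 % "Other" class appears in every part; it can be disabled.

Each learner has a protocol default: three-way splits for the kinds that
tune or stop on a validation part (ANFIS 50 repetitions, MLP 100, RBF
1000, bagged ID3 1000) and two-way with 1000 repetitions for the rest.
Per-repetition seeds are drawn once from the master seed (a seeded
`sample.int` of the integer range, one pair per repetition for the split
and the trainer), so runs are reproducible and repetitions never collide.
`model_select()` scores a hyperparameter grid by mean validation-part
misclassification over shared-seed repetitions and returns the minimizing
spec, ties to the smaller value; the test part is never touched during
tuning — it is not even passed in.

## Probability metrics

From a confusion matrix CM (rows = actual, columns = predicted):

- accuracy = trace / total, identically equal to the prior-weighted APM
  diagonal under empirical priors;
- APM: rows normalized — entry (i, j) is p(predicted j | actual i);
- CPM: the Bayes inversion CPMᵢⱼ = APMᵢⱼ p(cᵢ) / Σₖ APMₖⱼ p(cₖ). Under the
  empirical priors of the same matrix this is algebraically identical to
  column normalization of the counts, which the tests assert to 10⁻¹² and
  which serves as the independent oracle for the implementation.

Zero-support rows (APM) and columns (CPM) are set to zero and flagged,
never returned as NaN. Aggregation across repetitions is element-wise mean
and sample standard deviation (n−1; a single run reports 0 with a flag).
The per-run CPM mode — invert each repetition's APM, then average — is the
default because it keeps every per-run matrix column-stochastic; averaging
first and inverting once is available as `cpm_mode = "pooled"` and gives
different numbers. Note that the *mean* per-run CPM is column-stochastic
only in columns predicted at least once in every repetition; a rare class
can have a deficient column mean, which the flags make visible. Rounding
to two decimals happens only in printing, never in computation.

## Problem sizes in the tests and acceptance script

The full protocol (1000 repetitions per learner, six k values, 100
wrapper repetitions) is minutes-to-hours scale. The shipped tests and
`scripts/acceptance.R` exercise the identical code paths at reduced sizes
chosen as the package's standing verification budget: wrapper searches
with k ∈ {3, 7} and 20 repetitions (ten generator seeds for the recovery
check), 20–50 evaluation repetitions, 1000 random matrices for the
algebraic identities, and brute-force oracles at n ≤ 200. The recovery
check — Jaccard ≥ 0.6 against the planted subset in at least 8 of 10
seeds — is statistical by construction: near-optimal subsets differing by
one noise passenger or one weak informative feature are within Monte-Carlo
noise of each other, so occasional misses are expected and tolerated.

## Known limitations

- The generator's conditional-independence assumption understates the
  difficulty of real registry data; recovered subsets and accuracies on
  synthetic data say nothing quantitative about clinical performance.
- ANFIS regresses an arbitrary label order and predictably underperforms;
  it is included for completeness of the method comparison, not as a
  recommendation.
- The GLM's mean clamping makes the reciprocal-link fits differ from an
  unclamped IRLS wherever the unclamped mean would leave (0, 1); this is
  the documented, deliberate behaviour for one-hot targets.
- Backward elimination is greedy: with strongly redundant features it can
  drop a member of an informative group early and never recover it.
  Exhaustive verification is feasible (and tested) only for p ≤ 4.
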