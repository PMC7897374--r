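---
title: "Relaxometric learning: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxometric learning: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxlearn)
```

## The problem

A CPMG experiment samples the transverse-magnetization decay of a sample
as P uniformly spaced echo amplitudes. In heterogeneous biological
material the decay is multi-exponential — a mixture of water pools
("bound" water interacting with macromolecules at short T2, "free" water
at long T2 — so the curve shape encodes composition and physical state.
`relaxlearn` classifies these raw curves into two groups without fitting
a relaxation model, treating each time point as a feature and letting a
machine-learning classifier find the discriminating shape differences.

Two practical obstacles dominate this setting and motivate the framework:

1. **Uninformative late variables.** Beyond a few multiples of the
   dominant T2 the signal is mostly free-water decay and baseline noise,
   yet unit-variance scaling inflates those columns to the same nominal
   weight as the informative early ones.
2. **Class imbalance.** Data-driven labels (e.g. hard vs tender muscle
   from a force assay) are rarely balanced, and margin- or
   frequency-based classifiers then sacrifice the minority class almost
   entirely while still posting a flattering AUC.

## The procedure

For labeled curves the engine runs a repeated double cross-validation:
an outer stratified 5-fold split estimates performance, an inner 3-fold
grid search chooses hyperparameters on the outer training portion only.
Replicate curves of one biological sample are never split across an
outer boundary (a leakage guard asserted inside the loop), and
normalization statistics are always computed on the training portion and
applied to the held-out fold.

On each outer training portion the framework then:

* truncates the curve to its first `floor(P * rate)` points for each
  candidate usage rate and lets the inner CV pick the best rate together
  with the hyperparameters (ties prefer fewer variables, then the
  simpler model — smaller SVM cost, then smaller gamma);
* draws B bootstrap matrices, each with exactly m rows per class
  resampled with replacement within class, and trains one classifier
  replica per matrix;
* scores the held-out fold with the mean of the B continuous replica
  scores (default) or their majority vote.

AUC, accuracy and the per-class rates CCR-A / CCR-B are computed per
repeat from the pooled outer-fold scores and reported as mean ± sd over
repeats. The AUC is the Mann–Whitney concordance probability (ties count
1/2), which is identical to the trapezoidal area under the returned ROC
polygon — the test suite checks both routes against brute-force pairwise
concordance.

### Defaults and what they mean

| Parameter | Default | Meaning |
|---|---|---|
| `n_bootstrap` (B) | 100 | balanced matrices per outer fold; 10 already works, 100 is slightly better and is the canonical setting |
| `m_per_group` (m) | 150 | rows per class per matrix (300 total); below ~50 per class performance degrades |
| `usage_rates` | 1.0 … 0.1 by 0.1 | truncation ladder; on 256 variables this evaluates 256, 230, 204, 179, 153, 128, 102, 76, 51, 25 columns |
| `outer_folds` / `inner_folds` | 5 / 3 | double-CV structure |
| `repeats` | 10 | outer repetitions for the ± sd spread |
| SVM grid | gamma {1e-4 … 1}, cost {1 … 1000}, log-spaced | contains the modal values (0.03, 5) typically selected on real relaxometric data |
| `integration` | `mean_score` | smooth scores, well-defined ROC; `vote` uses the B-vote fraction as score |

The floor convention in truncation is deliberate: it is the only rounding
rule that makes a 90 % usage rate of 256 variables equal 230 columns
(ending at 0.92 s on a 1.024 s grid) and a 10 % rate equal 25 columns,
the canonical bookkeeping of the 256-point acquisition. Time point k sits
at k·T/P — the t = 0 sample is not stored — which is exactly what makes
the 230th point land on 0.92 s.

### The force pipeline

Hard/tender labels are derived, not assumed. Force–time traces from a
constant-rate compression test are converted to distance domain
(`distance = loading_rate/60 × (t − t_contact)`); the contact point is
the first sustained excursion above `baseline mean + k·sd` (the
instrument literature states that a zero point exists but not how to
find it, so the detector is an explicit, configurable rule). The 0–3.63 mm
window is fitted with `y = a·e^{bx}` via ordinary least squares on
`ln y` — the log-linear estimator that a spreadsheet exponential
trendline computes — dropping non-positive forces rather than clamping
them. Curves not reaching 3.63 mm are rejected with a reason, and
`accepted + rejected = input` always holds.

Per-sample medians of (a, b) are standardized and clustered
(Ward linkage; `ward.D2` by default, `ward.D` available since the
classical "Ward's method" label is ambiguous between the two update
rules). Standardization is a deliberate divergence risk: a and b have
different units, and an unstandardized Euclidean distance would let a
dominate. The cluster with the larger median fitted force at the window
end (a·e^{3.63·b}) is named A (hard). Per-curve clustering (no replicate
aggregation) is supported by passing replicate rows directly; per-sample
aggregation by median is the default because labels attach to samples.

## The synthetic generator

`decay_population_spec()` draws two-group populations of compartment
mixtures `y(t) = Σ fᵢ e^{−t/T2ᵢ}` with (i) additive i.i.d. Gaussian
point noise and (ii) optional per-sample jitter of the compartment
fractions — the biological variation that makes replicates of one sample
correlated while samples within a group still differ. Gaussian noise is
a stand-in: real CPMG noise statistics (Rician magnitude noise, baseline
drift, field inhomogeneity) are not modeled, so passing tests demonstrate
the statistical machinery, not instrument robustness.

`benchmark_decay_spec()` freezes the reference conditions used by the
test suite and the acceptance script: 10 A vs 40 B samples (the 1:4
imbalance the framework targets), 3 replicates, 64 points over 1.024 s,
compartments at T2 = 0.045 s and 0.18 s whose fractions differ by 0.10
between groups, fraction jitter sd 0.05, noise sd 0.02. These values were
chosen once to place the conventional classifier in the moderate-
performance regime (AUC ≈ 0.8–0.9 at this problem size, minority CCR
badly degraded), i.e. the regime where the framework's ingredients have
something to fix; they are not tuned per test. 64 points rather than 256
keeps the full nested search affordable at desk scale — the acceptance
comparison (B = 20, m = 40, rates {1.0, 0.7, 0.4}, 10 seeded runs)
completes in minutes on one CPU; the statistical structure is unchanged.

```{r benchmark, eval = FALSE}
cm  <- generate_decay_matrix(benchmark_decay_spec(seed = 11))
cfg <- framework_config(n_bootstrap = 20, m_per_group = 40,
                        usage_rates = c(1, 0.7, 0.4), repeats = 1, seed = 11)
double_cv(cm, classifier_spec("svm_rbf"), cfg)$metrics
relaxometric_learn(cm, classifier_spec("svm_rbf"), cfg)$metrics
```

## Numerical and design choices

* **Nested vs global rate search.** Selecting the usage rate on the same
  outer data that scores it is optimistically biased, so the nested mode
  (rate chosen by inner CV per outer fold) is the default;
  `optimize_usage_rate(mode = "global")` exposes the per-rate profile
  when the profile itself is the object of interest.
* **Hyperparameter sharing across replicas.** The inner search runs once
  per outer training portion on the unbalanced data and all B replicas
  share the result. A per-replica search would multiply cost by B for
  little gain, since balanced matrices from the same portion are
  near-exchangeable.
* **Bootstrap after splitting.** Matrices are drawn from the outer
  training portion only; resampling before the split would leak test
  rows into training.
* **Score orientation.** All backends emit "larger = more B-like"
  scores (SVM decision value sign-corrected, RF probability of B,
  PLS-DA dummy-response prediction for B); B is the ROC-positive class.
  Class thresholds: 0 for the SVM decision value, 0.5 for
  probability-like scores.
* **Determinism.** Every random step derives its seed from the master
  seed through a named sub-stream (`substream_seed(seed, "boot", r, f,
  b)` etc.), so whole runs are bit-reproducible and individual
  components can be replayed in isolation.
* **Degenerate inputs.** Zero-variance columns stop normalization with
  the column named; single-class folds raise a stratification error
  rather than silently scoring; identical (a, b) tables refuse to
  cluster; identity permutations in the robustness analysis are redrawn.
* **Normalization order.** Truncation happens before normalization; for
  the default column scaling the two commute, but for per-curve scaling
  they do not, and truncate-then-normalize keeps the row norms defined
  on the variables actually used.

## Limitations

* Binary classification only; multiclass labels and regression targets
  are out of scope.
* The curve model is phenomenological — no inverse Laplace / NNLS T2
  spectrum estimation, no Bruker raw-file parsing, no acquisition
  control.
* Synthetic benchmarks show the framework's behavior under its own
  assumptions (Gaussian noise, exponential mixtures); performance
  numbers on real relaxometric data will differ, and the package's
  claims on real data are qualitative (minority-class recovery, AUC
  preserved or improved).
* The permutation robustness default of 10 permutations per variable
  bounds runtime, not estimator variance; raise `n_perm` for publication
  figures.
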