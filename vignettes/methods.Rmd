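---
title: "Decoding animacy from epoched EEG: models, maps and resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding animacy from epoched EEG: models, maps and resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Epoched multichannel EEG carries a weak, subject-specific trace of
what a person is looking at. This package implements an intersubject
decoding pipeline for the binary *animacy* superclass (animal versus
non-animal stimuli): classifiers are trained on some subjects and
evaluated on trials of an entirely held-out subject, which probes
whether the learned EEG signature generalises across people rather
than within one recording session. Alongside the classifiers it
provides the interpretation layer — kernel-derivative sensitivity
maps, split-half effect sizes, and ERP statistics — and a synthetic
paradigm generator so that every stage is testable without any
recorded data.

# Data model

The central container (`epoched_eeg`) is a 4-d array indexed
(subject, trial, channel, time sample) with per-trial category and
animacy labels. The default paradigm has 15 subjects, 23 stimulus
categories of 30 trials each (10 animate categories, hence 300
animate and 390 inanimate trials per subject and a 56.5% inanimate
majority baseline), 32 channels in a standard 10-20 montage, and
600 ms epochs sampled at 100 Hz. The 60 samples are left-aligned on
the half-open window [-100, 500) ms, i.e. -100, -90, ..., 490 ms;
this convention makes "divide alpha by the 60 time samples" exact for
Bonferroni corrections on a trace.

Each trial (or pseudotrial) is z-scored to mean 0 and standard
deviation 1 across its channel x time entries before classification.
The *population* standard deviation (divide by n) is used: either
convention satisfies "unit sd", but one must be fixed, and the
population version makes the operation exactly idempotent.

Feature vectors are the flattened channel x time blocks in
channel-major order (channel varies fastest), giving 32 x 60 = 1920
features; `feature_grid()` exposes the bijection between feature
index and (channel, time).

# Classifiers

Both classifiers are soft-margin RBF-kernel support vector machines
solved in the dual. The decision function is

$$f(x) = \sum_n \alpha_n k(x_n, x) + b,\qquad
  k(x_n, x) = \exp(-\gamma \lVert x_n - x\rVert^2),$$

with signed dual coefficients $\alpha_n$ (zero for non-support
vectors, $\mathrm{sign}(\alpha_n) = y_n$, $|\alpha_n| \le c$). The
*single-trial* classifier trains on every z-scored trial of the
training subjects (690 per subject); the *pseudotrial* classifier
first averages the 30 trials of each category within each subject and
trains on the 23 averaged pseudotrials per subject, trading sample
count for a $\sqrt{30}$ noise reduction. By default averaging
precedes z-scoring, so the unit that enters the classifier is the
unit that is normalised; the opposite order is available via
`zscore_order` because the choice is not forced by the problem.

The quadratic program is solved by kernlab's SMO on a kernel matrix
precomputed by the package (BLAS-backed squared-distance expansion).
The solver's class orientation depends on label order, so the fitted
dual vector is re-oriented to the fixed convention: positive decision
values vote animate (+1), and an exact zero is assigned to the
inanimate majority class. Training rows are sorted by (subject,
trial) before fitting, making the fit invariant to input row order.

Hyperparameter grids are 10 logarithmically spaced values per
parameter, endpoints included: $c \in [0.05, 10]$,
$\gamma \in [2.5\times10^{-7}, 5\times10^{-3}]$ for the single-trial
preset and $c \in [0.25, 15]$,
$\gamma \in [5\times10^{-7}, 2.5\times10^{-2}]$ for the debiased and
pseudotrial presets. For z-scored 1920-dimensional features the
squared distance between two trials concentrates near 2 x 1920, so
the "active" kernel regime sits around $\gamma \sim 10^{-4}$; the
grids bracket it by orders of magnitude on both sides. Grid-search
ties break towards the smallest $c$, then the smallest $\gamma$
(prefer stronger regularisation, deterministic).

## Cross-validation schemes

* **Nested LOSO** (`loso_nested_cv`): the outer loop holds out each
  subject once; the inner loop is a second leave-one-subject-out over
  the remaining subjects that selects the grid combination with the
  highest mean validation accuracy. Validation units match the
  training mode; test units are chosen independently (pseudotrials or
  single trials), so a pseudotrial-trained model can be scored on the
  held-out subject's raw single trials.
* **Debiased double-holdout** (`loso_debiased_cv`): every iteration
  holds out one validation and one test subject, training on n - 2.
  Optimal parameters found on the validation subjects of one half of
  the cohort are averaged — arithmetic mean for $c$, geometric mean
  for $\gamma$ (its grid spans four decades, where arithmetic means
  are dominated by the top decade) — snapped to the nearest grid
  point, and transferred to score the other half's test subjects.
  With an odd cohort the first half holds floor(n/2) subjects and
  validation partners are assigned cyclically.
* **Oracle** (`oracle_cv`): parameters are chosen to maximise the
  held-out subject's own test accuracy. This is an optimistically
  biased upper bound and the result is flagged as such.

Accuracy summaries report both the naive standard error
$s/\sqrt{K}$ and a dependence-corrected one,
$s\sqrt{1/K + n_\mathrm{test}/n_\mathrm{train}}$: cross-validation
folds share training data, so fold accuracies are positively
correlated and the naive SEM understates the uncertainty. The
inflation term is the test/train size ratio, a documented reading of
the standard variance-correction argument rather than a universal
formula; both numbers are always co-reported.

Significance of a held-out subject's accuracy is assessed by
permuting that subject's labels against the fixed predictions
(default 1000 permutations) with the add-one convention
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_\mathrm{perm}+1)$,
which can never return zero.

# Sensitivity maps

The sensitivity map answers *which features the trained classifier
uses*. For the RBF kernel the decision-function gradient is analytic:

$$\frac{\partial f}{\partial x_j}
  = \sum_n \alpha_n\, 2\gamma\,(x_{n,j} - x_j)\,
    \exp(-\gamma\lVert x_n - x\rVert^2).$$

`sensitivity_map()` aggregates this gradient over a set of evaluation
points (default: the model's own training rows, which are always
available) into a channels x time map. The default aggregation is the
mean *squared* derivative, which yields a nonnegative importance map
in the probabilistic sensitivity-map convention; the signed mean is
exposed for inspecting direction. The implementation is verified
against central finite differences of the decision function and
against a naive per-point double loop. No kernel- or count-dependent
renormalisation is applied; the aggregation flag isolates the
convention so alternatives slot in cleanly.

# NPAIRS effect sizes

A full-data map has no intrinsic scale, so it is converted to an
effect size by split-half resampling: for each of $S = 100$ splits,
two disjoint partitions of 7 subjects are drawn (one random subject
left out per split with a 15-subject cohort), the map procedure is
run on each partition, and

$$\sigma^2 = \frac{1}{S\,T\,N}\sum_{i,t,n}
  \left(M^{(i)}_{1,tn} - M^{(i)}_{2,tn}\right)^2,\qquad
  \hat M = M_\mathrm{full}/\sigma.$$

The sum runs over all map elements — here channels x time, since the
maps are channel-by-time matrices. Inside the resampling the
sensitivity map procedure uses *fixed* hyperparameters (the
transferred or validation-mean parameters of a prior CV run, supplied
as inputs); they are never re-optimised per split, so the resampling
measures map variability, not selection variability. No per-split map
normalisation is applied before differencing. Identical partition
maps (sigma = 0) raise an error, since they indicate constant data or
a broken map procedure.

# ERP statistics

`compute_erps()` averages trials to subject-level class means and the
subject means to grand averages; subjects are weighted equally
regardless of trial counts, because the subject is the statistical
unit of the across-subject tests. The difference map is grand animate
minus grand inanimate (positive = stronger animate response). The
paired t-test map tests the per-cell subject differences; the default
correction scope is the conservative full-map Bonferroni
$\alpha/(60 \times 32)$, with a `time_only` mode that first averages
a posterior channel selection (O1, O2, Oz, PO3, PO4) and corrects by
the 60 time samples for trace-level testing. Zero-variance cells get
$t = \pm\infty$ (significant iff the mean difference is nonzero) and
identically zero cells get $t = 0$; real data never meet these cases
but the simulator's degenerate configurations can.

# The synthetic paradigm generator

`generate_dataset()` emulates the paradigm structure exactly: per
subject, 30 trials in each of 23 categories presented in blocks with
per-subject random category order and randomised within-block
content; 10 categories are animate. Each trial is

* a class-independent evoked template — Gaussian-windowed deflections
  (negativity near 90 ms, positivity near 140 ms, late positive
  subcomponents near 250 and 310 ms), strongest posteriorly — scaled
  by a subject-specific lognormal gain (log-sd 0.3) and shifted by a
  subject-specific latency drawn uniformly in ±20 ms;
* plus, for animate trials, the planted effect: two Gaussian bumps
  near 215 and 315 ms on the occipital/parietal channels O1, O2, P7,
  P8, peak amplitude 0.55 template units, same subject gain/latency;
* plus independent Gaussian noise (sd 1.4 by default, optional AR(1)
  temporal smoothing).

The timing module reproduces the session arithmetic: 5 s category
probes, 1 s stimuli, ISIs drawn with replacement from the 7-value
grid 1.85-2.15 s (mean 2 s, sd 0.1 s), five 35 s breaks — 2360 s
(39.33 min) at the default counts.

**Calibration.** The paradigm gives no quantitative single-trial SNR,
so `noise_sd` was calibrated once so that single-trial LOSO accuracy
at the default paradigm size lands in the weakly-decodable 0.55-0.65
regime, with the pseudotrial classifier on par when scoring single
trials; the planted amplitude 0.55 and noise sd 1.4 are the fixed
result of that calibration, not empirical values. The subject
gain/latency parameters are round magnitudes chosen to make
intersubject generalisation visibly imperfect (per-fold accuracies
spread by several points), mimicking the heterogeneity that motivates
leave-one-subject-out evaluation.

**What the generator does not emulate:** spatially correlated sensor
noise, volume-conduction channel covariance, eye-movement or muscle
artifacts, electrode dropout, sampling drift, or trial-to-trial
latency jitter within a subject. Tests passing on this generator
therefore certify the *algorithms* (recovery of a planted effect,
calibration of error rates under a known null), not performance on
any particular recording system.

# Numerical choices and degenerate inputs

* Kernel matrices are computed via the squared-norm expansion with a
  clamp of tiny negative rounding residues at zero.
* The SMO solver is deterministic given the kernel matrix and label
  order; rows are canonically sorted first.
* A constant trial cannot be z-scored and raises an error naming the
  (subject, trial); an empty subject x category cell fails
  pseudotrial averaging; single-class training sets are rejected.
* Decision ties (exact zero) go to the inanimate majority class.
* Permutation p-values use the add-one convention.

# Problem sizes used by the test suite

The test suite runs every scheme end-to-end at sizes chosen for a
single CPU: unit tests use 2-6 subjects with 5 categories; the null
control runs 5 seeds at the full default paradigm (15 x 690) with a
reduced 2 x 3 grid, plus 50 null simulations at 10 trials per
category for the familywise-error check (the subject-level t-test
sees only class means, so the trial count does not affect FWER
control); planted-effect recovery uses the full default dataset for
the pseudotrial classifier and 8 subjects x 230 trials for the
single-trial classifier; the parity check uses 10 subjects x 230
trials at the calibrated fixed hyperparameters. The acceptance script
fits the full 10350-row single-trial SVM and the 345-row pseudotrial
SVM on a freshly simulated default dataset.

# Known limitations

* Only binary animacy decoding is implemented; the 23-way category
  problem is out of scope.
* Only the RBF kernel is supported — the analytic sensitivity map is
  specific to it.
* The NPAIRS implementation covers equal-size split-half partitions,
  not prediction-vs-reproducibility curves.
* The dependence-corrected SEM is one documented convention among
  several in the cross-validation literature; both it and the naive
  SEM are reported so users can apply their own.
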