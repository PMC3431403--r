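---
title: "Lifespan connectivity trajectories and brain-age prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan connectivity trajectories and brain-age prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcLifespan)
```

# Scope and model

`fcLifespan` analyses how whole-brain resting-state functional connectivity
changes across the human lifespan and predicts an individual's "brain age"
from it. The pipeline assumes the kind of pooled two-centre design common in
public resting-state repositories: one centre contributing children through
middle-aged adults with a single scan each, a second contributing adults
through elderly subjects with two scans each, ages spanning roughly 8–79
years, with sex and centre coded as 0/1 covariates.

The analysis starts at regional BOLD time series (voxelwise preprocessing is
upstream and out of scope). Regional series are band-pass filtered
(0.01–0.1 Hz), linearly detrended and residualised against a user-supplied
nuisance matrix (typically nine signals: six rigid-body motion parameters
plus white-matter, CSF and global signals). Pairwise Pearson correlations
over `p` regions give a symmetric `p x p` network; Fisher's z-transform
normalises the correlations; and the strict upper triangle, in fixed
row-major order, is the feature vector — `p(p-1)/2` connections, 6,670 for
the standard 116-region anatomical parcellation. Instantaneous head motion
is summarised by framewise displacement, the sum of absolute backward
differences of the six realignment parameters with rotations converted to
arc length on a 50 mm sphere; the per-scan mean is the subject's motion
covariate.

## Developmental trajectories

Each connection \(y\) is fitted, per subject (repeated scans averaged
first), with two nested ordinary-least-squares models:

\[
y = \beta_0 + \beta_1\,\mathrm{age} + \beta_s\,\mathrm{sex} +
    \beta_c\,\mathrm{centre} + \varepsilon
\qquad
y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{age}^2 +
    \beta_s\,\mathrm{sex} + \beta_c\,\mathrm{centre} + \varepsilon
\]

The linear-model age t statistic tests linear change; the quadratic-model
age² t statistic tests curvature once linear age effects are removed. The
best model per connection is chosen by small-sample corrected AICc (plain
AIC via a flag). Because the physiological meaning of negative connectivity
is contested, selection is restricted to connections positive across
subjects (one-sided one-sample t, p < 0.001). To guard against influential
subjects, the relevant age term must stay significant (p < 1e-4,
two-tailed) in every leave-one-subject-out refit. Surviving connections are
classified by model and sign into positive/negative linear and positive
(U-shaped) / negative (inverted-U) quadratic trajectories; quadratic
connections get a peak age \(-\beta_1/(2\beta_2)\) from the vertex of the
fitted curve. A motion check (`regress_motion`) residualises selected
connections against mean framewise displacement before refitting.

Two subtleties worth knowing:

* *Scan averaging and heteroscedasticity.* Averaging the two scans of
  second-centre subjects halves their residual variance, so the collapsed
  design is mildly heteroscedastic and null p-values are slightly
  conservative (mean ≈ 0.53 rather than 0.50 in our calibration runs). The
  package's type-I calibration test therefore uses a single-scan design,
  where exact uniformity holds. The conservatism only strengthens the
  false-positive guarantees of the selection.
* *A ceiling on class recall.* For a truly linear connection, AICc prefers
  the quadratic model with probability ≈ 0.14 at n = 137 regardless of
  effect size (it is the type-I rate of the nested comparison at the AICc
  penalty), and the curvature term then rightly fails the robust screen, so
  the connection ends up unclassified. Recall for linear-true connections
  is therefore capped near 85% however strong the planted effect; quadratic
  recall is ≈ 98%. Overall recovery on the default synthetic mixture is
  ≈ 95%, quadratic-heavy because quadratic classes dominate that mixture.

## Supervised manifold learning

The feature space has dimension M ≫ n, but the age-related variation is
hypothesised to lie near a low-dimensional manifold. The package learns it
with supervised Locality Preserving Projections (LPP): pairwise Euclidean
distances are multiplied by a penalty (default 100) for sample pairs whose
age gap strictly exceeds a threshold (default 8 years); a union-symmetrised
k-nearest-neighbour graph (k = 8, binary weights, ties broken by index) is
built on the penalised distances; and, after centring and a
variance-preserving pre-projection of rank up to n − 1 (necessary since
M ≫ n makes the problem singular), the generalised eigenproblem

\[ X^{\top} L X\, a = \lambda\, X^{\top} D X\, a, \qquad L = D - W \]

is solved, keeping the d eigenvectors of smallest nonzero eigenvalue. The
pre-projection and eigenvectors compose into one linear map, so new samples
embed by matrix product — the property that makes leave-one-out evaluation
honest. PCA is provided as the unsupervised baseline; it preserves global
variance and is not expected to recover the chronological ordering.
Eigenvector signs and neighbour ties are fixed deterministically so
embeddings are bit-reproducible.

Design choices made where the method leaves room:

* *Binary edge weights* (the simple-minded LPP variant); a heat-kernel
  weight would introduce a width parameter nothing in the analysis pins
  down.
* *Penalised distances drive both neighbour selection and weighting*, since
  the supervision is defined as a modification of the distance itself.
* *Disconnected graphs are bridged*, not merely reported: when the kNN
  graph splits (which happens in cohort realisations with sparse 50–80
  year sampling, where the penalty isolates the elderly), the shortest
  inter-component edges are added until one component remains. Without the
  bridge the embedding degenerates into per-component coordinates and
  downstream prediction error roughly triples; with it, the continuous
  developmental progression survives sparse sampling. The contract-plain
  graph (no bridge) remains available in `build_knn_graph`.

## Brain-age regression

Regression of age on manifold coordinates uses support vector regression
with a quadratic loss and no ε-tube, which coincides with (kernel) ridge
regression and is solved in closed form: the penalty \(\lambda = 1/(2C)\)
maps the SVR trade-off C onto ridge shrinkage. Three variants are provided:
linear, RBF-kernel (width expressed as a multiple of the mean pairwise
training distance), and locally adjusted SVR (LASVR) — a four-step scheme
that fits a global linear model, predicts a new sample, refits a linear
model on training samples whose age lies within δ years (default 8) of the
global prediction, and returns the local prediction (falling back, flagged,
when the window holds fewer than 10 samples).

Embedding coordinates carry an arbitrary scale (generalised-eigenvector
normalisation), so all regressors standardise coordinates once on the
training set; LASVR local fits inherit the global scaling rather than
re-standardising inside each window, which would re-inflate noise
directions. With this convention C = 0.1 is a sensible default across
embeddings.

Evaluation is leave-one-out cross-validation at the subject level: the
embedding *and* the regressor are refit per fold on training subjects only
— the held-out subject's scans and age never enter the distance penalty,
the graph, the pre-projection or the fit — and per-scan predictions of
two-scan subjects are averaged. Reports carry the mean absolute error,
cumulative scores CS(j) (percent of subjects within j years), and a
predict-the-training-mean baseline. `sweep_parameters` evaluates grids over
embedding dimension, regressor variants and graph parameters, reusing one
cross-validation pass per graph setting.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated.

* **Cohort** (`generate_cohort`): 137 subjects by default, ages drawn from
  a mixture over seven lifespan bands (8–20 through 71–79) with weights
  matching the emulated two-centre design, which is children/young-adult
  heavy and sparse over 50; sex a fair coin; centre 1 (two scans) only for
  ages ≥ 19, centre 0 only ≤ 49, otherwise Bernoulli with the configured
  split; mean framewise displacement follows a U-shaped quadratic fitted
  through the band-level motion means (children and elderly move more),
  plus subject noise, floored at 0.
* **Trajectories** (`plant_trajectories`): each connection draws one of
  five classes with default proportions 0.10/0.10/0.30/0.30/0.20
  (pos-linear/neg-linear/pos-quad/neg-quad/null), quadratic-heavy to mirror
  the predominance of U- and inverted-U trajectories among age-sensitive
  association connections. Effect sizes are calibrated in t-units: a slope
  with `effect_scale = 6` (default) yields an expected age-term |t| of 6 at
  the reference design, using the *partial* sd of age given sex and centre
  (14.1 years — centre is age-dependent, so this is well below the marginal
  sd) and the partial sd of age² given age and the covariates (316.9).
  Per-connection ±10% heterogeneity keeps columns from being clones.
  Quadratic peaks are uniform on 34–47 years; baselines keep the noiseless
  trend positive (its minimum uniform on 0.2–0.6 z) so positivity screening
  is non-trivial but passable; residual noise is homoscedastic Gaussian,
  0.1 z by default.
* **Time series and motion** (`generate_timeseries`,
  `generate_realignment`): Gaussian processes with an exact target
  correlation (via a symmetric matrix square root, with PSD repair by
  eigenvalue clipping), and six random-walk realignment series whose
  increments are calibrated so the mean framewise displacement matches a
  requested scale, half through translations and half through rotations.

What the generator does *not* emulate: bounded or saturating connectivity
values, heteroscedastic or temporally autocorrelated noise, spatial
structure among connections, site differences beyond an additive offset,
and any nonlinearity beyond the quadratic term. Passing tests therefore
validate the machinery and its statistical calibration, not performance on
real cohorts.

One consequence deserves emphasis. Because generated features are exactly
linear in (age, age², sex, centre) plus noise, age is an exact linear
functional of the noiseless feature span, so a global linear regressor on a
rich embedding is essentially unbiased here, and LASVR's piecewise-linear
adjustment can only trade bias it does not have against window variance. On
replicate synthetic cohorts the two methods finish within a few percent of
each other with unstable sign (LASVR ahead on some cohort draws, behind on
others), while on real data the local adjustment targets genuinely
nonlinear age–connectivity structure. The package's test suite records this
honestly: the LASVR-beats-linear ordering is asserted as measured over
replicate cohorts and may fail under this generative family, whereas both
methods beating the predict-the-mean baseline by > 40% holds with a wide
margin on every cohort draw.

# Numerical conventions

* Band-pass filtering: second-order Butterworth applied forward-backward
  (zero phase) via `signal::filtfilt`; order filter → detrend → confound
  regression, configurable with a message since the steps do not commute.
* Framewise displacement of the first timepoint is 0 (no predecessor).
* Fisher z clips |r| at 1 − 1e-7 before `atanh`; the transform is odd and
  strictly monotone.
* OLS uses QR; standard errors come from the Cholesky inverse of X'X;
  tests are two-tailed on residual degrees of freedom. AICc includes the
  residual-variance parameter in its count.
* The LPP denominator matrix gets a ridge of 1e-8 × mean diagonal only if
  its Cholesky factorisation fails, with a warning; eigenvalues below
  1e-10 are treated as zero (degenerate directions).
* kNN ties break by sample index; eigenvector signs are fixed by making
  the largest-magnitude loading positive.
* All generators are deterministic given their seed; LOOCV precomputes the
  pairwise distance matrix once (training-fold submatrices do not depend
  on the held-out rows).

# Problem sizes used by the validation suite

The suite validates trajectory recovery on one cohort of 137 subjects with
2,000 connections (1,600 planted, 400 null), manifold and prediction
behaviour on cohorts of 137 subjects with 600 connections, and the method
comparison and penalty-effect claims as means over 5 replicate cohorts;
oracle-equivalence checks run on small random instances. These sizes were
chosen so each claim is measured with adequate Monte-Carlo precision while
the whole suite stays interactive.

# Known limitations

* The trajectory-class recall ceiling for linear-true connections (above)
  is a property of AICc-based nested model selection, not of the
  implementation; applications caring more about recall than parsimony can
  classify from the per-model significance screens directly.
* LASVR's advantage over a global linear fit is expected only when the
  age–feature relation is genuinely nonlinear; under the package's own
  generative family the two are statistically indistinguishable.
* The positivity screen intentionally drops connections that are negative
  or near zero across subjects; planted effects on such connections are
  invisible to the classification stage by design.
* No multiple-testing correction is applied across connections — the fixed
  per-connection threshold plus leave-one-out robustness is the selection
  rule; an FDR report can be layered on by the user but never gates
  classification.
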