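---
title: "Modelling cognitive decline with tensor multi-task ensemble regression"
author: "tensorMTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive decline with tensor multi-task ensemble regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorMTL)
```

## The problem

Disease-progression modelling for Alzheimer's disease asks: given a
patient's structural MRI biomarkers (FreeSurfer-style regional volumes,
surface areas and cortical thicknesses), what will their cognitive scores
(MMSE, ADAS-Cog) be one to four years from now? tensorMTL implements a
tensor multi-task regression with a gradient-boosting extension for
patients who keep returning for scans, plus the preprocessing, evaluation
and synthetic-data machinery needed to study it end to end.

Rather than feeding raw biomarker values into a regression, the model
works with *variation*: for each biomarker measured at two consecutive
visits it forms the 2-vector

* rate of change \((x_\text{late} - x_\text{early}) / x_\text{early}\)
  (dimensionless), and
* velocity \((x_\text{late} - x_\text{early}) / \Delta t\) in units per
  month (a month is fixed at 30.4375 days, the mean Gregorian month,
  since exam dates rarely fall exactly one month apart).

The pairwise Mahalanobis distances between a patient's \(d\) variation
vectors form a symmetric \(d \times d\) slice with zero diagonal; the
\(n\) patients stack into the similarity tensor
\(X \in \mathbb{R}^{d \times d \times n}\). The Mahalanobis form
\(\sqrt{(x_i - x_j)^\top S^{-1} (x_i - x_j)}\) makes the two heterogeneous
coordinates (a ratio and a per-month velocity) comparable.

## The model

For prediction time point \(t\) (M12, M24, M36, M48) the score of sample
\(n\) is predicted as
\[
\hat y_n = \textstyle\sum_{ij} \bigl[(A_t B_t^\top) \odot K \odot W_t
\odot X_n\bigr]_{ij},
\]
where \(A_t, B_t \in \mathbb{R}^{d \times r}\) are CP
(CANDECOMP/PARAFAC) latent factors of the tensor, \(W_t\) is an
elementwise weight matrix, and \(K\) is the strictly upper-triangular
*duplicate-data correction mask*: the slices are symmetric, so each
biomarker pair appears twice and \(K\) keeps exactly one copy.

The joint training objective sums per-time-point losses and couples the
weights across time:
\[
\sum_t \Bigl[\tfrac12 \lVert \hat y_t - y_t\rVert^2
 + \tfrac\lambda2 \lVert X - [\![A_t, B_t, C_t]\!]\rVert_F^2
 + \beta \bigl(\lVert W_t\rVert_1 + \lVert A_t\rVert_1
 + \lVert B_t\rVert_1 + \lVert C_t\rVert_1\bigr)\Bigr]
 + \theta \lVert W_f P(\alpha)\rVert_F^2 .
\]

* The CP term anchors \(A_t, B_t\) (and the sample factors \(C_t\), used
  only at training time) to the latent structure of the tensor.
* The single \(\beta\) is shared by all four \(\ell_1\) terms.
* \(W_f\) is the \((d^2) \times t\) unfolding of the weight stack and
  \(P(\alpha) = H\,D_1(\alpha_1)\cdots D_{t-2}(\alpha_{t-2})\) is the
  generalized temporal-smoothness operator: column \(i\) of \(W P\) is
  the blended progression \(\Delta w_1 = \delta w_1\),
  \(\Delta w_i = \alpha_{i-1}\Delta w_{i-1} + (1 - \alpha_{i-1})\delta
  w_i\) with \(\delta w_i = w_i - w_{i+1}\). With all \(\alpha = 0\) it
  reduces to the plain first-difference penalty; larger \(\alpha\) lets
  earlier progressions influence later stages, the way a clinician weighs
  a patient's history. For \(t = 2\) there are no \(\alpha\) parameters
  and \(P \equiv H\).

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `lambda` | CP-fit weight | 0.1 | keeps factors near the tensor's CP structure without dwarfing the prediction loss on normalized slices |
| `beta` | shared l1 weight | 0.001 | mild sparsity for exploratory fits; recovery/selection studies use larger values (0.1–0.3) or tune by CV |
| `theta` | temporal smoothness | 0.1 | weights drift slowly across 12-month horizons |
| `rank` | CP rank r | 3 | a few latent factors explain most of a distance tensor's structure |
| `alphas` | progression blending | 0 | reduces to first differences; tuned on the CV grid in `runProtocol()` |
| `tol`, `maxIter` | stopping | 1e-5, 500 | relative objective change |

## The solver

All four penalized blocks are updated per outer iteration in the order
\(A_t \to B_t \to C_t\) (each time point) and then the whole weight
stack \(W\) jointly, so the smoothness coupling is handled exactly. Each
block takes proximal-gradient steps (gradient of the smooth part, then
elementwise soft-thresholding) with a *monotone backtracking line
search*: a step is only accepted if it satisfies the quadratic
upper-bound inequality, and the curvature estimate is doubled otherwise.
We chose backtracking over a fixed \(1/L\) step from a power-iteration
estimate because an underestimated \(L\) can break monotonicity, and a
non-increasing objective trace is one of the package's contracts
(`objectiveTrace()` is checked in the tests to never increase beyond
1e-10). The W block — much larger than the factor blocks — additionally
runs 25 inner steps per outer iteration with monotone FISTA
acceleration (extrapolated steps that fall back to a plain proximal step
whenever the composite objective would rise).

Factors are initialized by a short deterministic CP-ALS run (leading
singular vectors of the mode unfoldings, sign-fixed, then five
alternating least-squares sweeps with balanced column norms). The solver
is therefore deterministic given the data; the seed recorded in
`tmtlParams()` is kept for provenance. `W` starts at zero and, because
every gradient is masked by \(K\), its support never leaves the strict
upper triangle.

Numerical details worth knowing:

* Per-patient covariance matrices of variation vectors are regularized
  as \(S + \varepsilon\,\overline{\mathrm{diag}(S)}\, I\) with
  \(\varepsilon = 10^{-6}\); a fully degenerate \(S\) (all variation
  vectors identical) falls back to the identity, under which identical
  vectors still have distance zero.
* Slices are min-max scaled to \([0, 1]\) by default (`normalize`),
  which puts the prediction loss, CP term and penalties on comparable
  scales; the flag can be turned off.
* Missing targets are excluded from the empirical loss but the sample
  still contributes to the CP term.
* Ties in `rankRelationships()` are broken by upper-triangle index
  order, so rankings are reproducible.

## The boosting ensemble

Patients keep returning for scans, giving consecutive intervals
BL→M06, M06→M12, M12→M24, each with its own similarity tensor. The
ensemble fits the first tensor to the scores and every later tensor to
the residual of the cumulative prediction (`fitEnsemble()`), and
`predictEnsemble(..., uptoStage = s)` supports dynamic prediction: a
patient with only \(s\) scans gets the best forecast those scans
support. Shrinkage `nu` defaults to 1 (pure residual fitting, the first
stage always unshrunk); residuals are computed in-sample, without
internal holdout machinery. The number of stages equals the number of
available consecutive intervals.

## The synthetic-data generator

ADNI-like cohort data are registration-gated, so the package ships a
generator whose defaults define the study conditions used by the tests
and the acceptance script:

* Trajectories: \(x_v = \text{baseline}\,(1 + \text{rate}\cdot
  \text{months} + \epsilon)\), \(\epsilon \sim N(0, 0.01)\), with
  group-dependent monthly rates (AD \(-0.004\), MCI \(-0.002\), CN
  \(-0.0005\) on average, surface area declining at half pace) and a
  per-biomarker multiplier in \([0.5, 1.5]\). Exam dates follow the
  nominal schedule with \(\pm 15\) days of uniform jitter (baseline
  anchors the schedule). Diagnosis mix 30/40/30 for AD/MCI/CN, an
  MCI-enriched composition typical of progression cohorts.
* Ground truth: the latent factors of each stage are taken from the same
  short deterministic CP-ALS run the estimator warm-starts from. This is
  a deliberate choice: the CP decomposition of a distance tensor is
  ill-posed (ALS keeps drifting along near-flat directions, and the
  factor product \(A B^\top\) does not stabilize), so defining the truth
  by a *converged* CP run would make the forward model depend on an
  arbitrary point of a degenerate optimization. Anchoring both the
  generator and the estimator to the same deterministic, data-driven
  routine makes the forward model exactly realizable and the recovery
  question well-posed.
* Weights: 10% of the upper-triangular cells carry weights of magnitude
  0.5–1.5 with random signs; consecutive time points share the support
  and drift by \(N(0, 0.05)\) on it — the structure the smoothness prior
  encodes. Stage contributions scale as 1, 0.4, 0.2, so every interval
  carries signal but later scans refine rather than dominate.
* Scores: forward-model predictions plus homoscedastic Gaussian noise
  with SD equal to 10% of the per-time-point signal SD. The noise model
  is a simplifying assumption; real score noise is bounded, discrete and
  heteroscedastic.

What passing tests on these cohorts shows — and what it does not: the
generator reproduces the statistical *shape* the method assumes
(group-separated drift, sparse smooth pair weights, latent low-rank
structure). It does not emulate real neuroanatomy, atlas geometry,
site/scanner effects, informative dropout, or floor/ceiling effects in
the scores, so performance numbers on synthetic cohorts say the
machinery works as specified, not how it will score on clinical data.

### Measuring recovery

`weightRecovery()` reports the Pearson correlation between the
vectorized upper-triangular weight stacks and a support-recovery F1. The
recovered support is defined as cells whose magnitude exceeds 5% of the
largest recovered magnitude: an \(\ell_1\) proximal solver stopped at
tolerance leaves tiny residual entries (typically below 2% of the
largest weight) that are optimization dust, not selected relationships.
`recoveryExperiment()` runs this over seeds at the documented study
scale (n = 100 patients, d = 20 biomarkers, rank 3, four time points,
10% score noise) with a long optimization budget
(`beta = 0.2`, `theta = 1`, `alphas = 0.5`, `maxIter = 1000`,
`tol = 1e-9`); `boostingExperiment()` checks, over 20 seeds at n = 80,
d = 12 with a 20% held-out patient set, that the full ensemble's mean
test rMSE beats or matches the single-scan model in at least 80% of
seeds. These problem sizes are the package's documented study scales:
large enough for the properties to be meaningful, small enough that the
whole suite runs on a laptop.

## The evaluation protocol

`runProtocol()` repeats (default 20 times): a patient-level 9:1
train/test split, 5-fold cross-validated grid search on the training
patients (selection by mean validation rMSE across folds and time
points, ties broken by grid order), a refit on the full training set and
held-out evaluation. Splits are always at the patient level — a
patient's visits never straddle the split. Reported metrics are the
per-time-point rMSE \(\sqrt{\lVert y - \hat y\rVert^2 / n}\) and the
overall normalized MSE
\(\sum_i \lVert Y_i - \hat Y_i\rVert^2 / \sigma(Y_i) \,/\, \sum_i n_i\),
where \(\sigma(Y_i)\) is the SD of the observed test targets at time
point \(i\) (computed over observed entries only).

`rankRelationships()` ranks biomarker pairs by absolute weight — the
magnitude measures impact on the prediction; the sign is reported
alongside — and `exportBrainNet()` writes node/edge text files in the
format network-rendering tools consume (with a synthetic circular
layout, since simulated biomarkers have no anatomical coordinates).

## Design decisions on genuinely open points

* **Covariance scope for the Mahalanobis distance**: per-patient by
  default (each slice is that patient's own covariance of variation
  vectors, matching the per-slice construction); a pooled scope across
  patients is available via `covarianceScope = "pooled"`.
* **Imputation scope**: the feature mean pools all retained rows across
  visits and groups; per-visit stratification is available
  (`byVisit = TRUE`) but off by default.
* **"More than half" missing** is a strict inequality: a feature missing
  in exactly half the records survives the default filter.
* **Per-time-point factors**: \(A_t, B_t, C_t\) are fitted per time
  point by default; `sharedFactors = TRUE` shares one triple across
  time points for ablation.
* **Ranking by magnitude**: higher \(|W|\) means greater impact; signed
  weights are reported alongside.
* **Shrinkage**: the boosting default `nu = 1` is pure residual fitting;
  values below 1 damp later stages.

## Known limitations

* The joint objective is non-convex; the solver guarantees monotone
  descent to a stationary point, not a global optimum. The deterministic
  initialization makes results reproducible but a different warm start
  can reach a different stationary point.
* The CP decomposition of near-symmetric distance tensors is degenerate;
  the package treats the factors as a regularizing representation, not
  as uniquely identified quantities.
* Only the elementwise weights \(W\) are interpreted; the latent factors
  absorb scale ambiguities and should not be read off individually.
* The generator's missingness is completely at random; informative
  dropout (sicker patients missing more visits) is not modelled.
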