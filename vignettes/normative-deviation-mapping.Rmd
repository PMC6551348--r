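---
title: "Normative modelling of cortical development and individual deviation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of cortical development and individual deviation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control comparisons of cortical anatomy assume that the clinical
group is homogeneous: they estimate the difference between an "average
patient" and an "average control". In conditions as heterogeneous as
autism, individuals may deviate from typical development in different
regions, in different directions, and at different ages — effects that
largely cancel in a group contrast. Normative modelling inverts the
question: instead of asking where groups differ on average, it builds a
growth-chart-like reference model of typical development and asks, for
each individual, where that person lies relative to the reference
centiles.

`normdev` implements this analysis end to end for vertexwise cortical
measures (thickness in mm, or surface area), together with a synthetic
cohort generator that emulates the statistical structure such a study
assumes, so every stage is testable without imaging data.

## The normative model

At every vertex we model the measurement $y$ of a typically developing
(TD) subject as a Gaussian process over the covariates $\mathbf{x}$
(standardized age and a male indicator; optionally IQ, site and a
surface-quality surrogate as dummy covariates):

$$y = f(\mathbf{x}) + \varepsilon, \qquad
  f \sim \mathcal{GP}(0, k), \qquad
  \varepsilon \sim \mathcal{N}(0, \sigma^2_n),$$

after centering $y$ on its training mean. The kernel is a sum of an
anisotropic (ARD) squared-exponential, a linear kernel and a constant:

$$k(\mathbf{x}, \mathbf{x}') =
  \sigma^2_f \exp\!\Big(-\tfrac12 \sum_d (x_d - x'_d)^2 / \ell_d^2\Big)
  + \sigma^2_l\, \mathbf{x}^\top \mathbf{x}' + \sigma^2_b .$$

The linear + constant part carries the dominant, nearly linear decline
of cortical thickness with age; the squared-exponential part captures
curvature such as the inverted-U trajectories seen at a minority of
vertices. All hyperparameters are set by empirical Bayes (type-II
maximum likelihood): L-BFGS-B on the log-parameters with analytic
gradients, multiple restarts (a data-driven start, a warm start from
the neighbouring vertex when fitting many vertices, and seeded random
perturbations), stopping when the negative log marginal likelihood
improves by less than $10^{-6}$.

Generalization is assessed the way the deviations are later scored:
TD subjects receive strictly out-of-fold predictions under 10-fold
cross-validation (folds seeded, optionally sex-stratified), and the
clinical cohort is predicted from a final model refit on all TD
subjects. This matters: it makes TD and clinical deviations comparable,
because neither is evaluated by a model that saw the subject.

### Numerical choices

* A relative jitter of $10^{-6}$ times the mean covariance diagonal is
  added before each Cholesky factorization and escalated tenfold up to
  three times if the factorization fails; a vertex whose fits still
  fail is flagged and excluded downstream (it no longer counts toward
  any subject's multiple-testing family).
* Age is z-scored with the training fold's TD statistics; dummies stay
  0/1. Missing IQ (when that covariate is requested) is mean-imputed
  with a missingness indicator.
* Log-parameters are box-bounded to $[-15, 8]$, which keeps every
  variance positive and the optimizer away from degenerate plateaus.
* A constant target collapses gracefully: variances shrink to the
  bound and the predictive mean returns the constant.

### What is and is not identifiable

The marginal likelihood identifies the *predictive distribution* well,
but not every hyperparameter separately: with length-scales comparable
to the covariate range, the squared-exponential variance trades off
against the linear and constant components (and against the centered
constant direction), so $\log\sigma^2_f$ alone can wander by more than
half a log-unit at $n \approx 200$ while predictions barely change. The
hyperparameter-recovery tests therefore use a short length-scale
configuration (0.1 on the standardized scale, i.e. many independent
wiggles in the observed range), where signal and noise variances are
individually identified; noise variance is well recovered in every
regime.

## Deviation maps and within-subject FDR

For subject $i$ at vertex $v$, the deviation score is

$$Z_{iv} = \frac{y_{iv} - \hat y_{iv}}
  {\sqrt{\sigma^2_{*iv} + \sigma^2_{nv}}},$$

the residual standardized by the *total* predictive uncertainty —
latent-function uncertainty plus observation noise. Because
$\sigma^2_*$ grows where data are scarce (e.g. at the edges of the age
range), inference automatically becomes more conservative there.

Each subject's map is thresholded with two-sided normal p-values,
$p = 2\Phi(-|Z|)$, corrected by Benjamini–Hochberg *within that
subject* across vertices at $q = 0.05$; surviving vertices keep the
sign of $Z$. Two-sided testing with a sign split after rejection is
used because deviations of both signs are scientifically meaningful;
BH (not BY) matches common vertexwise practice.

Cohort-level views are then:

* **overlap maps** — per-vertex counts of subjects with significant
  positive/negative deviations, per cohort and per age/ability
  schedule, plus the proportion of subjects contributing at least one
  significant vertex; and
* a classical **mass-univariate GLM** (OLS per vertex: diagnosis,
  centered age polynomial up to cubic, optionally sex or an
  age-by-diagnosis interaction; BH across vertices), fit pooled or
  stratified by sex. Centered age powers are used purely for numerical
  conditioning.

The package's central testable property is the contrast between these
two views: when deviations are individualized (minimally overlapping
across subjects), the GLM flags almost nothing while the overlap maps
show a large fraction of clinical subjects carrying significant
deviations.

## Extreme-value summaries and enrichment

A subject's atypicality summary is the trimmed mean of the top 1% of
absolute deviations, $k = \lceil 0.01\,m \rceil$ values (floored at one
vertex for small regions), computed globally and within each parcel of
the vertex parcellation. Across subjects these maxima-like summaries
are modelled with a Gumbel (type I extreme-value) distribution — maxima
of near-Gaussian scores lie in the Gumbel domain of attraction — fit by
maximum likelihood via the one-dimensional profile equation for the
scale. Cohort enrichment among the top-$k$ scorers is tested with a
tail probability under a chosen null: hypergeometric (sampling without
replacement from the realized cohort sizes; the default), a binomial at
the cohort case proportion, or a fair-coin binomial. All three are
reported because a printed "binomial test" bound does not determine the
null proportion; with 321 cases among 527 subjects and all of the top
15 being cases, they give
$\approx 5.2\times10^{-4}$, $\approx 5.9\times10^{-4}$ and
$2^{-15} \approx 3.05\times10^{-5}$ respectively.

## Symptom associations

Global and per-region extreme scores are correlated with six symptom
scores (lifetime parent-reported and current clinician-rated
instruments, three domains each) by mid-rank Spearman correlation,
overall and within each sex. P-values use the t-approximation at
$n \ge 10$ and exact permutation enumeration below that. Regional tests
are BH-corrected within each (symptom × stratum) family across regions
— the family structure mirrors per-symptom, per-sex regional maps, and
male/female maps are corrected separately; the global score is reported
at the nominal level in its own row. Missing scores are dropped
pairwise, with the n used recorded per cell. Post hoc confound checks
(global score vs IQ and the quality surrogate, per cohort) are reported
uncorrected and flagged as descriptive.

## The synthetic cohort generator

`sim_config()` defaults define the study conditions the analysis is
exercised under:

* **Design**: 206 TD (127 male) and 321 clinical (232 male) subjects,
  ages 6–31, in four schedules — A adults 18–30, B adolescents 12–17,
  C children 6–11, D adolescents/adults with IQ in [50, 70) — with
  schedule counts matching the study design (ASD 125/112/64/20, TD
  84/70/52/0). Ages are uniform within each schedule's window (the
  real within-schedule distributions are unpublished; uniform is the
  declared stand-in). IQ is truncated-normal above 70 (group-specific
  moments), uniform in [50, 70) for schedule D.
* **Geometry**: 1,000 vertices in 34 contiguous equal parcels (a
  per-hemisphere atlas-scale stand-in); both configurable.
* **Trajectories**: per-vertex linear decline (intercept
  $\mathcal{N}(3.0, 0.2^2)$ mm, slope $\mathcal{N}(-0.02, 0.007^2)$
  mm/yr) with an inverted-U quadratic at 20% of vertices peaking at
  ages 8–14; a male offset of $\mathcal{N}(0.05, 0.02^2)$ mm; residual
  SD uniform in 0.15–0.25 mm. These magnitudes are typical of cortical
  thickness growth modelling; they are stand-ins, not estimates.
* **Deviations**: exactly `round(0.4 × 321)` clinical subjects carry
  deviations (an exact count, not per-subject Bernoulli, so
  truth-based tests are not flaky), each in 2 whole parcels chosen per
  subject (hence minimal overlap across subjects), with magnitude
  $\mathcal{N}(4, 0.5^2)$ in local noise-SD units and sign negative
  for children (schedule C) and positive otherwise.
* **Symptoms**: six scores with the published means/SDs, linked to the
  planted deviation magnitude through a rank-preserving Gaussian
  copula. The latent correlation is calibrated by solving the exact
  expected Spearman correlation given the realized tied ranks, so the
  configured target (e.g. $-0.21$ for the current-repetitive-behaviour
  score) is hit despite the 60% tie mass at magnitude zero. Whole
  instruments are blanked for 13 (lifetime) and 63 (current) subjects,
  matching the published instrument sample sizes 308 and 258.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring vertices, realistic cortical geometry, longitudinal
repeats, site effects on the measurements, and non-Gaussian residuals.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions — calibration, FDR control, power against the
planted structure — not robustness to real-data violations of them.

## Problem sizes used in tests and the acceptance script

Subject-level conditions are always paper-scale (206 + 321). The
GP-heavy runs use reduced vertex counts, chosen as the package's
standard check sizes: the shared end-to-end run uses 200 vertices with
the default 34 parcels and 10-fold CV; the 20-seed replication of the
extreme-score right shift uses 30 vertices, 10 parcels and 3-fold CV;
pipeline-level fits use two optimizer initializations per vertex
(data-driven plus warm start). Null-FDR and extreme-value checks, which
involve no GP fitting, run at 500 subjects × 1,000 vertices and
n = 5,000 respectively.

## Known limitations

* Exact GP inference is $O(n^3)$ per vertex per fold; the package
  targets cohort-scale (hundreds of subjects) normative modelling, not
  population-scale cohorts or >100k-vertex meshes.
* The kernel is a declared composite; it covers near-linear and
  inverted-U development but is not a reconstruction of any particular
  published model, and non-Gaussian likelihoods or heteroscedastic
  noise models are out of scope.
* Outputs are tables keyed by vertex id; rendering on cortical meshes
  and reading imaging-native surface formats are out of scope.
* Whether one- or two-sided p-values precede the sign split in the
  analysis this design follows is not determinable from public
  descriptions; two-sided is the package's documented choice.
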