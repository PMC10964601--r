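---
title: "The resting-state FC scores model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The resting-state FC scores model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Healthy aging is accompanied by cognitive decline that standard
neuropsychological scales measure slowly, subjectively and at some cost.
Resting-state fMRI offers an objective alternative: the Pearson
correlation structure of regional BOLD signals (functional connectivity,
FC) carries individual-level information about cognitive status.  The
question this package addresses is how to turn a single older
individual's FC matrix into per-region scores that (a) quantify deviation
from a healthy young reference connectome, (b) localize the regions where
that deviation tracks cognitive performance, and (c) support subject-level
classification of excellent versus poor cognition.

`rsfcsm` implements the full chain on parcellated data (AAL-116 by
default): FC estimation, cross-site harmonization, reference-based
scoring, biomarker-region selection, and extreme-learning-machine (ELM)
classification, together with a synthetic cohort generator that provides
ground truth for every stage.

## The model

### Functional connectivity

For each subject, entry $(i,j)$ of the FC matrix is the Pearson
correlation of the BOLD time series of regions $i$ and $j$.  With $R$
regions the strict upper triangle holds $C = R(R-1)/2$ unique
connections ($C = 6670$ for $R = 116$); `vectorize_upper()` flattens it
in row-major order, the fixed convention shared by the harmonization
stage and `devectorize()`.  No Fisher z-transform is applied anywhere:
the downstream index is defined on raw correlations.

### Site harmonization

Pooling a young reference cohort from one scanner with an older cohort
from another introduces additive and multiplicative site effects per
connection.  `fit_combat()`/`apply_combat()` implement location/scale
empirical-Bayes harmonization: for subject $j$ at site $i$ and connection
$v$,

$$y^{adj}_{ijv} = \frac{y_{ijv} - \hat\alpha_v - X_{ij}\hat\beta_v -
\gamma^*_{iv}}{\delta^*_{iv}} + \hat\alpha_v + X_{ij}\hat\beta_v ,$$

where $\hat\alpha_v$ is the grand intercept, $X$ an optional biological
covariate design, and $\gamma^*_{iv}$, $\delta^*_{iv}$ the per-site
additive and multiplicative effects after parametric empirical-Bayes
shrinkage (normal prior on the standardized $\gamma$, inverse-gamma on
$\delta^2$, method-of-moments hyperparameters, iterative conditional
updates to an absolute tolerance of $10^{-6}$).  Only the $C$
upper-triangle values are harmonized; matrices are then rebuilt with unit
diagonal.  Harmonized correlations may leave $[-1, 1]$; they are accepted
downstream because the scoring stage only uses profile correlations.

Two practical points deserve emphasis:

* **Residuals scale with sampling noise.**  The EB-shrunken site effect
  removes the *true* site effect, not the finite-sample fluctuation of
  each connection's site mean; post-adjustment between-site differences
  are of order $\sigma\sqrt{2/n}$.  Tests of removal quality therefore
  use well-powered simulations (hundreds of subjects per site) so that
  this residual is small relative to the tolerance being checked.
* **Confounded designs need signal protection.**  In the emulated study
  layout all youth sit at one site and all older subjects at the other,
  so the youth/older contrast is *not* estimable separately from site.
  Unprotected harmonization then recenters the older site toward the
  pooled older mean; because the deviation score below is a magnitude,
  this inflates the excellent group's apparent deviation and deflates the
  poor group's, collapsing the between-group signal.  The pipeline
  therefore includes a poor-vs-rest dummy covariate by default (a full
  three-level cohort coding would be collinear with the site design).
  This protects the excellent-versus-poor contrast — the one that drives
  region selection and classification — while the residual
  excellent-versus-youth deviation at the shared site is partially
  absorbed into the site effect, an unavoidable cost of the confounded
  design.  Set `harmonization: covariates: "none"` to disable.

### The connectome distinctiveness index and its Z score

Let $f_{s,i}$ be region $i$'s connectivity profile in subject $s$: row
$i$ of the FC matrix with the self-connection removed (length $R-1$; the
constant 1 would bias profile correlations).  Against a reference cohort
of $N$ young subjects,

$$\mathrm{CDI}_{s,i} = \frac{1}{N-1} \sum_{p=1}^{N}
\bigl(1 - \mathrm{corr}(f_{s,i}, f_{p,i})\bigr).$$

The sum has $N$ terms but the divisor is $N-1$, and the definition is
implemented literally.  When the reference cohort is scored against
itself the self term is exactly $0$, which makes the divisor natural; for
non-reference subjects the index is uniformly inflated by $N/(N-1)$,
which is harmless after standardization and is deliberately not
"corrected".

The rs-FCSM score standardizes CDI against the reference cohort's own
distribution: with columnwise mean $\overline{\mathrm{CDI}}_i$ and sample
($N-1$) standard deviation $s_i$ over the youth cohort,

$$Z_{s,i} = \frac{\mathrm{CDI}_{s,i} - \overline{\mathrm{CDI}}_i}{s_i}.$$

Higher $Z$ means a larger deviation of region $i$'s connectivity profile
from the young connectome.  A region with zero reference spread makes $Z$
undefined and is an error by default (`sd_floor` provides an explicit
escape hatch).  Applying the standardization to the reference cohort
itself returns columns with mean 0 and sample standard deviation 1 to
machine precision — a useful end-to-end self-check.

### Biomarker-region selection

With the older cohort split into excellent- and poor-cognition groups,
each region gets

* `difference_mean`: the absolute difference of the two groups' mean
  $Z$ (the sign carries no information for ranking), and
* `sum_std`: the sum of the two groups' $Z$ standard deviations.

A region is selected iff it lies in the top $\lceil 0.10\,R\rceil$
regions by `difference_mean` ($12$ of $116$) **and not** in the top
$\lceil 0.10\,R\rceil$ by `sum_std`.  Ties break by ascending region
index.  The conjunction matters: a large mean gap produced by a few
extreme subjects comes with a large dispersion and is rejected.  Selected
(and all other) regions are annotated with a two-sided two-sample t-test
(pooled variance by default, Welch optional), Bonferroni-corrected over
all $R$ regions (the strict reading; the multiplier is configurable), and
with the ROC AUC computed by the rank (Mann–Whitney) formulation with
half credit for ties, excellent group as the positive class.  An AUC
below 0.5 is reported as-is, with the orientation documented, rather than
silently flipped.

### Extreme learning machine

The classifier is a single-hidden-layer network whose input weights
($\mathrm{Uniform}(-1,1)$) and biases ($\mathrm{Uniform}(0,1)$) are drawn
once from a seeded generator and never trained, following the referenced
MATLAB `elmtrain` convention; the hidden layer applies a logistic sigmoid
(500 units by default) and the readout solves the one-hot least-squares
problem with the Moore–Penrose pseudoinverse (SVD, default cutoff, no
ridge term).  Labels follow the cognition coding 1 = poor, 2 = excellent;
ties in the output scores go to the lower label.  Features are
standardized to the training fold's mean and standard deviation by
default (toggleable); the method is otherwise scale-sensitive through the
fixed weight range.  When the hidden width reaches the training-set size
the readout interpolates, so training accuracy is 100% — a property the
tests assert, and a reminder that test-fold metrics, not training fit,
are the meaningful quantity.

Evaluation uses stratified N-fold cross-validation (default $N = 10$):
subjects are shuffled within class and dealt cyclically across folds
(continuing the deal across classes), so per-class counts and fold totals
each differ by at most one — 98 subjects yield eight folds of 10 and two
of 9.  Per fold, sensitivity (true-positive rate on the excellent class),
specificity and accuracy are reported in percent with their confusion
counts, plus the mean ± sample standard deviation across folds.
`permutation_baseline()` re-runs the cross-validation under label
permutation; with the 55/43 class split the null accuracy sits near the
majority share (≈ 50–56%), a sanity bound the tests enforce loosely.

## The synthetic cohort generator

`generate_cohort()` emulates the two-database setting: 90 youth at a
"GSP" site and 55 + 43 older subjects at a "LEiDA" site, 116 regions,
150 timepoints.  Subjects are latent-factor Gaussians: region loadings on
8 "networks" (dominant loading $U(0.6, 0.9)$, cross-talk $N(0, 0.08)$,
unique noise sd 0.7) with per-subject loading jitter ($N(0, 0.1)$); FC is
computed from 150 simulated timepoints, so realistic sampling noise is
present throughout.  The generator plants three kinds of structure:

* **Biomarker regions** (default six; at 116 regions the
  parahippocampal/lingual/mid-occipital/mid-temporal set 40, 47, 51, 52,
  86, 87): the region's loading row is rotated toward *another* network's
  axis (orthogonalized against its own loadings) by magnitude 0.1 in the
  excellent cohort and 0.5 in the poor cohort, with small per-subject
  jitter (sd = 0.05 × magnitude).  Two design points were learned the
  hard way and are worth recording.  First, a *random* rotation direction
  can land close to the region's own loading direction, in which case the
  planted effect all but vanishes for that region; rotating toward a
  different network's axis makes the profile change comparable across
  planted regions.  Second, the within-cohort spread of a deviation score
  grows with the deviation itself (the linear cross-term between the
  planted displacement and subject noise), so generous magnitude jitter
  pushes exactly the true regions into the top-10% `sum_std` set that the
  dual rule excludes.  The planted effect is therefore a consistent
  cohort-level shift, not extra dispersion.
* **Dispersion regions** (default twelve, disjoint from the biomarker
  set): both older cohorts deviate with a random per-subject direction
  and magnitude ($N(0.4, 0.2)$), modelling aging-related between-subject
  heterogeneity with no cognition signal.  These populate the high
  `sum_std` tail, giving the second arm of the selection rule something
  real to reject — mirroring the partially overlapping top-10% sets seen
  in real data.  Without them the rule's exclusion arm is either idle or,
  worse, triggered only by the true regions.
* **Site effects**: in matrix mode (the default), per-connection additive
  offsets ($N(0, 0.1)$) and multiplicative scalings ($e^{N(0, 0.1)}$)
  applied to the older site's connection vectors; in time-series mode,
  a site-specific latent signal mixed into the series, so site effects
  emerge through the FC computation itself.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation, head motion, physiological noise, atlas misregistration,
site differences in temporal SNR, and any topography of real resting-state
networks.  Passing tests therefore demonstrate that the pipeline recovers
the kind of signal it assumes — region-level profile deviations riding on
a shared covariance — not that it would perform identically on real
multi-site data.

## Numerical choices and degenerate inputs

* FC matrices must be symmetric to $10^{-12}$ at construction ( $10^{-9}$
  tolerance on file ingest, configurable); a diagonal that is not exactly
  1 on ingest is reset to 1 with a warning, since self-correlation is
  definitionally 1 and the diagonal enters no computation.
* Zero-variance time series columns, constant connectivity profiles and
  degenerate (zero-spread) references are named errors, never silent NaNs.
* Connections with zero variance across all subjects pass through
  harmonization unadjusted and are logged.
* The ELM pseudoinverse uses `MASS::ginv` (SVD with its default relative
  cutoff); no regularization is added because the referenced procedure
  specifies none.
* Top-k ranking ties break deterministically by ascending region index.
* All randomness (generator, fold assignment, ELM weights, permutations)
  is derived from explicit integer seeds; identical config + seed gives
  identical output, byte for byte.

## Problem sizes used in the shipped checks

The test suite exercises reduced geometries (20–30 regions, 100
timepoints, cohorts of 10–30) for unit-level properties, and the full
emulated layout (116 regions, 90/55/43 subjects) for end-to-end checks:
the standardization identity, planted-region recovery across 20
replicate studies, and cross-validated classification across 10
replicate studies.  Harmonization-quality checks use two-site Gaussian
simulations of 300–400 subjects at 300–1000 connections, sized so that
finite-sample residuals sit well below the tolerances being asserted.
The acceptance script (`scripts/acceptance.R`) reruns the full-size
pipeline on 10 replicate studies.

## Known limitations

* The dual top-10% rule is a fixed-fraction heuristic; it has no error
  control and its recovery depends on the dispersion structure of the
  null regions, as the generator design above makes explicit.
* With site fully confounded with the youth/older contrast, no
  harmonization scheme can separate "site" from "aging"; the default
  covariate protection preserves the within-older contrast only.
* The ELM's random features make per-seed accuracy noisy at these sample
  sizes (± a few percent); reported summaries average over folds, and the
  acceptance script over replicate studies.
* Eq.-level fidelity is prioritized over statistical taste in two places:
  the $N$-term/$N-1$-divisor CDI, and the absence of any Fisher
  transform; both are documented rather than changed.
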