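---
title: "Statistical-genetics methods for biomass-derived material experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-genetics methods for biomass-derived material experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoherit)
```

## The experimental system and its model

`nanoherit` analyses hierarchically structured biomass-material experiments
of the biomass-to-nanopaper type: cellulose nanofibres (CNF) are produced
from several biomass varieties and plant sections, fibrillated at several
homogenisation energy levels, fabricated into duplicate nanopaper sheets,
and tested on several strips per sheet. The reference layout is 4 sorghum
varieties x 3 plant sections (nested within variety) x 3 energy levels x
2 nanopaper duplicates x 8 strips = 576 strip observations per metric.

Every analysis in the package starts from the additive random-effects model
for a measured trait $y$ (e.g. the nanopaper tensile index):

$$y = \mu + g_{\text{variety}} + g_{\text{section(variety)}}
      + e_{\text{energy}} + n_{\text{sheet}} + \varepsilon,$$

with each effect Gaussian, mean zero, and its own variance component. The
"genetic" terms are the biomass factors (variety and section-within-variety);
the "environment" is the processing pseudo-environment (energy level, sheet
fabrication, strip-to-strip residual). All effects are treated as random —
including the ordinal energy factor — because variance partitioning requires
a variance for every term; this mirrors the converted random-effects analysis
that the source study reports, not a claim that energy is sampled from a
population.

### Two codings of the replication factors

The model formula, written literally, shares nanopaper duplicate labels
(1–2) and strip labels (1–8) across all samples, so "duplicate 1" is a
single factor level common to every variety/section/energy cell. That is
rarely the physical reality (each sheet is its own object), but it is the
structure under which a separate strip-within-duplicate component is
estimable, and it is what reproduces a six-component partition of the
reference kind. `bn_model("literal")` provides it.

`bn_model("nested")` is the default and the defensible analysis: each
duplicate sheet is nested within its variety x section x energy sample, and
strips are the observational unit — strip-to-strip variation *is* the
residual stratum, so the nested model has no separate strip term (a nested
strip term would carry one observation per level and be confounded with the
residual; the fitting functions refuse it explicitly).

## Variance component estimation

Two estimators are provided, both authored in this package:

* **Expected mean squares (`ems_components`)** — the method-of-moments
  estimator for balanced layouts. Sequential analysis-of-variance strata are
  built as orthonormal increment bases (term order must run coarse-to-fine
  along nesting chains; ties between crossed terms are resolved by the order
  they appear in the `model_spec`, which does not affect balanced layouts).
  Each mean square's expectation is an exact linear combination of the
  component variances, with coefficients computed from the design's
  indicator matrices rather than from closed-form formulas, so any balanced
  crossing/nesting structure is handled uniformly. Negative solutions are
  truncated to zero and flagged; the untruncated solutions are retained in
  `$raw` because they, not the truncated values, are the unbiased quantities
  (a Monte-Carlo mean of truncated estimates is biased upward for small
  components). `ems_prepare()`/`ems_refit()` expose the design-preparation /
  response-refit split so bootstrap and Monte-Carlo loops cost microseconds
  per refit.

* **EM-REML (`reml_components`)** — restricted maximum likelihood via the
  classical EM algorithm on Henderson's mixed-model equations, for general
  (including unbalanced) layouts. Each sweep solves the mixed-model system
  (coefficient matrix of size 1 + total random levels, so sweeps are cheap),
  updates every component from its BLUPs and their conditional variances,
  and the restricted log-likelihood — recorded in `$loglik_trace` — never
  decreases. Components stay non-negative by construction.

Numerical behaviour worth knowing: EM components that belong on the zero
boundary decay like $c/\text{iteration}$, so with the default
`tol = 1e-8` on successive component changes a boundary fit often reaches
`max_iter` with `converged = FALSE` while the interior components are
already stable to many digits; raise `max_iter` (sweeps are cheap) when the
flag matters. On balanced data with an interior solution the two estimators
agree to high precision (the test suite requires 1e-3 relative and observes
~1e-11), and both match `lme4::lmer` on shared fixtures.

## Heritability shares

`factor_shares()` divides every component — residual included — by the total
variance, which is what makes the share column sum to 100%. The genetic
heritability of a metric is the summed share of the genetic terms
(default `Variety` + `Section:Variety`):

```{r shares}
comps <- read.csv(system.file("extdata", "tensile_index_varcomp.csv",
                              package = "nanoherit"))
partition <- factor_shares(stats::setNames(comps$variance, comps$term))
partition
round(100 * genetic_heritability(stats::setNames(comps$variance,
                                                 comps$term)), 1)
```

Shares are computed from unrounded variances; feeding already-rounded
variances (as above) reproduces a published share column only to the
rounding of its inputs, which is why sub-0.01% shares of near-zero
components are not recoverable from two-decimal variance tables.

`bootstrap_share_ci()` gives parametric-bootstrap percentile intervals
(type-1 quantiles, so two replicates yield their min/max) for every share.
Calibration is good for strata with adequate degrees of freedom (in our
checks, coverage ~0.89 for the 8-df section term and ~0.88 for the residual
at nominal 95%), but the energy stratum of a 3-level design has 2 degrees of
freedom: its share estimate is so variable that any plug-in bootstrap
re-centres on a noisy point value and undercovers (~0.75 observed). Treat
energy-share intervals as descriptive, not calibrated — a limitation of the
design, not of the bootstrap implementation.

## Synthetic data

`simulate_observations()` draws every effect independently from
$N(0, \sigma^2_{\text{term}})$ and always produces a fully balanced table;
`simulate_metric_matrix()` draws sample-by-metric populations from a
multivariate normal (via the symmetric eigendecomposition, so exact
positive-semidefiniteness with zero eigenvalues is allowed);
`planted_block_metrics()` plants block-correlated metric groups for cluster
recovery scoring. Seeds are explicit arguments and the caller's RNG state is
restored afterwards.

What the generator emulates: the factorial layout, the relative variance
magnitudes, and the correlation structure among characterisation metrics
(`default_metric_cov_spec()` uses a three-factor loading model — fibre
length/coarseness, fines, consolidation quality — with means and spreads on
typical CNF scales). What it does not emulate: non-Gaussian marginals of
real fibre-analyser metrics (skewness, physical bounds), energy as a
dose-ordered fixed effect, or instrument drift. Green tests therefore
demonstrate correctness of the estimators and pipelines under the stated
model, not robustness to those departures.

## Clustering

The default pipelines are the field-standard choices and fully
configurable: metrics are z-standardized, then metric clustering uses
correlation distance ($1 - r$) with average linkage, and sample clustering
uses Euclidean distance with Ward linkage. Agglomeration sorts labels before
merging so equal-distance ties always resolve toward the smallest label
pair, making dendrograms reproducible regardless of input order; `cut()`
numbers groups by their lexicographically smallest member. Newick export
writes branch lengths as height differences (leaves at height zero), so the
root-to-tip path equals the top merge height; labels are sanitised of
format-breaking characters. Constant metrics are flagged and mapped to zero
rather than failing, so a degenerate column cannot poison a distance matrix
with NaNs.

## Quality scores and selection gradients

A quality definition is a named, weighted, direction-signed set of
constituent metrics. Each constituent is min-max rescaled to $[0,1]$ over
the sample population (direction $-1$ reverses it), then combined as a
weighted mean — bounded, tunable, and invariant to affine positive
rescaling of any constituent. The shipped defaults are `Q1` (tensile index
alone: quality as sheet strength) and `Q5` (sedimentation aspect ratio +
water retention value, equal weights: quality as nanofibre-water
interaction); the equal Q5 weighting is a package default, chosen because no
canonical weighting is established.

The selection gradient of a trait is the OLS slope of the quality score on
the trait. Traits are z-standardized by default so gradients of
incommensurable metrics share one axis; correspondingly `g_matrix()`
defaults to the correlation matrix, keeping the breeder's-equation product
$\Delta \bar z = G\beta$ unit-coherent. Raw-scale analysis (`standardize_trait
= FALSE`, `standardized = FALSE`) and mean-relativized fitness are available
as flags since conventions differ across studies. A constant trait or
constant constituent is an error (its rescaling or slope is undefined), and
`predicted_response()` aligns $G$ and $\beta$ by metric label, refusing
silently mismatched inputs.

Production of CNF is not an evolving system: one round of "response to
selection" is a ranking device that weighs each metric's association with
quality by the population's variance-covariance structure, not a prediction
of generational change, and no multi-generation iteration is offered.

## Problem sizes and determinism

The test suite and the acceptance script simulate at the full 576-row
reference design where the check concerns that design (200-replicate
estimator recovery, bootstrap calibration) and at a 72-row three-variety
design for estimator-agreement checks; planted-block cluster fixtures use
200–500 samples, where exact recovery (adjusted Rand = 1) is the expected
behaviour for within-block correlation at or above 0.8. All stochastic
steps take explicit seeds; the acceptance script derives every seed from its
`--seed` argument.

## Known limitations

* Expected-mean-squares estimation requires balance; unbalanced tables are
  redirected to EM-REML.
* EM-REML convergence flagging near the zero boundary is conservative (see
  above); estimates are reliable before the flag clears.
* Plug-in bootstrap intervals for shares of low-df strata (the 3-level
  energy factor) undercover; see the heritability section.
* The energy factor is modelled as random with exchangeable levels; no
  dose-response (ordinal trend) structure is fitted.
* Cluster memberships on real data depend on the distance/linkage choices;
  the defaults are conventions, and the package treats them as configuration
  rather than findings.
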