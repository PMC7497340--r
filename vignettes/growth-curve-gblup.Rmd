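---
title: "Models and methods: VI growth curves, GBLUP and random regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: VI growth curves, GBLUP and random regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viGBLUP)
```

## The data this package models

A hybrid maize trial lays out each hybrid once per replicate block (an
RCBD, typically two blocks). A UAV flies the trial four to six times per
season; per flight, each plot contributes mean band reflectances from which
six vegetation indices are computed (`compute_all_indices()`): NDVI,
GNDVI, NDRE, SAVI (soil factor `L = 0.5`), EVI and the NIR/Red ratio. A
log10 option exists (`log10_transform()`), but the default pipeline
analyzes untransformed values because the transform does not materially
change mixed-model results for ratio-type indices. Reflectances are
assumed to be fractions in [0, 1]; this matters for SAVI and EVI, whose
additive constants are not scale-invariant.

Calendar time is replaced by thermal time: daily growing degree days
`(Tmax' + Tmin')/2 - 10`, with both temperatures floored at the 10 degree C
base and capped at 30 degree C, accumulated from planting to each flight
(`cumulative_gdd()`). Both the planting day and the flight day are included
in the sum; the convention is stated here because sources are usually
silent about it and it shifts every cumulative value by one day's GDD.

## Relationships for single-cross hybrids

Marker QC removes SNPs with more than 15% missing calls, minor allele
frequency below 0.01, or heterozygosity above 1% — in that order, each
marker attributed to the first filter it fails (`qc_markers()`). Remaining
missing calls are imputed with the marker mode, ties broken toward the
lower genotype code so imputation is deterministic (`impute_mode()`).

Each parental panel gets its own VanRaden (method 1) GRM,
`G = WW' / (2 sum p_j (1 - p_j))` with `W` centered by twice the
within-panel allele frequency. Assuming the two panels are unrelated, the
hybrid relationship is the average of the parental relationships,
`r_ij = 0.5 (r_{m_i m_j} + r_{p_i p_j})`, applied to diagonals as well
(`hybrid_grm()`). A diagonal epsilon of 1e-6 keeps every matrix positive
definite for the mixed-model equations; conditioning, not shrinkage, is
its only purpose.

## REML by EM, and why monotonicity is a design goal

All three mixed models — single-trait GBLUP, bivariate GBLUP, and the
random regression — are estimated by EM-REML. EM was chosen over
Newton-type (average-information) updates because every accepted iteration
provably does not decrease the restricted log-likelihood; the test suite
asserts this per-iteration for every fit it runs, which turns a classical
convergence property into a standing regression test on the engine.

Two engines implement the E-step:

* **Balanced designs** (every phenotyped hybrid observed once per
  replicate, all flights present): records are rotated into the eigenbasis
  of `G`, where the model decomposes into independent blocks of size
  (replicates x slots) per eigenvalue. Each EM iteration is a set of
  vectorized O(q) updates and never forms a large linear system. The
  permanent-environment term of the random regression is absorbed into the
  per-plot residual covariance `Phi Sigma_pe Phi' + diag(sigma_t^2)` and
  recovered in the E-step.
* **Unbalanced bivariate data** (cross-validation masking): Henderson's
  mixed-model equations over all hybrids in `G`. Plots recorded for both
  traits carry the full 2 x 2 residual covariance; single-trait plots carry
  the marginal variance. Missing trait records are treated as latent data
  inside EM, which keeps the residual M-step in closed form and preserves
  monotonicity. Residual covariance requires at least three jointly
  recorded plots.

Both engines were cross-checked against independent dense oracles (direct
optimization of the restricted likelihood built from the full `V` matrix);
estimates agree to at least six digits, and at fixed variance components
the BLUP solutions match a generalized-least-squares solve to 1e-8
(`mme_solve()` and the acceptance suite).

Numerical choices: starting values give half the phenotypic variance to
each component, with covariances started at `0.05 sqrt(v1 v2)`; interim
non-positive-definite covariance matrices are bent by flooring eigenvalues
at 1e-6 of the trace, and every bending is counted in the fit object;
convergence is declared when the log-likelihood changes by less than
`tol * (1 + |loglik|)` (default `tol = 1e-8`) *and* the largest relative
parameter change is below 1e-6. The relative form matters: fits whose
genetic correlation approaches the +-1 boundary crawl along it with
per-iteration log-likelihood gains that never reach an absolute 1e-8, yet
are converged by any practical standard. `max_iter` defaults to 500 and is
deliberately configurable — boundary-bound bivariate fits can need several
thousand cheap iterations in the eigen engine.

## Fixed effects

Every model uses replicate-cell means as fixed effects: replicate for the
single- and multi-trait models (equivalent to intercept plus replicate)
and replicate-by-time cells for the random regression (a saturated mean
curve per block, so the spline carries only deviations). No other
covariates are fitted.

## The random-regression model

With knots at a subset of flight GDDs, a record at thermal time `t` between
knots k and k+1 gets covariables
`z_k = (GDD_{k+1} - t) / (GDD_{k+1} - GDD_k)`, `z_{k+1} = 1 - z_k`, all
other entries exactly zero; at a knot the vector is an indicator
(`spline_covariables()`). Genetic spline coefficients have covariance
`Sigma_a (x) G`; one permanent-environment coefficient vector per plot
(covariance `Sigma_pe (x) I`) carries the within-plot correlation of
repeated records, and residuals are independent with one variance per time
point. Genetic covariance between any two times is reconstructed as
`z(t)' Sigma_a z(s)` (`reconstruct_covariance()`), exact at knot pairs.

Knot placement is a configuration choice. Defaults in the simulation
config use three knots at the first, middle and last flight; a four-knot
variant (first two and last two flights) is equally valid, and with few
flights there is little room for optimizing placement. The first and last
knots must flank all records — the basis does not extrapolate.

**Identifiability at boundary knots.** A knot that coincides with the
first or last flight loads that flight alone through an indicator
covariable, so its permanent-environment variance separates from that
flight's residual variance only through weak cross-time covariances. Its
REML estimate is therefore unbiased but noisy (sampling error amplified
roughly by the inverse covariable weight). Consequences adopted here: the
genetic covariance `Sigma_a` — the quantity of scientific interest — is
well identified and is what parameter-recovery tests check elementwise;
boundary-knot `Sigma_pe` entries should be interpreted only through the
reconstructed within-plot covariances, and the null-pe test compares total
pe variance against fits under a true nonzero pe rather than holding the
boundary coefficient to a threshold at its own noise level.

The random-regression fitter requires complete balanced plot x time data
(a flight dropped for cause should be dropped for all plots); this mirrors
how such seasons are analyzed in practice and keeps the fast engine exact.

## Cross-validation design

`make_folds()` partitions hybrids (not plots) into five folds differing in
size by at most one. For the single-trait benchmark, a fold's hybrids lose
all records of the target trait but remain in `G`; variance components are
re-estimated in each training set to avoid leakage, and masked hybrids are
predicted through their genomic relationships (`a_u = G_uo G_oo^{-1} a_o`,
which equals the full MME solution for record-free individuals). The
multi-trait variant keeps the secondary VI observed for every hybrid and
reads the masked hybrids' BLUPs directly off the bivariate MME. Accuracy
is the Pearson correlation between masked plot-level raw phenotypes and
the predicted genetic value of their hybrid, averaged over folds
(fold-averaging, not pooled-then-correlated, matching how fivefold
averages are usually reported). Folds whose masked set has zero phenotypic
or predictive variance are excluded from the mean with a warning.

## What the synthetic-data generator does and does not emulate

`sim_config()` fixes the study conditions: five flights at GDD 524, 816,
1129, 1173, 1501 (a realistic mid-May-planting schedule), three knots,
two replicates, a logistic mean VI curve rising from about 0.44 to 0.91
(VIs saturate late in the season), genetic coefficient SDs of 0.04-0.05
with correlations 0.5-0.8 across knots, permanent-environment variance
9e-4 and per-flight residual variances 0.9e-3 to 1.6e-3 — together giving
per-flight heritabilities around 0.3-0.55, the range reported for maize
VIs. End-of-season traits are yield-like (mean 180, total variance 1000,
default h2 0.4) and moisture-like (mean 20, total variance 5, default h2
0.85), each built to have a chosen genetic correlation (default 0.8) with
the VI genetic value at the mid-season flight. Genetic draws use a matrix
square root of `G` with negative eigenvalues floored at zero; all
randomness flows from one master seed split into named substreams.

Deliberately not emulated: linkage disequilibrium (markers are
independent), genotype-by-environment interaction (each dataset is one
site-year, as analyses are nested within site-year), band-level
reflectance noise (VI values are generated directly), and spatial field
trends. Passing recovery tests therefore demonstrates correctness of the
estimators under the models' own assumptions — not robustness to model
misspecification in real fields.

## Problem sizes used in the validation suites

Parameter-recovery runs use 400 hybrids x 2 replicates for the
single-trait model (true `sigma_a^2 = 500`, `sigma_e^2 = 850`, 20 seeds),
300 hybrids for the bivariate model (true genetic correlations 0 and 0.8,
20 seeds each) and the random regression, and 150 hybrids x 10 seeds per
scenario for the cross-validation comparison, where bivariate training
fits are warm-started from the full-data fit (a pure optimization detail —
components are still re-estimated per fold). These sizes were chosen so
Monte-Carlo standard errors are comfortably below the tolerances being
checked.

## Known limitations

* Multi-trait models are bivariate only; a five-flight joint multi-trait
  analysis is exactly the case the random regression replaces (and where
  unstructured multi-trait REML tends not to converge anyway).
* Linear splines only; quadratic/Legendre bases and knot-placement
  optimization are out of scope.
* The random-regression fitter does not handle per-plot missing flights.
* EM can need thousands of (cheap) iterations when a correlation sits on
  the boundary; fits that hit `max_iter` are flagged, never silently
  accepted.
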