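---
title: "Multi-parametric scoring of high-content screens: models and choices"
author: "mpdascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric scoring of high-content screens: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdascreen)
```

## The problem

In an image-based (high-content) compound screen, every well of a 384-well
plate is photographed and the phenotype of the well — here, fluorescent
reporter-positive stem-cell colonies — must be reduced to numbers that can
be compared across thousands of wells. Each plate carries *active control*
(AC) wells, in which the desired phenotype is maintained (doxycycline kept
in the medium, so many compact bright colonies), and *negative control*
(NC) wells, in which the phenotype collapses (doxycycline withdrawn:
sparse, small, dim debris). A compound is interesting when its well looks
like the active controls even though the supporting stimulus was removed.

`mpdascreen` implements this multi-parametric analysis end to end:
per-object segmentation and measurement, per-well aggregation into a
112-feature profile, Z′-factor-based feature selection and plate quality
control, Mahalanobis-distance scoring against both control populations,
triage of dead and phenotypically disparate wells, a 1-SD duplicate-run
hit rule, dose-range validation, and target-class summaries.

## Well profiles: the 112-feature catalog

Segmentation (Otsu's threshold with a robust background floor, connected
components, speck removal) yields per-object measurements: six shape
parameters — area, circumference, equivalent-circle diameter, circularity
$4\pi A/P^2$, anisometry (major/minor axis ratio of the second-moment
ellipse), compactness (area over convex-hull area) — and five intensity
values (mean, median, total, max, min). A well's objects, pooled over its
imaging fields, are aggregated with nine statistics (mean, median, sum,
sample SD, CV, min, max, 10th and 90th percentile), giving 99 features;
six covariances (each shape measure with per-object mean intensity) and
seven well-level scalars (object count, foreground area fraction, total
foreground intensity, background mean and SD, mean nearest-neighbour
centroid distance, fraction of objects 3 background-SDs above background)
complete the 112.

The exact feature list of the original instrument software is not public;
this catalog is a reconstruction that uses every named measurement and
statistic family and totals exactly 112. Choices worth knowing:

* *Circularity vs compactness.* Both names appear in the field's feature
  lists; they are deliberately distinct here (isoperimetric ratio vs
  convex-hull solidity) so two names never alias one number.
* *Perimeter.* Chain-code length with Kulpa's weights (0.948 straight,
  1.340 diagonal), which is near-unbiased for smooth shapes; a raw chain
  length would overestimate a disk's perimeter by ~5% and bias
  circularity low. Discretization can still push tiny objects past 1, so
  circularity is capped at the documented rasterization tolerance 1.1.
* *Degenerate wells.* Single-object wells define SD/CV/covariance as 0;
  empty wells are imputed to all-zero features with `no_object_flag` set
  rather than dropped, because phenotype-collapsed (NC-like) wells must
  remain scoreable.
* *Pooling.* Objects are pooled across a well's fields before
  aggregation (pooling-first); per-field aggregation then averaging is a
  defensible alternative, but pooling keeps across-object statistics
  meaningful when fields are sparse.

## Scoring: Z′, feature selection, and Mahalanobis distance

The Z′-factor summarises the assay window between two control readouts:

$$Z' = 1 - \frac{3(\sigma_+ + \sigma_-)}{|\mu_+ - \mu_-|},$$

bounded above by 1, with values ≳ 0.5 denoting an excellent window. Note
the leading $1-$: the statistic is a *penalty* of the control overlap
subtracted from 1; without it the reported "good performance" regime near
0.6 would be impossible.

Per feature, Z′ between the plate's AC and NC wells ranks the catalog;
features clearing a floor (default 0) are kept up to a cap (default 10,
ties broken in catalog order). The cap keeps the control covariance
estimable from a handful of control wells — in practice small
combinations of shape and intensity features carry the window.

Each control population is then modelled as a multivariate normal with a
shrunk covariance,
$\Sigma = (1-\lambda)S + \lambda \,\mathrm{tr}(S)/d\, I$ (default
$\lambda = 0.1$), which is positive definite even when control wells are
scarcer than features. Every well receives two distances,

$$\mathrm{MHD}(x) = \sqrt{(x-\mu)^\top \Sigma^{-1} (x-\mu)},$$

to the AC and NC models, computed by triangular solves from the stored
Cholesky factor (never an explicit inverse). At $\lambda = 0$ the score
is invariant under invertible affine maps of the feature space; features
are z-scaled on the pooled controls before fitting, which is
mathematically irrelevant at $\lambda = 0$ and documented as (mildly)
affecting results at $\lambda > 0$. Models are fit per plate, not pooled
across the screen, so plate-to-plate drift cannot leak into scores.
Plate QC is the Z′ between the AC and NC wells' MHD-to-AC distributions;
plates below a configurable floor (default 0.4) are excluded from hit
calling.

## Triage and hit calling

Wells are triaged into exactly one of four classes: `dead` (fewer than 5
objects), `disparate` (beyond the 95th percentile of *both* control score
distributions — far from both phenotypes), `ac_like`, or `nc_like`.
Dead and disparate wells stay in all tables but can never be hits.

The hit rule formalises "looks like the active controls": per replicate,
a compound passes when its MHD-to-AC is more than 1 SD *below* the mean
MHD-to-AC of that plate's NC wells; a final hit must pass in **every**
replicate (logical AND over duplicates) and be `ac_like` throughout. The
phrase "1 SD from the negative controls" admits a second reading (own
NC-model distance 1 SD above the NC self-distance); it is implemented
behind `hit_rule_config(rule = "nc_self")` but is not the default, since
hits are defined by similarity to the active controls. Dose validation
(8-point series in duplicate) requires ≥ 2 consecutive passing
concentrations in both replicates — the screen literature reports
validation without defining it numerically, so this conservative
criterion is a documented package choice surfaced in every report.

## The synthetic screen generator

No imaging data from the reference screen is deposited, so the package
ships a seeded generator at two levels.

*Image level.* A well field is Gaussian background noise (mean 400, SD 30
counts on a 16-bit scale) plus additive elliptical Gaussian-profile
objects. The AC phenotype averages 25 compact colonies per well (radius
log-normal around 12 px, amplitude ≈ 8× background); the NC phenotype 4
small dim elongated objects. Object placement rejects overlaps (bounded
retries), a well's Poisson budget is split over its 4 fields, and the
rendered truth (centres, radii, amplitudes) travels with each image, so
segmentation can be tested against ground truth. These constants are
stated defaults, not inferences — no pixel size or magnification is
published for the reference instrument.

*Feature level (fast path).* Downstream statistics do not need pixels:
wells are drawn directly in feature space. NC wells are
$N(0, \Sigma)$, AC wells $N(\delta w, \Sigma)$ with a fixed weight
pattern $w$ decaying from 1 to 0.4 over the first 12 of 20 features
(the rest pure noise), and $\Sigma$ an AR(1) correlation matrix
($\rho = 0.3$, unit variances). Planted actives (probability 0.05 per
compound well) sit at `active_effect` of the NC→AC offset; 15% of them
follow a "larger but dimmer" variant (size-like features amplified
1.15×, intensity-like attenuated 0.75×), mirroring the reported
alternative hit phenotype. Duplicate runs share one truth assignment but
draw noise independently.

The separation scalar $\delta$ is the generator's calibration surface:
it was fixed once, by a grid search, so that the *default pipeline's*
mean plate Z′ over seeded plates lands at the reported performance level
of a well-behaved screen (≈ 0.6), and it is not adjusted per run. At the
frozen $\delta = 8$ the mean plate Z′ over 10 plates is ≈ 0.59–0.63 with
an SD of 0.06–0.10 depending on seeds.

What the generator does *not* emulate: colony texture, illumination
gradients, well-edge effects, shot noise, segmentation ambiguity from
touching colonies. Passing tests therefore demonstrate the statistical
machinery and its calibration, not robustness to instrument artifacts.

## Numerical and scale choices

* All randomness flows through explicit seeds; every generator output is
  a pure function of (config, seed), and child seeds stay within 32-bit
  integer range.
* Covariance solves use Cholesky factors; singular post-shrinkage
  covariances raise errors rather than produce infinities.
* Z′ with equal control means raises a degenerate-separation error; a
  noiseless window returns exactly 1.
* Test and example problem sizes — 384-well plates in feature space, 10
  plates for QC calibration checks, 20 seeds for recovery/specificity
  properties, ~100 rendered 256-px fields for segmentation checks — were
  chosen so the whole suite runs in well under a minute of compute per
  property while keeping binomial error bands tight enough to be
  meaningful.

## Known limitations

* The 112-feature catalog is a reconstruction; only its cardinality and
  measure families are anchored in the published description.
* The hit rule's direction and the dose-validation criterion are
  documented interpretations of ambiguous prose; both are configurable.
* Control-well counts per plate (default 16 + 16, minimum 8) are a
  design choice — the reference screen does not state its own.
* No spatial (row/column/edge) artifact correction is included; B-score
  style normalisation is out of scope.
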