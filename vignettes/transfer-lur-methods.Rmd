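---
title: "Transfer-learning land-use regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer-learning land-use regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Land-use regression (LUR) maps long-term air pollution (here NO2 in
ug/m3 or ultrafine particles in particles/cm3) by regressing measured
concentrations on GIS-derived predictors: land-use areas, traffic
intensity, road length and population within buffers around each ~50 m
road segment. Mobile monitoring campaigns provide the response: 1-Hz
geolocated readings, snapped to road segments and aggregated to a
per-segment annual value.

The question this package addresses is what to do for a *target* city
with no measurements at all. Two failure modes stand in the way of simply
applying a model fitted elsewhere:

* **Covariate shift** — the predictor distributions differ,
  P(X_s) != P(X_t). A model fitted where roads carry 2000–5000
  vehicles/day is forced to extrapolate when the target's roads carry
  5000–10000. Regression models are only trustworthy inside the covariate
  range they saw.
* **Conditional shift** — the predictor-to-response relation differs,
  P(Y_s|X_s) != P(Y_t|X_t), e.g. through a different fleet composition
  (electric cars vs diesel trucks at equal traffic intensity).

## The method

### Covariance alignment (CORAL) + ridge

Stage 1 computes the alignment transform minimizing the Frobenius
objective

    min_A || A' C_S A - C_T ||_F^2

where C_S and C_T are the (regularized) feature covariance matrices of
the source and target city. The minimizer is closed-form,

    A = C_S^{-1/2} C_T^{1/2},

a whitening of the source followed by recoloring to the target
covariance; at this A the objective is zero to numerical precision, so
transformed source features have exactly the target covariance. Stage 2
fits a ridge regression of the source concentrations on the aligned
(standardized) source features. Because centered target features already
live in the aligned space, prediction needs no further transform. No
target concentration is used anywhere — covariate shift is addressed,
conditional shift deliberately is not (it cannot be, without target
labels).

Both feature tables are mean-centered per domain before alignment. The
Frobenius objective constrains covariances only; centering removes the
mean shift as well, and anchors predictions at the source's mean
concentration. A consequence worth knowing: aligned predictions span
roughly the range of the source response, so a target whose true levels
sit well above the source's will be predicted with compressed range —
the price of refusing to extrapolate.

### Inverse-distance-weighted model fusion

With several monitored source cities, each one yields a CORAL model for
the target. The predictions are combined with weights

    w_i = d_i^{-p} / sum_j d_j^{-p},   p = 1 by default,

over straight-line (great-circle) distances between declared city
centroids. The weights are constant across target segments: conditional
shifts differ between cities, not within the target. By Tobler's first
law, nearby cities share emission patterns, so up-weighting the near
source damps conditional shift; summing over sources also enriches the
covariate diversity seen in training. The layer is model-agnostic and
wraps stepwise members identically (the unaligned ensemble is the natural
ablation of the alignment step).

With the application geometry — sources at 57 km and 620 km — the near
city carries (1/57)/(1/57 + 1/620) ≈ 0.916 of the weight.

### Stepwise LUR baseline

The supervised baseline (and the local reference model) is forward
stepwise linear regression in the ESCAPE tradition: candidates are
scanned alphabetically and accepted when they raise adjusted R^2 by at
least `gain_min` (default 0.01), their coefficient sign matches an
a-priori constraint (traffic, industry, port, transportation,
residential, population positive; natural, green, agricultural, water
negative), all previously accepted coefficients keep their signs, and no
variance inflation factor exceeds 3. After selection, predictors with
p > 0.10 are pruned. All thresholds are configurable; the defaults are
the convention of this modelling tradition rather than values stated by
any single study. Applied unchanged to another city's features this is
the "directly applied" model — a pure linear extrapolator.

### Evaluation metrics

`evaluate()` reports n, MAE, RMSE, Pearson r, R^2 and Lin's concordance
correlation coefficient. Two conventions matter:

* **R^2 is the squared Pearson correlation**, not 1 − SSE/SST. Under
  systematic bias the two differ; external long-term validation in this
  literature reports the former.
* **CCC uses population (1/n) moments**:
  `2 r sx sy / (sx^2 + sy^2 + (mx − my)^2)`. It penalizes location and
  scale disagreement, so an affine-perfect but biased prediction has
  R^2 = 1 and CCC < 1.

Fixed validation sites are matched to their nearest road segment within
20 m (perpendicular distance), distinct from the 35 m GPS snap threshold
used for mobile readings (half a 50 m segment plus GPS error; the
matching threshold for routine sites is stricter because their positions
are surveyed).

### Preprocessing

The pipeline order is: range filter (NO2 outside [0, 500] ug/m3, UFP
outside [250, 500000] particles/cm3 removed, bounds inclusive),
campaign-wide winsorizing at the 2.5th/97.5th percentiles (type-7
linear-interpolation quantiles — the clamped values depend on the
quantile definition, so it is fixed), additive temporal correction of
NO2 against a routine reference site (subtract the hour's deviation from
the campaign-mean reference level; configurable `additive`/`none` since
the exact correction is a campaign-specific choice), snapping to the
nearest segment (ties to the smallest segment id), and "mean of means":
per segment, the mean of within-drive-day means, unweighted over days.
Winsorizing is applied campaign-wide per pollutant, before snapping — it
is a raw-data step, not a per-segment one.

## The synthetic study generator

`make_study()` builds a three-city world mimicking the application
geometry (a target plus sources at roughly 57 and 620 km). It is the
package's test bed; its defaults are the study conditions, not tuning
knobs.

* **Features**: ten predictors with realistic LUR scales (traffic in
  vehicles/day, buffer areas in m^2, population counts), multivariate
  normal with moderate within-group correlation, rectified at 0. The
  rectification slightly perturbs the requested covariance (checked to be
  within 5% at n = 10000 away from the boundary).
* **True surface**: `Y = intercept + s(X) (beta_general + beta_city) + eps`,
  giving an NO2-like surface (mean ≈ 28, SD ≈ 4 ug/m3). `s` saturates
  each column above a knee at the base mean + 0.5 SD with residual slope
  0.1. The saturation is the point: with a strictly linear truth, a
  correctly specified linear model would extrapolate perfectly and no
  alignment method could beat it under pure covariate shift. Saturating
  responses (dispersion, background mixing) are also the physically
  plausible reason extrapolated LUR predictions overshoot.
* **Covariate shift**: target feature means shifted by 5.3 source SDs
  along an urban-densification direction (traffic, industry, port,
  residential, population up; natural and green areas down), SDs scaled
  by 1.3. The magnitude matches the illustrative traffic scenario of a
  source with 2000–5000 vehicles/day and a target with 5000–10000.
* **Conditional shift**: per-city coefficient perturbations drawn from a
  zero-mean Gaussian process over city centroids with covariance
  `tau^2 exp(-d / 200 km)` (tau equal to |beta_general| per coordinate),
  then projected orthogonal to the mean covariate profile so they
  redistribute the response across predictors without changing the
  citywide level — pattern differences, with distance-decaying
  correlation the IDW step can exploit. Nearness helps: at 57 km the
  kernel correlation is 0.75, at 620 km it is 0.045.
* **Campaigns**: each day an independent random subset of segments is
  driven (the daily probability calibrated so the mean drive pass over
  measured segments matches the request — 1.8 over 30 days for sources,
  1.7 over 40 days for the target); each visit yields 5 readings
  `Y + day_effect + noise` with a campaign-wide day effect (SD 3 ug/m3,
  meteorology) and 1-Hz instrument noise (SD 8 ug/m3).

What the generator does *not* emulate: street-canyon geometry, spatially
autocorrelated residuals within a city, on-road vs roadside bias,
seasonal confounding between campaign period and annual mean, and
non-Gaussian heavy-tailed feature distributions. Passing tests therefore
show that the estimators behave as designed under the stated shift
mechanisms — not that the method attains any particular accuracy on real
campaigns.

## Numerical choices

* Matrix square roots via symmetric eigendecomposition with eigenvalues
  clipped at `lambda_reg` — deterministic and robust to the rank
  deficiency of feature tables with many all-zero buffer columns
  (Cholesky would fail there).
* `lambda_reg` defaults to 1e-5 of the mean diagonal variance (relative
  regularization; scale-free across pollutants and units).
* `ridge_alpha` defaults to 1.0 on standardized aligned features, with an
  optional 5-fold CV over a log grid on the source
  (`ridge_alpha = "cv"`).
* Disk–polygon intersection areas are exact (Green's theorem with
  circular-sector terms), not discretized; in-buffer road lengths use
  closed-form chord clipping. Buffers are centered on segment midpoints
  (deterministic and cheap; a whole-line buffer differs negligibly at
  50 m segment length).
* Stepwise ties on equal adjusted-R^2 gain resolve alphabetically, making
  the fit invariant to column order.
* Local planar coordinates come from an equirectangular projection about
  a per-city origin — adequate at city scale; inter-city distances are
  great-circle.

## Problem sizes

The shipped tests and the acceptance script use 3 cities x 2000 segments
x 20 seeds for the shift studies, 500 segments for the learning curve
(day grid 5 vs 40, 20 resamples), and n <= 10 covariance dimensions for
the alignment checks — sizes at which every distributional claim asserted
in the tests is stable, while a full run stays in the minutes range on a
single core.

## Known limitations

* CORAL corrects second moments only; a nonlinear covariate shift, or a
  conditional shift, passes through untouched. The ensemble damps but
  does not remove conditional shift.
* Per-domain mean centering anchors predictions at the source mean
  response; the citywide level of the target is not identified without
  any target information.
* The IDW weights are fixed by geometry. Learned or dispersion-informed
  weights are out of scope.
* The GeoJSON reader handles LineStrings and simple Polygons (outer
  rings); polygon holes and MultiGeometries are not supported.
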