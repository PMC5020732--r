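---
title: "Land use regression for nitrogen oxides: models, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression for nitrogen oxides: models, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurcity)
```

## The modelling problem

Land use regression (LUR) predicts ambient pollutant concentrations at
unmonitored locations from GIS-derived covariates. Given annual or seasonal
mean concentrations $y_s$ of NO, NO$_2$ or NO$_x$ (ppb) at monitoring
stations $s$, and a catalog of *potentially predictive variables* (PPVs)
$x_{sk}$ — buffer sums of road length and land-use area, distances and log
distances to features, population kernel densities, traffic/distance
ratios, elevation and slope — the model is an ordinary linear regression on
a transformed response,

$$ t(y_s) = \beta_0 + \sum_{k \in M} \beta_k\, g_k(x_{sk}) + \varepsilon_s,
   \qquad t(y) = (\log y)^p , $$

where $M$ is a small selected subset of the catalog, $g_k$ is a per-PPV
linearizing transform, and $p$ is a power chosen so the transformed
response passes a Shapiro-Wilk normality check ($p = 1$, i.e. a plain log,
whenever $\log y$ already passes). Concentrations are strictly positive and
roughly multiplicative in their drivers, which motivates the log link; the
extra power accommodates the residual skewness that seasonal means of a
regulatory network often show.

The package implements the whole workflow around that regression: the
spatial feature engineering, the imputation of gappy hourly series that
produces $y_s$, a constrained stepwise selection of $M$, post-fit
diagnostics, mapping with floor/ceiling rules, and a seasonal comparison of
the mapped surfaces. Because the monitoring and GIS data that motivated the
design are not public, the package also ships a synthetic city generator
with known ground truth; every end-to-end claim the package makes is tested
against that ground truth.

## Spatial predictors

All predictors are computed on a planar square grid (`raster_grid`) from
vector inputs (`vector_layer`), mirroring standard GIS tooling:

* **Traffic surrogates** — rasterize a road class to presence cells, sum
  presence over a circular neighborhood (`focal_sum`), multiply by the cell
  size: road length (m) within the buffer. Circular neighborhoods are used
  throughout; the buffer radius is the neighborhood radius.
* **Land use** — the same with polygon presence and cell area:
  land-use area (m²) in the buffer, for ten land-use types
  (RES, GRS, URF, IND, OFIC, TRS, SNS, AGR, ARD, OTHR).
* **Distance variables** — exact Euclidean distance transform
  (`euclidean_distance`, centre-to-centre, verified against a brute-force
  scan) and its natural log. `log_distance` computes $\log(d + \epsilon)$
  with $\epsilon$ equal to one cell size, so cells on the feature map to
  $\log(\text{cell size})$ rather than $-\infty$; the offset choice is a
  package decision, made because the GIS convention is not standardized.
* **Population density** — quartic-kernel density (`kernel_density`) of
  weighted census centroids, in persons per km²; the kernel radius is the
  bandwidth. Mass is conserved to well under 1 % for in-grid kernels.
* **Product variables** — buffer sum divided by distance (or squared
  distance) to the same feature class. The denominator is floored at one
  cell size so feature cells never divide by zero; this floor is again a
  package decision on a point the GIS recipe leaves open.
* **Geographic location** — DEM elevation and Horn-stencil slope in
  degrees (`slope_from_dem`; borders use replicated edge cells, so the
  exact stencil holds at interior cells).

The default catalog (`build_catalog()`) contains 210 PPVs in six classes
(26 traffic, 50 land use, 58 distance, 22 population, 52 product,
2 geographic). The distance class is sometimes headed with a count of 60 in
summaries of this design, but its itemization — 15 traffic and land-use
feature types plus 14 named features, each as distance and log-distance —
gives 58, which is what makes the grand total 210; the catalog follows the
itemization and records the note in an attribute. Default buffer radii are
100–500 m for streets, highways and land use, 100–1000 m for the
road-aggregate classes, 400–500 m for bridges, and 500–3000 m in 250 m
steps for the population kernels. The exact radii inside each class are
configurable (`ppv_radii()`) because they are a survey-design choice, not a
property of the algorithm.

Every PPV carries an *a-priori direction of effect*: `+` for traffic,
products and population, `-` for green space and other emission-poor land
uses, the opposite sign for distances to a class, and `none` where no
plausible direction exists (e.g. slope, elevation, distance to hazardous
facilities). These priors are data, not preferences: selection enforces
them as hard constraints.

Before any regression or mapping, nodata cells are set to zero
(`nodata_to_zero`): a cell outside every buffer has zero road length, zero
land-use area, zero density.

## Hourly imputation

A complete year of hourly data has 8760 values per station and pollutant;
regulatory networks typically miss roughly a quarter of them (the package
defaults use 28.1 / 27.7 / 27.6 % for NO / NO$_2$ / NO$_x$). Station means
are therefore computed from multiply-imputed series
(`em_bootstrap_impute`):

1. bootstrap the hourly rows;
2. fit a multivariate normal by EM to stations jointly plus fully observed
   time covariates (sin/cos of hour-of-day and day-of-year, plus eleven
   month indicators — the covariate encoding is a package choice);
3. impute each missing cell of the original matrix by its conditional mean
   plus a draw from the conditional covariance;
4. repeat (default ten runs) and average the station means across runs.

Observed values are never altered, negative imputed concentrations are
clipped to zero before averaging, and convergence is declared when the
relative change in observed-data log-likelihood falls below $10^{-6}$
(at most 200 iterations); a relative ridge of $10^{-6}$ on the covariance
diagonal guards near-singular fits. Imputation is per pollutant and joint
across stations — the cross-station correlation (shared meteorology) is
what the conditional means exploit. Calibration is tested on simulated
correlated data: at 28 % missingness the averaged station means fall within
two Monte-Carlo standard errors of the complete-data means, and the mean
absolute imputation error is monotone in the missingness rate.

Seasons are fixed as **warmer = April–September** and **cooler =
October–March**, with an override argument where a different hemisphere or
climate requires one.

## The selection algorithm

`forward_select()` implements a constrained forward stepwise search. At
each iteration, every not-yet-included candidate is fitted alongside the
current terms, and survives only if **all** of the following hold for the
resulting model:

1. every coefficient matches its a-priori sign where one is assigned
   (checked for all included terms, not just the entrant, so accepted
   models are internally consistent);
2. every predictor has $p < 0.1$;
3. the leave-one-out cross-validated $R^2$ (`loocv_r2`, computed with the
   hat-matrix identity and verified against brute-force refits) strictly
   increases;
4. the largest variance inflation factor stays below the threshold
   (default 5 — a conservative conventional cutoff; reported maxima in
   practice are far lower).

Among survivors, the candidate with the highest adjusted $R^2$ enters;
ties break by lower maximum VIF, then candidate order. The model size is
capped at $\lceil\sqrt{N}\rceil$ terms for $N$ stations (5 terms at
$N = 23$), and the final model's residuals are Shapiro-Wilk checked — a
failure flags the model rather than rejecting it. Every candidate
evaluation is recorded in a trace, and `audit_selection()` re-verifies all
five constraints from the trace and the final fit; the test suite asserts
that no accepted model ever violates them.

Decisions the algorithm leaves open and how the package resolves them:
normality gates use $\alpha = 0.05$; "increases LOOCV $R^2$" is read as a
strict inequality; candidate p-values are evaluated on the model that
includes the candidate; and the response-power candidates are
$\{-4,-3,-2,-1,2,3\}$, covering the exponents that arise for seasonal
nitrogen-oxide means. Predictor linearization (`linearize_ppvs`) chooses
among identity, $\log(x+\epsilon)$, $x^{0.1}$, $x^{0.5}$ and $x^2$ by
maximum absolute Pearson correlation with the transformed response, keeping
the identity on ties.

## Diagnostics, mapping and seasonal comparison

`loocv_coefficient_stability()` refits the selected model once per held-out
station and reports each coefficient's min, max and coefficient of
variation; a stable model keeps every coefficient's direction across
refits. `morans_i()` computes global Moran's I on residuals with
inverse-distance, row-standardized weights by default (k-nearest-neighbour
weights are available), expectation $-1/(n-1)$, and a p-value from the
normal approximation under randomization (a permutation p-value is
available for small networks); the implementation is verified against a
double-loop oracle and an independent reference implementation.

`predict_surface()` evaluates a fitted model cell-wise on the transformed
scale and inverts the response transform to ppb. For even powers the real
root matching the observed response range is taken; cells whose transformed
value is non-invertible are treated as below the floor. `clip_predictions()`
applies the mapping rules: a **limit of prediction** equal to the minimum
observed concentration divided by $\sqrt 2$ (the usual
detection-limit convention) raises low cells, and a ceiling of 120 % of the
maximum observed concentration truncates high ones. Counts of affected
cells are taken before modification, so enlarged + truncated + untouched
always equals the cell total, and clipping is idempotent.

`sample_locations()` draws uniform distinct cells over the mapped domain
(no minimum separation is enforced) and `correlate_predictions()`
correlates the annual/cooler/warmer surfaces there, using Pearson only when
both series of a pair pass a Shapiro-Wilk gate at $\alpha = 0.05$ and
Spearman otherwise.

## The synthetic city and what passing tests mean

`generate_city()` builds a deterministic city from a seed: roads on a
jittered grid in three classes, bridges on major roads, ten land-use types
grown as contiguous regions on a block lattice (which induces realistic
spatial correlation among predictors), eleven facility point kinds, a
central traffic-access-control zone plus a larger irregular critical-episode
zone containing it, census centroids with total and adjusted weights, and a
smooth DEM. `simulate_concentrations()` then draws hourly series from a
log-linear ground truth: log concentration = log base level + seasonal
level shift + (per-season coefficient multipliers x true coefficients x PPV
values) + a deterministic diurnal cycle + a city-wide shared hourly
component + independent noise, with NO$_x$ = NO + NO$_2$ at every hour.
The default truth uses cooler/warmer base ratios of 2.3 (NO) and 1.4
(NO$_2$), matching the seasonal contrast of a heating-dominated city.

The log-linear ground truth is a *testing assumption*: the design it
validates is exactly the model family the regression fits. Passing
recovery tests therefore demonstrates that the pipeline is internally
correct — that selection finds planted variables, estimates their
coefficients, and never violates its own gates — not that any real city
follows a log-linear law. The generator also simplifies reality in ways
worth keeping in mind: no dispersion physics or meteorology beyond a shared
hourly factor, straight roads, block-shaped land-use polygons, and
missingness that is either exactly-MCAR or geometric-length instrument
outages.

One calibration subtlety in the recovery study (`recovery_trial`): its
responses are station *annual means*, and an annual mean over 8760 hours
compresses hourly log-noise by about $\sqrt{8760}$, so the study's default
response noise is 0.005 on the log scale — small, but the faithful
counterpart of a realistic hourly noise near 0.35. Under these conditions,
50 seeded replicates (40 stations, 2 planted predictors among 146
catalog candidates) recover a superset of the planted variables with
correct signs, and the regression on the planted variables returns
coefficients within three standard errors of truth, in well over 90 % of
replicates — with zero constraint violations across all accepted models.

## Problem sizes and numerical choices

Desk-scale runs use coarser grids than the 5 m production resolution the
feature recipes assume; all operations take the cell size as a parameter,
and the defaults in the test suite and validation studies are: 1.5–3 km
cities at 20–40 m cells, 9–40 stations, reduced radii sets (two or three
per class), and 2–10 imputation runs. The bundled pipeline demo (nine
models end to end) runs in well under a minute on one CPU at those sizes;
the full 210-PPV catalog on a 3 km / 20 m city computes in a few seconds.
Focal sums are FFT convolutions (5-smooth padded sizes), exact up to
floating-point round-off of order $10^{-10}$; the distance transform is the
exact two-pass parabolic-envelope algorithm; LOOCV uses the hat-matrix
shortcut, identical to refitting up to $10^{-12}$.

## Known limitations

* Forward selection with hard gates cannot guarantee exact variable
  identification when a decoy is extremely correlated with a planted
  variable (e.g. adjacent buffer radii of the same layer); in such
  replicates a sibling may absorb the signal and the p-value gate then
  blocks the original. This is a property of greedy stepwise search, not
  of the implementation, and is why the recovery criterion accepts a
  superset rather than an exact match.
* `rasterize()`'s length and area-weighted modes are sampling
  approximations (quarter-cell line steps, 4x4 polygon subsamples);
  presence mode, which the predictor recipes use, is exact for the
  geometries the generator produces.
* The EM imputer assumes joint normality on the measurement scale (a log
  option exists); it re-implements the EM-with-bootstrap idea generically
  and does not reproduce any specific software's ridge priors or
  time-series lag options.
* Moran's I weight schemes beyond inverse-distance and kNN (e.g.
  variogram-derived weights), local spatial statistics, and kriging of
  residuals are out of scope.
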