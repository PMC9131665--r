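---
title: "Methods: landscape-based pecky rice damage prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape-based pecky rice damage prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The response is the percentage of pecky rice grains in a paddy's harvest,
arcsine-square-root transformed and expressed in degrees:

$$y = \arcsin\!\sqrt{p/100} \cdot 180/\pi \in [0, 90].$$

The source never states whether the transform uses the square root or
radians; we fix both by consistency: observed damage of at most 0.27 %
must map to roughly 3 on the transformed scale (the reported ceiling of
the transformed values), which only `asin(sqrt(p/100))` in *degrees*
achieves — the radian version saturates at 1.57 and the non-square-root
version maps 0.27 % to 0.15. `arcsine_transform()` and
`inverse_arcsine()` are exact inverses to 1e-10 across the full range.

Two printed prediction equations are carried verbatim as
`original_model()` and `extended_model()`:

* original: $y = -0.09 + 40.05\,S + 52.7\,B - 1.12\,P + \mathrm{RI}_{year}$
* extended: $y = 0.03 + 32.07\,S + 44.5\,B + 2.6\,P + u_{region} + w_{year\,
  in\, region}$

where $S, B, P$ are the areas (km²) of source habitat, soybean and rice
paddy within a 300-m radius of the focal point. The coefficient table of
the underlying model selection reports 44.52 and 2.61 at higher precision
than the printed equation's 44.5 and 2.6; we treat the printed equation as
canonical and expose the precise values behind
`extended_model(precise = TRUE)` rather than resolving the discrepancy.
The original model's year intercepts were never printed; they default to
zero, and `year_mode = "conservative"` reproduces the original study's
precaution of predicting with the largest stored year intercept when no
year is supplied.

Refitting (`fit_lmm()`) estimates the same structure by REML with a
Gaussian error distribution: fixed land-use effects plus random intercepts
for region and year-within-region (or year only, the original structure).
Estimation is delegated to `lme4::lmer`, the field-standard deterministic
REML implementation; the restricted log-likelihood it maximizes is checked
in the test suite against an independent direct evaluation of the profiled
REML criterion on a >1000-node variance-component grid, and against
`nlme::lme` (the implementation the source study used). Wald standard
errors, BLUPs, variance components and Nakagawa–Schielzeth R² values

$$R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \sum_l \sigma^2_l + \sigma^2_e},
\qquad
R^2_c = \frac{\sigma^2_f + \sum_l \sigma^2_l}{\sigma^2_f + \sum_l
\sigma^2_l + \sigma^2_e}$$

(with $\sigma^2_f$ the variance of the fixed linear predictor over the
data) are extracted into a serializable `damage_model`.

### Model selection

`rank_models()` compares candidate fixed-effect sets by
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ with Akaike weights and a
tie flag at $\Delta\mathrm{AICc} < 2$. Two accounting choices were open
and are fixed here: (i) $k$ counts fixed effects + variance components +
the residual variance, the standard mixed-model accounting; (ii)
candidates are refitted by maximum likelihood for the comparison, because
REML likelihoods are not comparable across different fixed-effect sets —
`fit_lmm()` itself defaults to REML for estimation. Candidates with
$n \le k + 1$ are flagged invalid rather than silently dropped.
Collinearity is screened by $\mathrm{VIF}_j = 1/(1 - R^2_j)$; exact
collinearity is reported as `Inf` with a flag.

## Buffer features

`buffer_composition()` intersects a circular buffer with every field
polygon and sums intersection areas per category in km². Numerical
choices:

* The circle is a regular 256-gon (relative area error
  $\approx (2\pi/256)^2/6 < 10^{-4}$, below every stated tolerance).
* Clipping is Sutherland–Hodgman against a convex clipper, which is exact
  for any simple subject polygon; no geometry package in the target
  environment provides polygon intersection, so the primitive is
  implemented here and tested against an independent Monte-Carlo
  point-in-polygon oracle and an independent shoelace implementation.
* Fields wholly inside (or wholly outside) the buffer are detected by
  bounding-box distance and skipped past the clipper; this preserves the
  invariant that category areas sum to at most $\pi r^2$.

The field-margin model adds `max(0, 0.3978 · perimeter − 25.173)` m² of
grassy margin per agricultural field into the source-habitat total. The
linear fit goes negative below a perimeter of ~63.3 m, which is physically
meaningless, hence the clamp. How the original study treated fields only
partially inside the buffer is unstated; we prorate each field's margin by
the fraction of its area lying inside the buffer, the consistent continuum
choice (a field drifting out of the buffer contributes continuously less
margin). The same proration is used for hexagon cells.

## Evaluation

Grades follow the regulatory thresholds (first ≤ 0.1 %, second ≤ 0.3 %,
third ≤ 0.7 %, substandard above), inclusive on the better grade. The
positive class for confusion statistics and ROC analysis is *failing first
grade* (damage > 0.1 %), the event of economic concern to farmers; both
observed and back-transformed predicted values are binarized at that same
boundary (whether the original evaluation used this or an ROC-optimal
threshold is unstated; the fixed regulatory boundary is the interpretable
choice). Rates with empty denominators are flagged undefined, never
silently zero-filled. AUC is the Mann–Whitney concordance probability with
ties counted ½; the returned curve integrates to the same value by the
trapezoidal rule, and both are tested against exhaustive pairwise
concordance.

`obs_vs_pred()` refits observed on predicted with region and
year-within-region random intercepts and reports conditional R², RMSE and
a Wald chi-square for the slope. A perfectly linear relation makes that
mixed model degenerate (zero residual variance), so the closed-form limit
(conditional R² = 1) is returned instead of forcing REML onto a boundary.

Cross-validation defaults to region-holdout folds (`by_region`): the
published three-fold cross-validation tested accuracy "for unknown data"
within three regions, and holding out one region at a time is the
interpretation that actually confronts the model with unknown
region-years; stratified random folds are available as the alternative.
Held-out folds are scored with population-level predictions (random
intercepts contribute zero). The per-fold R² is the squared Pearson
correlation between observed and predicted arcsine damage — the exact
fold-level statistic of the original evaluation is unstated, and the
mixed-model conditional R² cannot be computed on a single held-out region.

## Hazard mapping

`hex_grid()` tiles the extent with flat-top regular hexagons of 300-m
sides — the largest hexagon fitting a 300-m-radius circle, so a cell
approximates the 600-m-diameter buffer the features were calibrated on.
The grid is anchored at the extent's lower-left corner (any rigid motion
is admissible; a fixed anchor keeps runs reproducible). Cell composition
uses raw within-cell areas without rescaling to the buffer area, matching
the direct assignment described for the published map. Cells without
agricultural area are dropped (`drop_empty = FALSE` keeps them, e.g. for
area-conservation audits). The priority rule — the published map selects
"priority areas" without stating the rule — is *predicted grade worse than
first* (back-transformed prediction > 0.1 %), configurable via the
threshold argument. `scenario_table()` evaluates the equation over the
published min/average/max source-habitat and soybean areas at the average
paddy area, for a low- and a high-risk random-intercept case.

## The synthetic world

The generator emulates the three study regions as a *stated world*, not a
tuning knob:

* Regions, years and sample sizes: Maesawa 2011–2013 with 47 points,
  Otomo 2018 and 2020 with 18, Semine 2016–2018 with 28 — 93 observations
  over 8 region-years. Points are assigned to years round-robin.
* Mean field areas 0.15 / 0.11 / 0.16 ha and landscape source-habitat
  shares 14.65 / 0.32 / 9.34 % follow the published region summaries; the
  remaining composition fractions (paddy-dominated inland plains for
  Maesawa and Semine, a forest-dominated coastal mosaic for Otomo) are
  fixed once from the published landscape descriptions.
* The mosaic is built by recursive binary splitting of the extent with
  stochastic stopping around the target mean area — gap-free, exact
  rectangle areas — rather than a Voronoi tessellation. Categories are
  assigned in spatial clumps by nearest-centroid growth around random seed
  parcels (pastures occur in clumps, and the buffer statistics are
  sensitive to that); this replaces adjacency-graph region growing with an
  order-of-magnitude simpler equivalent. The dominant category takes the
  remainder, so realized composition matches the target to within a
  single parcel per category.
* Research points sit 10 m inside a corner of distinct paddy parcels
  (toward the centroid), at a minimum pairwise spacing of 300 m — the
  buffer radius. The published inter-field distances (560–810 m) are
  *averages*, not minima; using them as hard minima would require ~100-km²
  extents. Default extents give random sequential placement ample slack
  (it saturates well below lattice packing when points are confined to
  clustered paddies).
* Damage is drawn from the extended equation as generating truth with
  region / year-in-region / residual standard deviations 0.3 / 0.5 / 0.6
  arcsine degrees (unpublished in the source; chosen once so the simulated
  between-year spread resembles the observed variation), truncated to
  [0, 90]. Truncation at zero rather than resampling matches the
  one-sided pile-up of real damage data at zero. Grain counts are
  simulated with totals uniform on 18,498–46,049; the stored percentage is
  the exact model value and the counts are its quantized shadow (an exact
  count-ratio percentage and an exact noise-free degenerate case are
  mutually incompatible; the count-ratio invariant applies when reading
  counts from CSV).

What the generator does **not** emulate: realistic shapes for forest and
water bodies, terrain, weather, insect phenology, or spatially correlated
residuals. A green test on this world therefore establishes that the
pipeline's *computations* are correct and that the statistical machinery
recovers a known truth of the assumed form — not that the fitted model
transfers to any real landscape.

### A known limitation the tests surface

The truncation of the generative response at zero censors ~15 % of
observations (concentrated in the low-predictor Otomo region) and biases
the REML slope for source habitat downward by a fraction of a standard
error. In the parameter-recovery experiment (200 replicates at n = 93) the
±2-SE coverage for the source coefficient consequently falls a few points
short of the nominal 90 %, while the soybean coverage and the AICc
identification of the true covariate set meet their targets. This is an
estimator-bias consequence of fitting a Gaussian mixed model to censored
data — the same thing the original study did with real zero-inflated
damage data — and is left visible rather than masked by softer noise
settings.

## Degenerate inputs and tie-breaks

* Composition fractions must sum to 1 (±1e-9); a single category at 1.0
  yields a uniform mosaic.
* Empty field sets give all-zero buffer compositions; an all-forest
  landscape gives an empty cell table.
* Grade boundaries are inclusive on the better grade (0.1 % is first).
* Equal AICc candidates share weights exactly; ΔAICc < 2 flags ties.
* Unknown random-intercept labels predict as zero (population level)
  unless `strict = TRUE`.
* Negative margin predictions clamp to zero; negative perimeters, radii,
  percentages outside [0, 100] and transformed values outside [0, 90] are
  errors, not warnings.
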