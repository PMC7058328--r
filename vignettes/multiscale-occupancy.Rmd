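---
title: "Multi-scale patch-landscape occupancy analysis with scaleocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale patch-landscape occupancy analysis with scaleocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleocc)
```

## The problem

Species that persist in remnant habitat patches respond to their
surroundings at characteristic spatial scales: the amount of habitat,
cropland or urban cover within 50 m of a patch may matter very differently
from the amount within 3 km. A patch-landscape occupancy study treats each
habitat patch as the unit of observation, surveys it repeatedly for a
species that is detected imperfectly, and asks which landscape,
geometry and habitat-quality variables — and at which buffer distance —
best explain where the species occurs.

`scaleocc` implements that whole workflow: covariate construction from
land-cover rasters and patch polygons, single-season occupancy modelling
with imperfect detection, per-variable scale-of-effect scans, collinearity
screening, single-scale and multi-scale all-subsets model selection with a
spatial-autocorrelation correction, parametric-bootstrap goodness of fit,
and confusion-matrix evaluation. A synthetic-landscape generator with
known parameters makes the full pipeline verifiable by parameter and scale
recovery.

## The occupancy model

Each patch $i$ has a latent occupancy state $z_i \sim
\mathrm{Bernoulli}(\psi_i)$ and, conditional on $z_i = 1$, each of $J$
surveys yields a detection $y_{ij} \sim \mathrm{Bernoulli}(p_{ij})$. Both
probabilities get logit-linear models,

$$\operatorname{logit}\psi_i = \mathbf{x}_i^\top\boldsymbol\beta, \qquad
  \operatorname{logit}p_{ij} = \mathbf{w}_{ij}^\top\boldsymbol\alpha,$$

and the marginal likelihood of site $i$ integrates the latent state out:
a site detected at least once contributes
$\psi_i \prod_j p_{ij}^{y_{ij}}(1-p_{ij})^{1-y_{ij}}$, while an all-zero
history contributes the mixture
$\psi_i \prod_j (1-p_{ij}) + (1-\psi_i)$.

`fit_occupancy()` maximizes this likelihood with BFGS using analytic
gradients of the exact marginal log-likelihood, from five deterministic
jittered starts (the best optimum is kept). We chose analytic over
numerical gradients deliberately: the gradient has a simple closed form,
it is exact at the clipping boundary, and it makes each fit roughly an
order of magnitude faster — which matters because the selection stage fits
thousands of models and the bootstrap refits hundreds more. The gradient
is verified against central finite differences in the unit tests, and the
likelihood itself against brute-force latent-state enumeration.

Numerical choices: probabilities are clipped to $[10^{-10}, 1-10^{-10}]$
before logs; a fit is flagged `converged` when the gradient norm at the
optimum falls below $10^{-6}$ and `boundary` when any coefficient exceeds
15 on the logit scale (separation); covariates are z-scored at fit time so
coefficients are comparable across variables, with the centring constants
stored for prediction in original units.

Model fit is summarized by AIC, AICc (with $n$ = number of sites, not
site-survey records), and the Nagelkerke $R_N^2$

$$R_N^2 = \frac{1 - \exp\{\tfrac{2}{n}(\ell_0 - \ell_1)\}}
               {1 - \exp\{\tfrac{2}{n}\ell_0\}},$$

where the null model $\ell_0$ is intercept-only in *both* $\psi$ and $p$ —
the only null nested in every candidate, since candidates vary both
submodels.

## Landscape covariates

Composition variables (`habitat`, `crop_pas`, `urban`) are proportions of
cells whose centres fall in the ring between the patch boundary and the
buffer distance, at the ten standard scales 50, 150, 250, 500, 750, 1000,
1500, 2000, 2500 and 3000 m. The focal patch itself is excluded from the
ring; other patches are not — the ring describes the patch's
surroundings, whatever they contain. Rings are clipped at the raster
edge, as in any bounded study region.

Configuration variables: `np_dist` is the edge-to-edge distance to the
nearest patch; the proximity index is

$$\mathrm{prox}(s) = \sum_{k:\, d_k \le s} A_k / d_k,$$

the sum over all patches falling at least partly in the buffer of area
over edge-to-edge distance. We follow this first-power form as the
definition of record; a `squared = TRUE` switch provides the FRAGSTATS
PROX convention $A_k/d_k^2$, since the two conventions circulate side by
side in the landscape-metrics literature. Touching patches ($d_k = 0$)
have their distance floored at one cell size so the index stays finite —
a conservative, resolution-scaled choice. `prox` is monotone
non-decreasing in scale by construction.

Geometry: area, perimeter, their ratio, and the square-normalized shape
index $P/(4\sqrt A)$, which is exactly 1 for a square and $\ge 1$ for any
cell-aligned (rectilinear) outline. Distances to the river line and to the
crop and urban classes are edge-to-edge (zero on contact).

Habitat quality: foliage height diversity is the Shannon entropy of the
nine vegetation-coverage classes of a 25 m² plot, in natural log (a
`base` argument gives log₂); all nine classes enter by default, with a
`mask` argument to exclude the non-foliage classes (rocks, bare soil)
should the analyst prefer a stricter reading — the choice is not settled
by convention. Plot FHD values are pooled by habitat type *across*
patches, and each patch's `veg_str` is the type-area-weighted mean, a
convex combination of the type means. Slope is Horn's 3×3 finite
difference on the DEM averaged over cells inside the patch; radiation is
accepted as a supplied covariate and passed through.

## Scale of effect and model selection

`scale_profile_scan()` fits one univariate $\psi$-model per scale, holding
detection at the full three-covariate structure (vegetation structure,
day of survey, patch area — fixed after `detection_model_scan()` ranks
the $2^3$ detection structures by AICc). The scale of effect is the scale
with the highest $R_N^2$; exact ties resolve to the smallest scale.

`collinearity_filter()` screens candidate variables per dataset: Spearman
$|r_s| > 0.60$ pairs lose their weaker member (lower univariate $R_N^2$ at
the variable's own scale of effect — "strongest effect" needed an
operational definition and this is ours), then variance-inflation factors
are pruned iteratively until all VIF < 10. Pairs the analyst flags as
ecologically important are exempt: both members survive, and
`build_model_sets()` builds one candidate set per combination of one
member per pair (two pairs → four sets). Because flagged members are
alternates that never co-occur in a model, only one member per pair
enters the VIF computation and neither can be VIF-dropped.

`assemble_global_model()` resolves the roster at a scale label: at a
single scale every composition variable carries that scale's suffix; in
the multi-scale model each carries its own scale of effect.
`all_subsets_selection()` then fits every $\psi$-subset crossed with every
detection subset ($2^{k_\psi} \times 2^{k_p}$ models, guarded at 50 000),
and retains candidates with $\Delta\mathrm{AIC} < 2$. AIC is the default
ranking criterion for this stage, with AICc available by flag; the
detection scan uses AICc. Detection submodels vary inside the subset scan
because the candidate tables report "different combinations of the three
variables explaining detection probability".

## Spatial autocorrelation

Residuals are conditional-occupancy residuals $z^*_i - \hat\psi_i$, where
$z^*_i$ is 1 for detected sites and the posterior probability
$\hat\psi q/(\hat\psi q + 1 - \hat\psi)$, $q = \prod_j(1-\hat p_{ij})$,
otherwise. An occupancy model has no single canonical residual; this one
is bounded, honours what was observed, and reduces to the naive residual
when detection is perfect.

`global_morans_i()` tests them with inverse-distance weights between patch
centroids and a two-sided permutation test (999 permutations, seeded).
When significant at $\alpha = 0.05$, `pcnm_autocovariate()` builds spatial
eigenvectors — principal coordinates of neighbour matrices, computed with
`vegan::pcnm` (truncation at the longest minimum-spanning-tree edge,
distances beyond it replaced by four times the truncation) — and the
single axis with the largest absolute Spearman correlation with the
residuals enters the global model as one fixed occupancy term, present in
every candidate of the subset scan. A single fixed autocovariate (rather
than forward selection over all axes) matches the workflow this package
reproduces; note that because the axis is *selected* to correlate with the
residuals, its coefficient should not be interpreted, only used as a
nuisance adjustment.

## Goodness of fit and evaluation

`gof_parametric_bootstrap()` computes the Pearson chi-square over the
$2^J$ history cohorts, with expected counts summed over sites from the
fitted model, and compares it with $B$ parametric-bootstrap replicates
(simulate from the fit, refit, recompute). It reports the bootstrap
p-value $\#\{\chi^2_b \ge \chi^2_{\mathrm{obs}}\}/B$ and the
overdispersion ratio $\hat c = \chi^2_{\mathrm{obs}} / \overline{\chi^2_b}$.
$\hat c$ is reported, not used to adjust the selection criterion. Be
aware that $\hat c$ is a heavy-tailed ratio: under a correctly specified
model its *expectation* is near 1, but single-run values scatter widely
and its median sits well below 1 — judge overdispersion from large values
sustained across models, not from one number.

Selected models are evaluated against naive occupancy (detected at least
once) using the unconditional $\hat\psi$: percent correctly classified and
Cohen's kappa at threshold 0.5, the rank-based (Mann-Whitney) AUC, and
the kappa-optimal threshold found by evaluating all 101 thresholds
$0, 0.01, \ldots, 1$, ties resolved to the smallest threshold. Naive
occupancy is the only observable ground truth; this choice makes the
indices conservative when detection is poor.

## The synthetic generator

`sim_config()` defaults define the reference scenario the test-suite
calibrations run under: a 3 × 3 km landscape at 5 m resolution, 40
disjoint patches (axis-aligned rectangles with random side bumps, so the
shape index varies) targeting 12% habitat cover, a meandering 1-cell
river, urban blocks covering ~20% of the matrix with cropland elsewhere,
a smooth sinusoidal DEM, two surveys per patch, and occupancy driven by
the habitat proportion at a true scale of 250 m plus distance to river
(logit-scale coefficients 1.5 and −1 on z-scored covariates), detection
by vegetation structure, day and area. Patch counts and the habitat
fraction mirror a two-region field design of 42 and 33 surveyed patches
in landscapes with 11–13% habitat; the extent is our own desk-scale
choice — patch count, not extent, is what drives the statistics. The
generator standardizes covariates before applying coefficients, so true
and fitted coefficients live on the same scale.

Patch polygons are traced from the rasterized cells, so vector and raster
representations agree exactly; identical configurations (including the
seed) reproduce every artifact bit for bit.

Two tabular simulators complement the raster generator where landscapes
would only add cost: `simulate_occupancy_data()` draws iid standard-normal
covariates for estimator calibration at large $n$, and
`simulate_scale_data()` emulates nested buffers by giving each annulus an
iid field value and forming area-weighted cumulative means — neighbouring
scales are correlated the way nested rings are, and occupancy responds to
the covariate at the true scale only. Scale-of-effect recovery checks use
it at $n = 200$; the raster pipeline is exercised end-to-end at 12–18
patches in the unit tests and 40 in the acceptance script.

What the synthetic data do *not* emulate: realistic vegetation
succession, classified-map error, spatially autocorrelated occupancy
beyond what covariates induce, unequal survey effort, or multi-type
patches (each generated patch is one habitat type). Passing recovery
tests therefore demonstrate the estimator and the scan logic, not
robustness to map error or residual spatial processes.

## Known limitations

- Two surveys per site is the design minimum; detection parameters are
  weakly identified at small $n$ and boundary fits (flagged) occur.
- No missing-survey handling, no multi-season dynamics, no abundance
  models.
- Model averaging and QAIC adjustment are out of scope; $\hat c$ is
  reported only.
- Geometry is planar; inputs must already be in a projected CRS in
  metres.
- With $J = 2$ the goodness-of-fit chi-square has few cohorts; its power
  against subtle misfit is limited.

## A worked run

```{r, eval = FALSE}
cfg <- region_config(
  sim = sim_config(seed = 7),
  run_scales = list(250, 1000, "ms")
)
run <- run_region_analysis(cfg, seed = 7)
run$scale_of_effect
run$selected
autoplot(run$profiles$habitat)
autoplot(run$region$landscape)
```

Each stage is also exposed on its own (`patch_metrics()`,
`detection_model_scan()`, `scale_profile_scan()`, `collinearity_filter()`,
`all_subsets_selection()`, `spatial_autocorrelation_check()`,
`gof_parametric_bootstrap()`, `evaluate_model()`), all taking and
returning tibbles so runs compose with the usual dplyr verbs.
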