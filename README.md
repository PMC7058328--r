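# scaleocc

Multi-scale patch-landscape occupancy analysis for species with imperfect
detection.

Ecologists studying species in fragmented landscapes — remnant grassland,
shrubland or woodland patches in a crop/urban matrix — need to know which
properties of a patch and its surroundings determine whether the species
occupies it, and at which spatial scale those surroundings act. `scaleocc`
implements that analysis end to end for a patch-landscape survey design
(each patch surveyed a few times, detection imperfect):

- **Covariates** from a land-cover raster and patch polygons: buffer
  composition (proportions of habitat, crops/pastures, urban) at ten
  scales from 50 m to 3 km, the proximity index
  `prox(s) = Σ A_k / d_k` over patches within the buffer, edge-to-edge
  nearest-patch distance, distances to river/crop/urban, patch geometry
  (area, perimeter, `P/A`, shape index `P/(4√A)`), foliage height
  diversity (Shannon entropy of 9 vegetation-coverage classes) aggregated
  to a patch vegetation-structure score, and Horn-method DEM slope.
- **Occupancy model**: single-season likelihood with logit links,
  `z_i ~ Bern(ψ_i)`, `y_ij | z_i ~ Bern(z_i p_ij)`, maximized by BFGS
  with analytic gradients from multiple starts; AIC/AICc, Nagelkerke R²,
  Wald intervals, broom-style `tidy()`/`glance()`.
- **Scale of effect**: per-variable univariate R² profiles across scales
  (`scale_profile_scan()`, `autoplot()`).
- **Selection**: Spearman (|r_s| > 0.60) and VIF (< 10) screening,
  alternative model sets for ecologically important correlated pairs,
  single-scale and multi-scale global models, all-subsets fits with
  ΔAIC < 2 retention.
- **Diagnostics**: Moran's I permutation test on conditional-occupancy
  residuals with a PCNM autocovariate correction; MacKenzie–Bailey-style
  parametric-bootstrap goodness of fit with the overdispersion ratio
  c-hat.
- **Evaluation**: PCC, rank-based AUC, Cohen's kappa at 0.5 and at the
  optimum over the 101-point threshold grid; prediction curves.
- **Synthetic data**: a seeded landscape/covariate/detection generator
  with known truth, so the whole pipeline is testable by parameter and
  scale recovery.

Everything takes and returns tibbles and composes with the pipe; results
have `autoplot()` methods.

## Worked example

Fit the constant occupancy/detection model to a two-survey detection
summary of 42 patches — 17 detected in both surveys, 7 in one, 18 in
none:

```r
library(scaleocc)
hist42 <- tibble::tibble(
  patch_id = 1:42,
  y_1 = c(rep(1, 17), rep(1, 7), rep(0, 18)),
  y_2 = c(rep(1, 17), rep(0, 7), rep(0, 18))
)
fit_occupancy(hist42)
#> Single-season occupancy model fit
#>   sites: 42  params: 2  logLik: -48.021  AIC: 100.04  AICc: 100.35
#>   Nagelkerke R2: 0.000
#>   psi: (Intercept)=0.358
#>   p:   (Intercept)=1.580
```

`plogis(0.358) = 0.589` and `plogis(1.580) = 0.829`: an estimated 58.9%
of patches are occupied and the species is detected on 82.9% of surveys
of an occupied patch. The naive occupancy 24/42 = 0.571 is lower because
two surveys at p = 0.83 still miss an occupied patch about 3% of the
time.

Find a variable's scale of effect on simulated data whose true scale is
250 m:

```r
sim <- simulate_scale_data(200, true_scale = 250, beta1 = 1.5, seed = 42)
prof <- scale_profile_scan(sim$data, "habitat")
as.data.frame(prof[, c("scale", "rn2", "sign")])
#>    scale    rn2 sign
#> 1     50 0.0965    +
#> 2    150 0.1848    +
#> 3    250 0.3247    +
#> 4    500 0.0879    +
#> ...
scale_of_effect(prof)
#> [1] 250
```

The R² profile peaks at the generating scale. The full regional workflow
— synthetic landscape, detection scan, profiles, collinearity screening,
model sets, spatial check, goodness of fit, all-subsets selection,
evaluation — runs with:

```r
run <- run_region_analysis(region_config(sim = sim_config(seed = 7)), seed = 7)
run$scale_of_effect
run$selected        # ranked selected models with PCC/AUC/kappa columns
```

`write_region_run(run, "out/")` writes all stage artifacts (ESRI ASCII
rasters, GeoJSON patches, CSV tables, a JSON summary). A thin CLI over
the same function lives at `inst/scripts/scaleocc.R`.

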