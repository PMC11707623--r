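# udlevels

Multilevel spatial habitat-use analysis for animal telemetry.

Many animals are episodically gregarious: they aggregate communally for part
of the year (e.g. temperate snakes overwintering and basking at shared
hibernacula) and disperse to solitary activity ranges for the rest. The
habitat where the *population* concentrates can then differ sharply — even
oppositely — from the habitat where *individuals* concentrate, and a
single-level habitat model misses the contrast. `udlevels` is for movement
ecologists with radio-telemetry relocations and per-observation habitat
measurements who want to quantify habitat use at both levels and test
whether covariate effects differ between them.

## What it computes

For relocations with planar coordinates (m) and five percent-cover habitat
covariates (canopy, coarse woody debris, ground-layer vegetation, rock,
woody understory vegetation):

1. **Home ranges** — 95% minimum convex polygons per animal-season (peeling
   the points farthest from the centroid), a ≥ 20-relocation season filter,
   and a subsampling area curve supporting that threshold.
2. **Utilization distributions** — kernel densities whose bandwidth *h* is
   tuned in 1-m increments until the 95% volume contour of the UD first
   reaches the 95% MCP area: one UD per season, and a population UD averaged
   over 1000 resampling iterations that each pool one random season per
   animal.
3. **Core labels** — each relocation is scored core/noncore at both levels
   by membership in the 30% volume contour of the season UD and of the
   population UD.
4. **Resource-utilization models** — logistic regression of core membership
   on z-scored covariates: pooled at the individual level, with a random
   intercept per season (lme4) at the population level; all 2⁵ covariate
   subsets fitted, full model averages over the ΔAIC < 2 set with
   unconditional SEs (β̄ⱼ = Σₘ wₘ βₘⱼ, SEⱼ = Σₘ wₘ √(SEₘⱼ² + (βₘⱼ − β̄ⱼ)²)),
   and a per-covariate cross-level Wald test
   W = (β̄_ind − β̄_pop)² / (SE_ind² + SE_pop²) ~ χ²₁.
5. **Reproductive-class comparison** — multinomial logistic models of core
   habitat by class (gravid-female reference) and by level, pairwise
   estimated-marginal-mean contrasts at the covariate means, Bartlett's
   sphericity test, correlation-matrix PCA with the |0.5| loading rule, and
   seeded bootstrap summaries (1000 iterations).
6. **Diagnostics** — empirical semivariograms of every covariate at the
   relocations.

A seeded synthetic-data module (`sim_config()`, `generate_landscape()`,
`simulate_telemetry()`, `planted_truth()`) generates Gaussian-random-field
covariate landscapes and episodically gregarious telemetry with *known*
level-dependent effects, so the whole pipeline can be validated against
planted ground truth.

## Worked example

```r
library(udlevels)

cfg  <- sim_config(seed = 11)            # 16 animals, 27 seasons, ~870 relocations
land <- generate_landscape(cfg)
tel  <- simulate_telemetry(cfg, land)
res  <- run_pipeline(tel, run_config(seed = 11, pop_ud_iterations = 100))
print(res)
```

```
Multilevel habitat-use pipeline result
   16 animals, 27 seasons, 892 relocations
  population UD bandwidth (median): 31 m
  core fraction (individual): 0.564  (population): 0.377 

Level contrast (model-averaged coefficients):
   covariate beta_ind beta_pop        W        p
1     canopy -0.28677  1.76055  25.9580 3.49e-07
2        cwd  0.00644 -0.00445   0.0502 8.23e-01
3 ground_veg  0.37578 -2.45484  77.7155 1.19e-18
4       rock -0.63968  3.50268 147.9386 4.89e-34
5  woody_veg -0.03971  0.00398   0.3387 5.61e-01
```

Reading the table: canopy cover has a *negative* model-averaged effect on
the odds that a relocation falls in an individual core area but a *positive*
effect at the population level, and the Wald test flags the difference —
exactly the planted structure (individuals summer in open vegetated patches;
the population aggregates on a forested rocky slope). `ground_veg` shows the
mirror-image contrast, while `cwd` and `woody_veg` were planted with no
level-dependent role and are not flagged. `run_pipeline()` also returns the
UDs, core labels, class and level multinomial fits with pairwise contrasts,
PCA, bootstrap summaries, and semivariograms; `write_raster()`,
`write_region()` and `write_telemetry()` export the artifacts (ESRI ASCII,
GeoJSON, CSV). A thin command-line wrapper lives at `inst/cli/udlevels.R`.

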