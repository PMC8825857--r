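# arclakes

Shallow Arctic tundra lakes sit at the crossing point of several
climate-sensitive drivers: seasonal snow cover sets the terrestrial growing
season, vegetation attracts migratory Barnacle geese whose droppings are the
dominant organic nitrogen input, and lake-to-catchment geometry governs how
much terrestrial carbon reaches the sediment. Those nutrient inputs
propagate into the aquatic food web, reshaping the diet, trophic position
and food-chain length of the top consumer, the notostracan *Lepidurus
arcticus*. `arclakes` implements the full analysis chain for an 18-lake
study system of this kind - from rasters to food-web inference - together
with a seeded synthetic-study generator with known ground truth, so every
stage is testable without field data or satellite downloads.

The package is aimed at ecologists and methodologists who want a
transparent, dependency-light reference implementation of this pipeline, or
a sandbox in which to check how reliably such a design recovers known
effects.

## What is computed

**Terrain.** Depression filling (least-upper-bound fill), D8 flow
directions and accumulation, catchment delineation, and the
lake-to-catchment area ratio L/C (the lower the ratio, the more "open" the
lake to terrestrial runoff).

**Remote sensing.** NDVI = (NIR − Red)/(NIR + Red),
NDSI = (Green − SWIR)/(Green + SWIR), snow classification by a two-node
decision tree (NDSI ≥ 0.40 and Red ≥ 0.20), the catchment snow-cover
fraction FSC, and NDVI summaries (catchment mean over June–August, 100-m
near-lake buffer, ΔNDVI = near-lake − catchment in August, June-to-August
change).

**Isotope food-web metrics.** δ-notation
(δX = (R_s − R_std)/R_std × 10³), AFDM%, C:N, goose-dropping transect
scores, δ15N baselines from aquatic vegetation, and trophic position

    TP = (δ15N_consumer − δ15N_baseline) / TEF + 1,   TEF = 2.3 ± 0.5 ‰,

so a consumer one enrichment step above primary producers sits at TP = 2.
The top consumer's TP is each lake's food-chain length.

**Diet mixing.** A Bayesian stable-isotope mixing model: consumer
observations are Normal with mean Σ p_k(μ_k + λ) and variance
Σ p_k²(σ_k² + τ²) per isotope ((λ, τ) = TEF mean and SD), Dirichlet(1)
prior on the diet proportions p, sampled by Metropolis on
additive-log-ratio coordinates with a mode-jumping prior-independence
component, split-Rhat convergence monitoring, and a trophic-link count
(sources with posterior median ≥ 0.05).

**Inference.** Permutation-tested OLS (9999 permutations, two-sided,
add-one rule) with 95% percentile bootstrap CIs (1999 resamples) and the
dual significance criterion (permutation p < 0.05 AND CI excluding zero);
Gaussian AIC selection and a VIF collinearity screen; one-way PERMANOVA on
(δ13C, δ15N); Mantel tests; Type-II two-way ANOVA; Welch/paired t tests;
uncorrected 2×2 chi-square.

**Synthetic study.** `generate_study()` plants the study's causal diagram
(snow–distance, NDVI–snow, geese–NDVI, goose-driven δ15N enrichment,
openness-driven sediment δ13C, quality-driven consumer diets) over the
published per-lake template (distances, L/C ratios, categories) with
configurable effect sizes and noise, and returns the ground truth next to
the data.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 1 simulates
the study, stages 2–5 consume the written files:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_terrain_and_indices.R
Rscript analysis/03_foodweb_metrics.R
Rscript analysis/04_diet_mixing.R
Rscript analysis/05_hypothesis_battery.R
```

With the default seed this prints, among other things:

```
L/C ratios: 0.01 - 0.27 | June FSC: 0 - 0.88
Spring FSC >= 0.9 everywhere: TRUE
Top consumer present in 9 lakes; TP range 1.92 - 2.79 ; maximum food chain length 2.79
Trophic links per lake: 2 - 3
PERMANOVA sediment between lakes: F = 20.6, p = 0.0001
Consumer x benthic vegetation: chi2 = 9.0, p = 0.0027
Significant regressions (dual criterion): 15 of 17
                        name   slope r_squared permutation_p
             fsc_vs_distance   0.416      0.92        0.0001
                 ndvi_vs_fsc  -0.476      0.95        0.0001
           droppings_vs_ndvi   6.635      0.91        0.0001
        sed_d13c_vs_lc_ratio  12.937      0.82        0.0001
           sed_diet_vs_sed_c  -0.071      0.91        0.0006
```

Reading: delineated L/C ratios reproduce the published range; June snow
cover rises with distance from the coast (slope 0.45 per km planted, 0.42
recovered); summer NDVI falls with snow; goose droppings track NDVI;
sediment δ13C is enriched in closed lakes (high L/C, little terrestrial
carbon); and the consumer's sediment diet share falls as sediment C%
rises (carbon excess = poorer quality), with every recovered sign matching
the planted causal diagram. The chi-square of consumer occurrence against
benthic vegetation reproduces the printed 9.0 exactly.

Single computations work directly:

```r
library(arclakes)
trophic_position(5.3, 3.0, 2.3)$lake_tp   # 2: one TEF above the baseline
ndvi(matrix(0.5), matrix(0.1))            # 0.667
openness_ratio(0.002, 0.010)              # 0.2, the smallest study lake
```

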