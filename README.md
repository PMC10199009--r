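# travelCAR

Area-level associations between travel behaviour and health outcomes, with
Bayesian conditional autoregressive (CAR) spatial regression.

Ecological studies that link household travel surveys to small-area health
estimates need a chain of non-trivial steps: classifying each travel-diary
person-day by the duration of walking/cycling and car use, aggregating
participants into area profiles (category shares, travel-mode diversity,
covariates), building a border-contiguity structure, and fitting spatial
regressions that respect autocorrelation between neighbouring areas.
travelCAR implements the whole chain for R, along with a synthetic
travel-survey generator with known ground truth so every stage can be
validated offline — the survey microdata such analyses use are typically
access-restricted.

## The model

The core estimator is a Gaussian identity-link regression with spatially
structured random effects,

y_i = x_i' β + φ_i + ε_i,  ε_i ~ N(0, ν²),

where φ carries the proper Leroux CAR prior with precision
(ρ (D − W) + (1 − ρ) I) / τ², W the binary matrix of shared borders, D its
degree matrix, and ρ ∈ [0, 1] the spatial dependence. A purpose-built
Gibbs/Metropolis sampler (C++ core, R's RNG, bit-reproducible under a seed)
estimates β, φ, ν², τ² and ρ; posterior medians and 95% credible intervals
are reported per 5-percentage-point increment of each travel metric, with
significance read off zero-exclusion and convergence checked by the Geweke
diagnostic.

Exposure metrics follow the standard duration-based classification — low
active travel (1–29 min/d walking/cycling, no car), high active travel
(30+ min/d, no car), mixed travel (both), sedentary travel (car without
walking/cycling; prolonged ST at 60+ min/d) — plus the normalised
Shannon-entropy diversity of mode groups,

D = −Σ p_k ln p_k / ln N (N = 3),

over walking/cycling-only, car users and public-transport users. The model
battery mirrors common practice: unadjusted (M1) and covariate-adjusted
(M2) models per metric, and a compositional **substitution model** (M3) in
which low AT, high AT, MT and no-travel shares enter simultaneously with ST
omitted, so each coefficient estimates the effect of statistically
replacing sedentary travel with that category.

## Worked example

An end-to-end simulated study at realistic scale — an 18×18 grid of areas
(324 areas, ~150 diary participants each), the default behaviour profile,
and an outcome generated with a high-AT effect of −0.134 %-points per
1-point share (−0.67 per 5 points), ρ = 0.5, τ² = 2, ν² = 1:

```r
library(travelCAR)
report <- run_full_study(list(seed = 1,
  simulate = list(rows = 18, cols = 18),
  mcmc = list(n_iter = 5000, burn_in = 1000, thin = 4)))
print(report)
```

```
Simulated area-level travel/obesity study
47677 participants in 324 areas (324 included, 0 excluded by the min-30 rule)
Outcome: mean 61.4% (ground truth intercept 62.0, rho 0.50)

Models fitted: M1.pct_low_at, M1.pct_high_at, M1.pct_mt, M1.pct_st, M1.pct_pst,
M1.pct_no_travel, M2.pct_low_at, M2.pct_high_at, M2.pct_mt, M2.pct_st,
M2.pct_pst, M2.pct_no_travel, M3, DIVERSITY_M1, DIVERSITY_M2

Substitution model (replacing sedentary travel, per 5 percentage points):
     parameter increment median  lower upper significant geweke_z
    pct_low_at         5 -0.195 -0.775 0.378       FALSE   -0.580
   pct_high_at         5 -0.322 -0.751 0.106       FALSE    0.256
        pct_mt         5 -0.152 -0.451 0.178       FALSE    2.227
 pct_no_travel         5 -0.047 -0.279 0.195       FALSE   -0.702
        pct_st        NA     NA     NA    NA          NA (substitution target)
```

Each substitution row is the estimated change in the area outcome rate (%)
when a 5-point share of sedentary travel is replaced by that category; the
high-AT contrast comes out negative — replacing car-only travel with 30+
min/d of walking/cycling is associated with a lower outcome rate — though
with a single simulated outcome draw at this noise level its credible
interval still spans zero. The ST row carries no numbers because it is the
omitted substitution target. The suite's calibration tests show the
machinery behind these numbers is sound: ~95% interval coverage of true
coefficients and a ~5% false-positive rate under a null effect over 200
simulated replicates, and agreement with the conjugate closed-form
posterior when spatial variance is negligible.

The pieces are usable on their own — and on real extracts in the same
schema:

```r
cl   <- classify_travel(trips, persons)        # person-day categories
prof <- aggregate_areas(cl, outcomes, irsd)    # area profiles
keep <- filter_areas(prof, min_n = 30)$included
W    <- adjacency_from_edges(keep$area_id, edges)
fit  <- fit_car_leroux(outcome_rate ~ pct_high_at + irsd, keep, W,
                       mcmc_config(seed = 1))
summarise_posterior(fit, increment_pct = 5)
```

## Package layout

- `R/classification.R` — person-day summaries, duration categories, mode groups
- `R/aggregation.R` — area profiles, entropy diversity, filters, correlations
- `R/spatial.R` — adjacency construction and connectivity checks
- `R/car-fit.R`, `src/car_sampler.cpp` — the Leroux CAR sampler
- `R/car-methods.R`, `R/geweke.R` — posterior summaries and diagnostics
- `R/pipeline.R` — the model battery and the end-to-end study runner
- `R/synthetic-data.R` — the ground-truth survey generator
- `vignettes/travel-behaviour-car-methods.Rmd` — models, assumptions, design choices
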