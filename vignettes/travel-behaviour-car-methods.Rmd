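---
title: "Methods: area-level travel behaviour metrics and CAR spatial regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: area-level travel behaviour metrics and CAR spatial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(travelCAR)
```

## The scientific problem

Transport policy is made for areas, not individuals, so ecological evidence
on how an area's travel-behaviour profile relates to its obesity burden
complements the individual-level literature. travelCAR implements the full
analysis pipeline for such studies: travel-diary person-days are classified
by what people did and for how long, participants are aggregated into
small-area profiles, and the association between those profiles and an
area-level health outcome (here, the age-standardised rate of high waist
circumference, in %) is estimated with Bayesian conditional autoregressive
(CAR) regressions that account for spatial autocorrelation between
bordering areas.

Because the microdata such studies use are typically access-restricted, the
package ships a synthetic survey generator with known ground-truth
parameters. Every stage — classification, aggregation, adjacency, model
fitting — can therefore be validated end-to-end with parameter-recovery and
calibration experiments.

## Person-day classification

Each participant's survey-day trip legs are totalled into walking/cycling
minutes and car minutes (driving, riding as a passenger, taxi). Motorcycle
and commercial-vehicle legs count toward having travelled but toward
neither total; public-transport legs (bus, train, tram, ferry) set a use
flag but contribute no minutes, since in-vehicle posture — and hence the
health implication — is ambiguous.

The duration-based categories cross the two totals:

| walking/cycling | car 0 min/d | car 1+ min/d |
|---|---|---|
| 0 min/d | no travel | sedentary travel (ST) |
| 1–29 min/d | low active travel (AT) | mixed travel (MT) |
| 30+ min/d | high AT | MT |

Prolonged sedentary travel (PST) is the ST sub-category with 60 or more
car minutes. The 30 min/d boundary is inclusive for high AT ("30+"), and
the PST boundary is inclusive at exactly 60 minutes. Durations may be
fractional; we read the "1–29" row as *any positive duration under 30
minutes*, so that the five categories partition all person-days — the
tests enforce that partition property directly.

Two cases the category table does not define get documented conventions:
a person whose only legs are public transport has zero minutes in both
totals and falls in the no-travel cell of the duration scheme (while being
a public-transport user in the mode scheme); a person travelling only by
motorcycle/commercial vehicle is likewise placed in no-travel for
durations, and excluded from the three mode groups (counted and warned
about as `OTHER`).

The mode-based grouping is hierarchical: any public-transport use makes a
`PT_USER` (this is the park-and-ride rule: car plus train is still a
public-transport user), otherwise any car use makes a `CAR_USER` (some
walking/cycling allowed), otherwise positive walking/cycling makes a
`WALK_CYCLE_ONLY` traveller.

## Area profiles and travel-mode diversity

Area profiles report each duration category as a percentage of all
participants in the area, covariate percentages (men, adults 65+, workers,
households with children, low-income households) over the same
denominator, and the mode-mix diversity over travellers:

$$D = -\frac{\sum_{k=1}^{N} p_k \ln p_k}{\ln N}, \qquad N = 3,$$

with $p_k$ the share of mode group $k$ among the area's travellers and the
convention $0 \ln 0 = 0$. $D$ is 0 when one mode dominates entirely and 1
when the three groups are equally represented. The natural logarithm is
used throughout. Whether covariate shares should be computed over all
participants or travellers only is not a settled convention; we use all
participants, matching the denominators of the duration categories.

Two minimum-sample rules apply, both with the conventional threshold of 30
participants: areas with fewer than 30 participants are excluded outright,
and within included areas the diversity score is set to missing when fewer
than 30 participants travelled, so diversity models run on the smaller set
of areas with a reliable mode-mix estimate while duration-category models
keep the full set.

Sub-area deprivation scores aggregate to the area by population weighting
(`weighted_irsd()`), and `correlation_table()` reports pairwise-complete
Pearson correlations between all metrics and the outcome.

## The spatial model

The fitting function `fit_car_leroux()` estimates the Gaussian
identity-link model

$$y_i = x_i^\top \beta + \phi_i + \varepsilon_i, \qquad
\varepsilon_i \sim N(0, \nu^2),$$

where the spatial random effects $\phi$ carry the proper Leroux CAR prior
with precision matrix

$$\frac{1}{\tau^2}\,Q(\rho) = \frac{1}{\tau^2}\big(\rho (D - W) +
(1 - \rho) I\big),$$

$W$ the binary border-contiguity matrix, $D$ its diagonal degree matrix,
$\rho \in [0, 1]$ interpolating between independent effects and the
intrinsic autoregression. This proper, single-parameter family is the
default behaviour of the established areal-modelling software this kind of
analysis uses; the synthetic outcome generator draws from exactly the same
family so that recovery experiments are well posed. Islands (areas with no
neighbours) are retained: for $\rho < 1$ their conditional prior is the
exchangeable $(1-\rho)/\tau^2$ component, so the precision stays proper
rather than the area being silently dropped.

### Sampler

The MCMC scheme is Gibbs with one Metropolis step, implemented in C++ and
driven by R's RNG so a seed reproduces chains bit-exactly:

* $\beta$ — conjugate multivariate Gaussian update under independent
  $N(0, 10^5)$ priors per coefficient;
* $\phi$ — single-site conjugate Gaussian updates using the Leroux full
  conditionals, re-centred to mean zero after every sweep for
  identifiability with the intercept;
* $\nu^2, \tau^2$ — conjugate inverse-gamma updates under IG(1, 0.01)
  priors;
* $\rho$ — random-walk Metropolis with a Uniform(0, 1) prior, proposals
  reflected at the boundaries, and the step size adapted every 100
  burn-in iterations toward 30–50% acceptance (fixed after burn-in). The
  determinant term $\log|Q(\rho)|$ is evaluated from the precomputed
  eigenvalues of $D - W$.

All hyperparameters are overridable through `car_priors()`. The default
schedule (`mcmc_config()`) is 100,000 iterations, 10,000 burn-in, thinning
by 100 — retaining exactly 900 draws; scaled-down schedules are used
throughout the tests and examples, with retained-draw counts always equal
to `floor((n_iter - burn_in) / thin)`.

### Summaries and diagnostics

`summarise_posterior()` reports the posterior median and the 2.5th/97.5th
percentile credible interval per parameter; an effect is flagged
significant when the interval excludes zero (no multiplicity adjustment —
none is conventional for this design). Because predictors are percentages,
coefficient draws are multiplied by a 5-point increment by default, so an
entry reads "change in the outcome rate per 5-percentage-point increase of
the metric". The scaling is applied at summary time, which is
mathematically identical to rescaling the design matrix and keeps the
design interpretable.

Convergence is checked with the Geweke diagnostic: a z-test comparing the
mean of the first 10% of a chain against the last 50% (the diagnostic's
conventional windows), with window-mean variances estimated from the
spectral density at zero via an AIC-selected AR fit. Constant chains make
the statistic undefined and are reported as `NA` with a warning.

## The model battery and the substitution model

`run_model()` fits the standard battery over included area profiles:

* **M1** — outcome on one travel metric, unadjusted;
* **M2** — M1 plus the six covariates (men, 65+, workers, households with
  children, low income, deprivation index);
* **M3** — the *substitution model*: low AT, high AT, MT and no-travel
  percentages entered simultaneously, ST omitted, plus covariates. Because
  the five category shares always total 100%, holding the other three
  constant means a coefficient is interpretable as the effect of
  statistically replacing ST with that category, unit for unit. PST never
  enters M3, being a sub-category of ST;
* **DIVERSITY_M1 / M2** — the entropy score, unadjusted and adjusted.

Diversity models drop areas with missing diversity and rebuild the
adjacency matrix on the retained subset — subsetting rows of $W$ without
rebuilding would leave a precision matrix referencing absent areas. The
substitution parameterisation is checked by a re-parameterisation test:
refitting with a different omitted category and re-deriving the
ST-replacement contrasts reproduces the original contrasts up to
Monte-Carlo error.

`run_full_study()` chains every stage on a synthetic survey from one
config (R list, YAML or JSON): geography, diaries, classification,
aggregation, filtering, outcomes from the configured ground truth, the
battery, the correlation and substitution tables. Per-stage seeds are
derived by fixed offsets from the config seed, so a config reproduces its
report bit-exactly.

## What the generator emulates — and what it does not

The generator's defaults describe an Australian metropolitan setting:
a few hundred contiguous areas (grid with rook contiguity), on the order
of 100–200 diary participants per area, duration-category probabilities
(no travel 20.8%, low AT 2.6%, high AT 5.5%, MT 11.9%, ST 59.2%) matching
published area means, and an outcome centred at 62% with spatially
autocorrelated noise. Durations are truncated log-normal within each
category's bounds — positive, right-skewed, and bound-respecting, with
medians (low AT ≈ 12, high AT ≈ 55, MT walk ≈ 28, MT/ST car ≈ 55–60
min/d) placed so that mean durations and the PST share of ST (roughly
half) sit near reported values. Per-category public-transport
probabilities (45%/40% for low/high AT, 4% elsewhere) were chosen once so
the implied mode-group split among travellers lands near the published
5% / 86% / 9% walking-cycling / car / public-transport shares.

Public-transport legs are attached without extra access-walking legs for
car and no-travel categories (their walk minutes must stay zero); for AT
and MT categories the drawn walking minutes already play that role. This
keeps the defining round-trip property exact: re-classifying generated
diaries recovers every person's generating category.

Deliberate simplifications: areas are exchangeable (no urban gradient in
behaviour or demographics), attributes are independent of travel category,
the outcome is generated directly at area level from the linear predictor
(no individual waist circumference, no age-standardisation step — the
outcome is consumed as a given area rate), and the contiguity graph is a
regular grid. Passing tests therefore demonstrate the *statistical
machinery* — classification logic, estimator calibration, interval
coverage — not that real surveys meet the model's assumptions.

## Numerical choices and edge cases

* Entropy uses natural logs; all-zero traveller counts give a missing
  score rather than an error.
* Category bounds are closed at 30 (high AT) and 60 (PST) minutes.
* `rho = 1` makes $Q$ singular (intrinsic CAR); the generator reports the
  singularity instead of silently regularising. The sampler never proposes
  the boundary with positive density, and the log-determinant guard
  rejects it.
* Duplicate adjacency edges are collapsed with a warning; self-loops and
  unknown area ids are errors.
* Zero-variance columns in the correlation table yield `NA` with a
  warning rather than a crash.
* Problem sizes in the tests: calibration uses a 10×10 grid with 200
  replicates at 2,200 iterations per chain; oracle-equivalence uses 50
  areas at 6,000 iterations; the end-to-end demo uses a 12×12 grid with
  15 models at 3,000 iterations. These sizes give Monte-Carlo error well
  inside the asserted tolerances while keeping the suite quick to run.

## Known limitations

* Gaussian likelihood only — no binomial/Poisson CAR variants, no
  multivariate or spatio-temporal extensions.
* The Leroux form is the only CAR prior; analyses that used intrinsic or
  BYM priors will differ, particularly in $\tau^2$'s interpretation.
* One survey day per person; no trip purposes, origin–destination
  structure, or survey weights.
* Adjacency must be supplied or grid-derived; there is no polygon/GIS
  border detection.
* Exact numerical agreement with analyses run in other CAR software is
  not expected: priors, update order and RNGs differ even for the same
  model family.
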