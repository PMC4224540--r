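# growmort

Size-standardized growth–mortality trade-off analysis for longitudinal
seedling censuses.

## The problem

Enrichment-planting and forest-regeneration studies follow tagged seedlings
of many species for years, recording basal diameter, survival and canopy
openness at a handful of irregular census dates. Two classic questions are
whether species differ intrinsically in growth and mortality (rather than
merely responding differently to light), and whether fast growers pay for
speed with higher mortality — the growth–mortality trade-off that structures
shade-tolerant tree communities. Naive comparisons founder on two artifacts:
relative growth rate declines with size, so species measured at different
sizes are not comparable; and deaths are observed only between unevenly
spaced censuses, so raw interval death fractions are not comparable either.

`growmort` implements an analysis pipeline that removes both artifacts:

* **Growth.** Diameter follows a power-law ODE, `dM/dt = α M^β`, whose
  closed-form trajectory is fitted to each individual's diameter series by
  nonlinear mixed-effects (`nlme`): species intercepts and a common
  log-canopy-openness slope on log α, common β and M₀, individual random
  effects on all three parameters, and per-species residual variances.
  Species are compared by the **size-specific relative growth rate**
  `SGR = α Mc^(β−1)` at a common reference size Mc (annualized; Mc = 10 mm
  by default). With a shared β the species ranking is the same at every Mc.
* **Mortality.** Census records become interval-censored death records and
  are fitted with a binomial GLMM with complementary log-log link, an
  offset of log interval length in years (`lme4`), species, openness and
  initial-diameter fixed effects, and random intercepts for individual and
  census occasion — so intercepts are annual hazards and probabilities
  compose exactly across unequal gaps.
* **Trade-off.** Species trait means (wood density, SLA, seed mass, leaf
  C:N) are estimated by random-intercept models across experiments, related
  to SGR and annual mortality through a Pearson correlation matrix, and the
  growth–mortality relationship is summarized by standardized major axis
  (SMA) regression: slope = sign(r)·sd(y)/sd(x) through the centroid.
* **Validation.** A synthetic census generator (`simulate_population()`)
  draws populations with known truth — including the latent
  growth–mortality coupling and a wood-density axis — so every estimator is
  validated by parameter recovery.

## Worked example

Simulate a 15-species planting (40 individuals per species, seven censuses
over ~9.7 years), fit both models and summarize the trade-off:

```r
library(growmort)

sim    <- simulate_population(sim_config(n_individuals = 40, seed = 2024))
growth <- fit_growth(sim$census, method = "ML")
growth
#> Power-law growth NLME fit (ML)
#>   beta = 0.861 [0.853, 0.869], M0 = 4.13 mm
#>   log-openness slope on log(alpha) = 0.099
#>   alpha range: 0.000322 - 0.000792 mm mm^-1 day^-1 over 15 species
#>   pseudo-R2 = 1.000, BIC = 6957.9, n = 2934 obs / 522 individuals

mort <- fit_mortality(build_intervals(sim$census))
mort
#> Interval-censored cloglog mortality GLMM
#>   light slope = -0.071 per % openness, size slope = -0.025 per mm
#>   random-intercept variances: individual 0.000, census 0.108
#>   333 deaths over 2803 intervals, BIC = 1766.7

demog <- species_demography(growth, mort, ref_size = 10, ref_light = 4.5)
tradeoff_summary(demog)
#> Standardized major axis regression (n = 15 )
#>   slope     0.9500  [0.5738, 1.5726]
#>   intercept -0.0940
#>   r = 0.480, R2 = 0.230, p = 0.07027
#>   an SGR increase of 0.1 yr^-1 implies a 9.5 percentage-point change in annual mortality
```

The scaling exponent β̂ = 0.861 recovers the generator's 0.86 (sub-
exponential growth: bigger seedlings grow relatively slower); the α range
and the light slope recover the species spread and the proportional light
effect; the mortality fit recovers the negative light and size effects.
`demog` holds per-species SGR (yr⁻¹ at 10 mm and 4.5% openness) and annual
mortality; the SMA slope converts directly into percentage points of annual
mortality per 0.1 yr⁻¹ of SGR. At 15 species the trade-off test has limited
power — correlations near 0.5 sit at the p ≈ 0.05 boundary, as the
correlation matrix shows:

```r
traits <- estimate_trait_means(sim$traits$observations)
tab <- dplyr::inner_join(traits,
                         dplyr::select(demog, species_id, sgr_yr, annual_mortality),
                         by = "species_id")
correlation_matrix(tab, vars = c("wood_density", "seed_mass", "leaf_cn",
                                 "sla", "sgr_yr", "annual_mortality"))
#> Pearson correlations (15 pairs; * p<0.05, ** p<0.01)
#>                  wood_density seed_mass leaf_cn sla   sgr_yr annual_mortality
#> wood_density
#> seed_mass        -0.09
#> leaf_cn          -0.35        0.02
#> sla              -0.07        0.14      -0.17
#> sgr_yr           -0.59*       0.14      0.19    -0.29
#> annual_mortality -0.25        0.42      -0.24   -0.29 0.48
```

Wood density — the one trait the generator couples to demography — comes out
negatively correlated with SGR; the other traits are noise, as designed.
`autoplot()` methods draw the fitted trajectories with parametric confidence
bands, the per-species mortality–light curves and the SMA scatter;
`tidy()`/`glance()` return broom-style tibbles. `run_pipeline(run_config(...))`
chains every stage and writes all tables plus a JSON manifest.

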