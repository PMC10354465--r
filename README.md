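# phenorep

Variance partitioning, repeatability and heritability of breeding
phenology from longitudinal records of individually marked animals.

The package implements the analysis chain used for long-term monitoring of
female southern elephant seals (*Mirounga leonina*) at Marion Island: one
row per female × breeding season, with the arrival date at the breeding
colony as the response. It answers four questions about reproductive
timing:

1. **How repeatable is arrival date?** A Gaussian linear mixed model with
   crossed random effects partitions phenotypic variance
   σ²_P into between-individual (σ²_i), between-year (σ²_j) and residual
   (σ²_ε) components. Repeatability is the "enhanced agreement" form
   R = σ²_group / (σ²_i + σ²_j + σ²_ε + σ²_f), with the fixed-effect
   variance σ²_f added back into the denominator; confidence intervals come
   from a parametric bootstrap.
2. **Do individuals differ in plasticity?** Each female gets a behavioural
   reaction norm on the (standardized) departure date of her preceding
   moult: a random intercept and a correlated random slope
   (arrival_ij = cell mean(age, state) + β_wean·wean_i + (β_moult + s_i)·moult_ij
   + u_i + v_j + ε_ij). The slope term is tested with a likelihood-ratio
   test (χ² with 2 df: slope variance + intercept–slope covariance).
3. **Which fixed effects matter?** Candidate fixed structures (age ×
   breeding-state cell means, moult and wean covariates, within-subject-centred
   climate indices SAM/SOI, population density, a linear trend) are fitted
   by ML and ranked by AIC = deviance + 2·n.p.; the best model is refitted
   by REML for estimation.
4. **Is timing heritable?** Mother–daughter dyads of first-breeding arrival
   dates (daughters averaged per mother) give a single-parent regression;
   narrow-sense heritability is h² = 2 × slope, with significance from a
   randomized-dyad permutation test.

Because the original field data are not bundled, the package ships a
calibrated individual-based simulator (`simulate_population()`) that
reproduces the statistical shape of the study population — ~1772 females,
~5297 female-season records over 1989–2019, individual intercept SD 6.5 d,
slope SD 1.6, year variance 3.08 d², residual variance 44.56 d², heritable
intercepts with h² ≈ 0.4 — so every stage of the pipeline can be verified
against known truth. Dates are day offsets: breeding dates from
1 September, moult dates from 1 November of the preceding summer.

## Worked example

```r
library(phenorep)

cfg     <- sim_config(seed = 2026)            # the calibrated default world
records <- simulate_population(cfg)
fit     <- fit_lmm(records, model_spec(c("age*state", "moult", "wean")),
                   method = "REML")
fit
#> <pheno_lmm> age*state + moult + wean [REML]
#>   5325 obs, 1767 females, 31 years; n.p. = 30
#>   sigma_i2 = 39.69  sigma_m2 = 1.15  cov = -0.545  sigma_j2 = 2.92  sigma_e2 = 44.27
#>   logLik (REML) = -18727.26

repeatability(fit, "female")
#> # A tibble: 1 × 8
#>   group      R sigma_group2 sigma_f2 denominator include_slope include_fixed singular
#>   <chr>  <dbl>        <dbl>    <dbl>       <dbl> <lgl>         <lgl>         <lgl>
#> 1 female 0.406         39.7     10.9        97.8 FALSE         TRUE          FALSE
```

The fitted variance components sit near their generative values
(σ²_i = 42.25, σ²_j = 3.08, σ²_ε = 44.56), and individual identity explains
~41% of phenotypic variance in this draw — arrival date is a strongly
repeatable trait. `bootstrap_ci()` adds percentile intervals,
`rank_models(records, env, marion_models())` reproduces the AIC ranking
workflow, `build_dyads()` + `parent_offspring_h2()` give the heritability
regression, and `run_pipeline()` chains every stage into one reproducible
run directory. Plot helpers (`plot_reaction_norms()`, `plot_age_curve()`,
`plot_dyads()`, `plot_permutation()`) return ggplot objects.

`marion_model_table()` carries the reported model-selection table
(n.p., ΔAIC, deviance) of the source analysis for bookkeeping checks, and
`true_parameters(cfg)` exposes the generative truth (variance components,
σ²_f, R, h²) for any configuration.

## Acceptance script

```
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at the given seed: the individual-intercept
variance, the moult-date slope and the wean-date slope recovered by a REML
refit of the top model on one study-scale synthetic dataset, and the
narrow-sense heritability estimated from mother–daughter dyads in a large
heritable population. Results are written as JSON with the problem size of
each computation.

## Layout

- `R/simulate.R` — configuration, environment series, individual-based
  population generator, generative truth and heritability calibration
- `R/datamodel.R` — CSV ingestion/validation, within-subject centring,
  age×state cells, model specifications and design bookkeeping
- `R/lmm.R` — REML/ML fitting (lme4 backend), AIC, reaction norms,
  `tidy()`/`glance()` methods
- `R/modelsel.R` — random-slope LRT, AIC ranking
- `R/varpart.R` — variance partition, repeatability, parametric bootstrap,
  first-vs-later regression
- `R/herit.R` — dyads, parent–offspring h², permutation test
- `R/agecurve.R` — age×state cell means, old-age trend
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/phenology-methods.Rmd` — model, assumptions, calibration
  derivations and design choices
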