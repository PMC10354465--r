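---
title: "Models and methods: repeatability, plasticity and heritability of breeding arrival dates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenorep analyses longitudinal breeding-phenology tables — one row per
female × breeding season — built around the annual cycle of capital-breeding
female elephant seals: a moult haulout in early summer, a long foraging
migration, and arrival at the breeding colony the next spring to give birth.
This vignette states the model, the conventions and calibrations behind the
synthetic data generator, and the design choices made where the problem was
genuinely open. It contains no empirical claims beyond what the package's
tests and acceptance script themselves compute.

## The mixed model

The arrival date (in days from 1 September of the breeding year) of female
$i$ in season $j$ is modelled as

$$
y_{ij} = \mu_{c(i,j)} + \beta_w\,\mathrm{wean}_i + (\beta_m + s_i)\,
\mathrm{moult}_{ij} + u_i + v_j + \varepsilon_{ij},
$$

where $\mu_{c}$ are age × breeding-state cell means, $\mathrm{wean}_i$ is
the female's own weaning date as a pup (time-constant), and
$\mathrm{moult}_{ij}$ the departure date of her preceding moult haulout
(season-varying; days from 1 November, so the covariate never wraps a
calendar year). The random effects are crossed:

* $(u_i, s_i)$ — bivariate normal individual intercepts and moult-slopes
  with variances $\sigma^2_i$, $\sigma^2_m$ and covariance
  $\mathrm{cov}_{im}$: the behavioural reaction norm of breeding arrival on
  moult timing;
* $v_j \sim N(0, \sigma^2_j)$ — year intercepts;
* $\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)$ — residual
  within-individual variation.

Estimation is restricted (or full) maximum likelihood through `lme4`, the
standard tool for this model class; the package surface (`fit_lmm()`)
returns the five random-effect parameters, both likelihoods, the deviance
and BLUPs, and is verified against two independent oracles in the test
suite: the closed-form ANOVA solution of a balanced one-way layout, and a
dense multivariate-normal evaluation of the likelihood on a tiny crossed
fixture. Boundary fits (a zero variance or |correlation| = 1) are flagged
as singular (Cholesky tolerance 1e-6) rather than treated as errors.

### Age × state cells

Ages are capped at 21; first-time and experienced breeders are separated at
ages 4–7; age 3 is first-breeder-only; from age 8 the two states share one
cell: 23 cells, coded as cell means (no intercept). This coding makes the
fixed-column count plus the random-parameter count reproduce the reported
n.p. of every candidate model (a 12-row bookkeeping identity asserted in
the tests) and avoids rank deficiency from the partial crossing of age and
state.

### Covariate scaling

The moult and wean covariates enter the design **z-standardized** over the
analysed rows, so both population slopes are "days per SD of covariate" and
the random moult-slope is centred. This is a deliberate deviation from
merely grand-mean-centring, forced by internal consistency: the variance
partition treats $\sigma^2_m$ (≈2.6) as directly summable with day²
components, which requires $\mathrm{Var}(\mathrm{moult}) \approx 1$ on the
analysis scale; and a moult slope of ~1.9 on a day-scaled covariate with a
realistic 6–8 d spread would imply a fixed-effect variance larger than the
total phenotypic variance implied by the observed arrival spread (~10 d
SD). Standardization reconciles the slopes, the variance components, the
repeatability and the arrival distribution simultaneously. Climate indices
(SAM, SOI) and density are additionally split by within-subject centring
into a between-individual mean and within-individual deviations (two
columns each); the linear trend enters raw.

## Model selection

Random structure first: the female moult-slope (plus its covariance with
the intercept) is tested by a likelihood-ratio test against the
random-intercept model with the same fixed part, referred to $\chi^2_2$.
At the variance boundary this reference is conservative; the package uses
it as-is (documented) rather than a boundary mixture. Fixed structures are
then ranked by AIC = deviance + 2·n.p. from ML fits (REML likelihoods are
not comparable across fixed structures, and `aic()` refuses them); ties
break by fewer parameters, then input order. The best structure is refitted
by REML for reporting.

## Repeatability

Repeatability is the "enhanced agreement" ratio with the fixed-effect
variance added back:

$$
R_{\mathrm{group}} = \frac{\sigma^2_{\mathrm{group}}}
{\sigma^2_i + \sigma^2_j + \sigma^2_\varepsilon + \sigma^2_f},
\qquad \sigma^2_f = \mathrm{Var}(X\hat\beta),
$$

with $\sigma^2_f$ the population variance of the fitted fixed linear
predictor over the analysed rows. The individual slope variance
$\sigma^2_m$ is **excluded** from the denominator by default: this is the
only convention under which the reported point estimates for females
(0.45) and years (0.03) are reconcilable with the reported variance
components through a single $\sigma^2_f$ (≈4.1); a flag includes it.
Confidence intervals are percentile bounds from a parametric bootstrap
(simulate from the fitted model, refit, recompute R; inverse-ECDF
quantiles so a 2-replicate smoke run returns min/max). The bootstrap errors
out if more than 10% of refits fail.

## Heritability

Mother–daughter dyads pair a mother's first recorded breeding arrival with
her daughters' mean first-breeding arrival; the single-parent regression
slope doubles into narrow-sense heritability, $h^2 = 2b$. Significance uses
a permutation null: daughter values are shuffled across daughter slots with
the mother vector and the daughters-per-mother counts held fixed, then
re-averaged — the closest exchangeable null to "dyads drawn at random" that
preserves the observed multiplicity structure. The p-value is the plain
count/n_perm of null $h^2$ values exceeding the observed one (a
(count+1)/(n+1) variant is available).

## The synthetic world

`simulate_population()` is the generative inverse of the analysis model,
calibrated once to the published summaries of the Marion Island population
and then frozen:

| quantity | default | basis |
|---|---|---|
| founders / analysed females | 1340 → ~1772 | analysed-data counts |
| records | ~5300 | analysed-data counts |
| seasons per female | 1–16, mean ~3 | records ÷ females |
| mean arrival | offset 33 (4 Oct) | reported median |
| $\sigma_i$, $\sigma_m$ | 6.5 d, 1.6 | reported SDs |
| $\sigma^2_j$, $\sigma^2_\varepsilon$ | 3.08, 44.56 d² | reported components |
| $\beta_m$, $\beta_w$ | 1.92, 1.26 d/SD | reported slopes |
| cell means | first-breeders 2–3 d early; experienced peak at prime age, −0.43 d/yr from age 8 | reported age pattern |
| survival, skip | 0.73, 0.15 | calibrated to counts; gap structure unreported |
| recruitment ages | 3–7, weights (.30,.30,.20,.15,.05) | cell structure; exact distribution unreported |
| moult dates | mean 45 (mid-Dec), between/within SD 5/4 d | realistic haulout spread |
| wean link | mother's arrival + 28 d + N(0, 5.6²) | ~5 d pre-partum + ~23 d lactation |
| h² | 0.40 (phenotypic target) | reported estimate |

With these values the implied arrival SD is ~10 d and the central 80%
interval ~26 d (matching the reported late-September–mid-October spread),
the generative female repeatability is ~0.44 and the year repeatability
~0.03 — inside the reported intervals. Observation error (surveys up to
weekly, so observed arrivals can be late by up to 6 d) is **off** by
default and excluded from acceptance runs; `obs_error_max = 6` enables a
uniform late-shift.

### Heritability calibration

Two pathways make daughters resemble mothers: genetic transmission of the
intercept ($a_d = 0.5\,a_{mother} + $ Mendelian noise of variance
$0.75\,\sigma^2_a$, so the phenotypic dyad covariance gains
$0.5\,\sigma^2_a$), and a maternal pathway — a daughter's weaning date
tracks her mother's arrival in the birth season and feeds back into the
daughter's own arrival through $\beta_w$. A configured $h^2$ on the
intercept scale alone cannot reproduce the *phenotypic* parent–offspring
estimate of ~0.4: the regression is attenuated by year and residual
variance, capping the recoverable phenotypic $h^2$ near 0.34. Since the
reported quantity *is* the phenotypic narrow-sense heritability (twice the
phenotype regression slope), the generator treats `h2` as the phenotypic
target and back-solves

$$
\sigma^2_a = h^2\,\mathrm{Var}(y_{\mathrm{first}}) - 2\,
\underbrace{\beta_w\,\kappa\,\mathrm{Var}(y_{\mathrm{first}})/s_w}_{\text{maternal covariance}},
$$

where $s_w$ is the weaning-date SD and $\kappa$ the deterministic
correlation factor between a mother's first arrival and her arrival in a
random breeding season (mixture over the survival/skip season process,
the between-female share of moult variance, and the recruit-age-induced
covariance of cell means; `herit_calibration()` exposes every term).
Targets below the maternal floor or above what $\sigma^2_i$ allows are
clamped with a warning. With the maternal link switched off
(`maternal_wean_link = FALSE`) the rule reduces to
$\sigma^2_a = h^2\,\mathrm{Var}(y_{\mathrm{first}})$, and an $h^2 = 0$
world is exactly exchangeable — the configuration used for type-I-error
checks of the permutation test.

A corollary, real in the study system too: the wean fixed effect is
confounded with the genetic intercept in heritable worlds, biasing
$\hat\beta_w$ upward by ~0.2–0.3 d/SD. Estimator-recovery checks therefore
use a world parameterized only by the variance components and slopes
(heritable machinery off).

### What the generator does not emulate

Detection/tag-resight error (off by default), spatial structure within the
colony, male seals, tag loss, multi-generation pedigrees (daughters do not
reproduce), and real climate series (SAM/SOI are standardized AR(1)
surrogates). A green recovery test therefore establishes correctness of the
estimators under the stated stochastic model, not robustness to survey
artefacts.

## Numerical choices

* Optimizer: lme4 defaults with derivative checks disabled for speed;
  oracle tests tighten `xtol_abs`/`ftol_abs` to 1e-12.
* Singularity: `isSingular(tol = 1e-6)` on the standardized Cholesky scale.
* Bootstrap/permutation/environment/population streams derive child seeds
  deterministically from one master seed, so stages are independently
  reproducible.
* Percentile CIs use inverse-ECDF quantiles (type 1).
* Negative LRT statistics (numerical noise under nesting) clamp to zero
  with a warning.
* Out-of-range $h^2$ estimates (outside [0, 1]) are reported with a
  warning, never clipped.
* Degenerate inputs error early and informatively: empty year ranges,
  all-zero variance partitions, duplicate (female, year) keys, non-monotone
  ages, wean dates varying within a female, fewer observations than fixed
  columns.

## Known limitations

* Wald standard errors and CIs throughout (no profile or small-sample df
  corrections), matching the reporting style the analysis mirrors.
* The slope variance $\sigma^2_m$ and year variance $\sigma^2_j$ are
  weakly identified at ~3 records per female and 31 year levels: their
  single-dataset estimates carry Monte-Carlo noise of roughly 45% and 30%
  of the true values. Recovery assertions for these components use
  simulation-SE-based bands; per-replicate ±10% bands are not attainable
  for them in this world.
* The $\chi^2_2$ random-slope test is conservative at the boundary.
* The age-3 cell exists only for first-time breeders, and cells absent
  from a dataset are reported as missing rather than imputed.
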