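---
title: "Counterfactual mediation in the mother-milk-infant triad: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual mediation in the mother-milk-infant triad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(milkmediate)
library(dplyr)
```

## The scientific problem

Appetite-regulating hormones (ARHs) — leptin, insulin and adiponectin — are
present in human milk, and their concentrations have been associated both
with maternal adiposity and with infant milk intake and growth. Two causal
questions structure the package:

1. Are associations between maternal body composition (BMI, fat-mass index)
   and milk ARH concentrations *mediated* by the maternal circulating level
   of the same hormone, or do they reflect direct secretion pathways
   (mammary epithelium, adipose tissue)?
2. Are associations between milk ARHs and infant outcomes (24-h milk intake,
   intake per feed, weight, length, fat-mass index, body-fat %) mediated by
   the infant's circulating hormone level — as would be expected if
   ingested hormone is absorbed and acts systemically?

Cohorts of this kind follow mother–infant dyads over three postpartum
visits (1–3.49, 3.5–5.99 and 6.0–8.5 months) plus a colostrum sample within
72 h of birth, with repeated hormone panels in milk, maternal plasma and
infant plasma, maternal body composition, infant anthropometry, and a 24-h
test-weighing protocol for milk intake. Such dyad-level datasets are rarely
public, so the package ships a calibrated synthetic cohort generator with a
*known* mediation structure: every downstream stage is testable by
parameter recovery rather than by re-analysis of private data.

## The mediation model

For exposure $X$ (e.g. maternal BMI), mediator $M$ (log maternal plasma
hormone) and outcome $Y$ (log milk hormone), three linear mixed models are
fit, each with a per-subject random intercept to absorb the repeated
visits:

$$\begin{aligned}
\text{(1) total effect:}\quad & Y = \gamma_0 + c_1 X + \boldsymbol{\beta}'\mathbf{Z} + u_i + \varepsilon \\
\text{(2) mediator model:}\quad & M = \alpha_0 + a_1 X + \boldsymbol{\alpha}'\mathbf{Z} + v_i + \varepsilon' \\
\text{(3) outcome model:}\quad & Y = \delta_0 + c_1'' X + b_1 M + b_3 XM + \boldsymbol{\delta}'\mathbf{Z} + w_i + \varepsilon''
\end{aligned}$$

with covariates $\mathbf{Z}$ fixed a priori (research question 1: infant
sex, visit, visit-centred age; research question 2 intake outcomes: milk
energy, sex, infant weight, centred age; growth outcomes: milk energy,
total intake, birth weight, sex, centred age).

The indirect (mediated) effect at exposure level $x$ is the product of
coefficients

$$\widehat{\text{indirect}}(x) = \hat a_1\,(\hat b_1 + \hat b_3 x),$$

the direct effect is $\hat c_1 - \widehat{\text{indirect}}(x)$, and the
proportion mediated is $100\cdot\widehat{\text{indirect}}(x)/\hat c_1$.
Defining the direct effect by subtraction makes the decomposition identity
`direct + indirect = c1` hold to machine precision by construction. In the
linear, interaction-free case the product of coefficients coincides with
the difference of coefficients $c_1 - c_1''$ (an algebraic identity for
nested least-squares fits on identical complete cases; `run_mediation()`
enforces one shared complete-case set across steps precisely so this
identity is meaningful).

These closed forms coincide with the counterfactual natural direct/indirect
effects for linear models; with an exposure–mediator interaction the
decomposition is reported at each of the two fixed exposure levels.

### Monte Carlo confidence interval

The sampling distribution of a product of two regression coefficients is
not normal, so the indirect-effect CI is built by simulation: draw
$a^* \sim N(\hat a_1, \widehat{\mathrm{Var}}(\hat a_1))$ and
$(b_1^*, b_3^*)$ jointly from the outcome model's multivariate normal,
form $a^*(b_1^* + b_3^* x)$ per draw, and take percentile quantiles
(default 20,000 draws, 95% level). Draws from the two models are
independent — the models are fit separately and share no estimated
parameters. `monte_carlo_ci()` is validated in the test suite against a
brute-force product-distribution quantile computation at $10^6$ draws
(agreement within 0.005) and its 95% interval attains 93–97% empirical
coverage over 1,000 simulated cohorts of 200 dyads.

### Interaction screening and exposure dichotomisation

`screen_and_dichotomize()` Wald-tests the exposure-by-mediator coefficient
in the outcome model. If significant at 0.05, the exposure is converted to
the conventional adiposity categories — overweight at BMI $\ge 25$
kg/m$^2$ (closed bound), excessive fat mass at FMI $> 9$ (open bound) —
and the interaction is retained, giving level-specific decompositions at
the two category codes (0, 1). Otherwise the continuous, interaction-free
analysis proceeds.

### Back-transformation

Outcomes analysed on the natural-log scale are reported as percent
differences, $100(e^\beta - 1)$ (`percent_difference()`). For outcomes in
original units regressed on a log exposure, the effect of a `pct`%
exposure increase is $\beta\,\ln(1 + \text{pct}/100)$
(`effect_per_percent_increase()`). Both are exact closed forms.

## Mixed-model engine

All models are `outcome ~ fixed effects + (1 | dyad)` fit by REML through
lme4. Design choices:

* **Random intercept only.** The subject random effect captures
  within-dyad correlation across visits; no random slopes are fit. The
  hormone-trajectory description (`visit_contrasts()`) consequently uses a
  compound-symmetric within-subject covariance rather than an unstructured
  one; with three visits and moderate dispersion the adjacent-visit
  contrasts are nearly identical, but users should know the covariance
  model is the simpler one.
* **Wald z inference.** Coefficient p-values use the normal reference
  distribution. Degrees-of-freedom corrections (Satterthwaite,
  Kenward-Roger) matter mainly below ~30 subjects, far under the cohort
  sizes targeted here.
* **OLS degeneracy.** When each subject contributes one row the random
  intercept is unidentifiable and the fit reduces to ordinary least
  squares; the same fallback catches degenerate mixed fits (e.g. zero
  residual variance). The `engine` field of the fit records which path ran.
* **Complete cases.** Each model drops rows incomplete for its own
  variables; the mediation engine additionally restricts all steps to one
  shared complete-case set, and reports the total-effect model both ways
  (`c1_full` on its own larger sample vs `c1` on the shared sample), since
  mediator missingness — infant plasma is drawn at V2 and only one of
  V3/V4 — can shrink the mediation sample substantially and attenuate
  previously significant total effects.

## The synthetic cohort generator

`generate_cohort()` draws dyads with:

* **Visit structure**: colostrum (V1) for 65% of dyads, then three
  postpartum visits with ages uniform in the study windows and per-visit
  retention (1.00 / 0.94 / 0.91 by default, matching typical completion).
* **Hormones**: log-normal per compartment (milk, maternal plasma, infant
  plasma) with per-visit medians defaulting to published cohort medians
  (e.g. milk leptin 419/90/48/33 pg/mL across V1–V4) and log-scale SDs
  chosen from the corresponding interquartile ranges. Between-subject vs
  residual variance shares are not identifiable from published summaries;
  the default splits each channel's variance equally (configurable via
  `subject_sd` / `resid_sd`).
* **Mediation structure**: the `a1, b1, b3, c1_prime` slopes of
  `cohort_params()` act on centred exposure and centred log mediator, so
  the configured medians stay the marginal medians; slopes are invariant
  to this centring and the per-visit shift is absorbed by the visit term
  the analysis models include. The same structure is applied to all three
  hormones; an optional `rq2_*` structure routes log milk insulin through
  infant plasma insulin into infant weight.
* **Exposure**: maternal BMI is drawn once per mother (mean 23.6, SD 3.0)
  with a small downward drift across visits (postpartum weight loss) and
  within-mother visit noise; FMI is a linear map of BMI plus noise rather
  than a bioimpedance model.
* **Censoring**: below-LOD values are blanked with a flag. Detection
  limits are 12 pg/mL (insulin), 11 pg/mL (leptin) and 5 ng/mL
  (adiponectin) in assay units; after the assay dilution factors, the
  plasma leptin/adiponectin and milk adiponectin channels are effectively
  uncensored at observed concentrations (published milk adiponectin
  interquartile ranges sit entirely below the nominal assay LOD, so the
  effective LOD in measured units must be lower), hence the default
  censor thresholds apply to milk leptin, milk insulin and plasma insulin
  only.
* **Feed logs**: per-feed volumes are a Dirichlet split of the true daily
  total (so clean logs conserve it exactly — weights are left unrounded;
  scale-resolution rounding is deliberately not simulated), timestamps are
  uniform in the 08:00-to-07:59 window, and missing weights (2%/feed) and
  >400 g spikes (0.5%/feed) are injected at configurable rates.
* **Infant phenotypes** are drawn around sex-and-visit reference means
  (e.g. birth weight 3510 ± 364 g, milk energy 633 ± 102 kcal/L).

What the generator does **not** emulate: assay plate effects and
inter-assay drift, colostrum-collection timing variation, informative
(outcome-dependent) dropout, seasonality, or any non-lognormal hormone
shape. Passing recovery and coverage tests therefore demonstrates that the
estimator chain is correct *under the generating model*, not that the
model is a complete description of real dyad data.

## Test-weighing intake

`feed_volume()` is the post-minus-pre weight difference, reported as mL at
density 1 g/mL; negative differences are treated as missing (physically
impossible intake — the protocol is silent on them). QC marks single
feeds above 400 g as unrealistically high *before* counting missing feeds
(so a spike contributes to the discard rule), and logs with more than 3
missing feeds are discarded. Remaining gaps are hot-deck imputed from the
nearest non-missing feed by event index, preferring the preceding feed on
a distance tie (the published rule names "neighboring weights" without
fixing the tie-break; nearest-preceding is deterministic and requires no
RNG). Imputation never alters observed volumes.

## Numerical and reproducibility choices

* Every stochastic entry point (`generate_cohort()`, `monte_carlo_ci()`,
  `run_mediation()`, `run_simulation_study()`) requires an explicit seed
  and restores the global RNG state afterwards; reruns with identical
  inputs are byte-identical.
* Age centring uses `age - mean(age at visit)`; the opposite sign
  convention yields the same fits with flipped coefficient sign.
* Values exactly at the LOD are treated as detectable; substitution uses
  `0.5 * LOD` and is idempotent.
* Proportion mediated divides by the step-1 total effect at every exposure
  level (the alternative `indirect / (indirect + direct)` is identical
  under the subtraction-based decomposition); it is reported as undefined
  when `c1 = 0`.
* The simulation study sizes used by the acceptance checks are 400 dyads
  x 200 replicates for bias and 200 dyads x 1,000 replicates for
  coverage, with 5,000 Monte Carlo draws per CI — endpoint noise at 5,000
  draws is already an order of magnitude below the coverage tolerance.

## Worked example

```{r example}
params <- cohort_params(n_dyads = 300, seed = 11,
                        a1 = 0.5, b1 = 0.8, c1_prime = 0.2,
                        lod_censor = FALSE)
cohort <- generate_cohort(params)
visits <- preprocess_visits(cohort$visit_table) |> filter(visit != "V1")

res <- run_mediation(
  visits,
  mediation_spec("bmi", "log_mplasma_leptin", "log_milk_leptin",
                 covariates = c("infant_sex", "visit", "centered_age"),
                 n_draws = 20000, seed = 5))
tidy(res)
glance(res)
```

With the generating values `a1 = 0.5`, `b1 = 0.8`, `c1' = 0.2` the indirect
effect should land near 0.40 and the direct effect near 0.20, with the
Monte Carlo CI excluding zero.

## Known limitations

* Mediation validity rests on the usual no-unmeasured-confounding
  assumptions for the exposure-outcome, exposure-mediator and
  mediator-outcome relations, plus no exposure-induced mediator-outcome
  confounding; none of these are testable from the data.
* Only two-level categorical or continuous exposures, a single mediator,
  and Gaussian outcomes are supported; no sensitivity analysis for
  unmeasured confounding is provided.
* The trajectory model's compound-symmetry covariance is a simplification
  (see above).
* p-values across the hormone-by-outcome grid are unadjusted, matching
  field practice; the result tables carry the test count so users can
  apply their own correction.
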