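---
title: "Two-part multilevel models of long-term care need and use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part multilevel models of long-term care need and use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltchurdle)
```

## The model

`ltchurdle` studies home-based long-term care (LTC) among older adults in a
multi-country survey. Two questions are deliberately separated, because the
forces behind them differ: *who needs personal care*, and — given need —
*which form of care is used* (informal care by family or other unpaid
persons, formal paid services, a mixture of both, or none despite need, i.e.
unmet need).

**Part I (need).** For individual $i$ in country $j$, need is a binary
indicator derived from self-reported functional limitations. Its probability
follows a logit model with a country random intercept:

$$\Pr(y^*_{ij} > 0 \mid x_{ij}, u_{0j})
  = \operatorname{logit}^{-1}\!\left(x_{ij}'\beta + u_{0j}\right),
  \qquad u_{0j} \sim N(0, \sigma^2_{u_0}),$$

where $x_{ij}$ stacks individual-level covariates (wealth quintile,
education, partner and children indicators, age and age squared, sex) and
country-level covariates (means testing, cash-for-care availability, LTC
beds per 1,000 aged 65+, net pension replacement rate, a personal-care price
index, GDP per capita, female labour-force participation). One stacked
coefficient vector covers both blocks.

**Part II (care type conditional on need).** Among those in need, the
four-way care outcome follows a multinomial logit with reference category
"none" and a country random intercept per non-reference care type:

$$\Pr(y_{ij} = k \mid y^*_{ij} > 0, x_{ij}, u_{kj})
  = \frac{\exp(x_{ij}'\beta_k + u_{kj})}
         {1 + \sum_{l} \exp(x_{ij}'\beta_l + u_{lj})},
  \qquad u_{kj} \sim N(0, \sigma^2_k) \ \text{independent across } k.$$

**Unconditional use.** The hurdle assumption — observed need implies some
care is required — lets the population probability factor as a product:
$\Pr(\text{type } k) = \Pr(\text{need}) \cdot \Pr(k \mid \text{need})$, and
$\Pr(\text{no care}) = 1 - \Pr(\text{need}) + \Pr(\text{need}) \cdot
\Pr(\text{none} \mid \text{need})$. Rows of the four-way table sum to one by
construction; the "no care" cell mixes the never-needing with unmet need.

## Estimation

Both parts are estimated by maximum marginal likelihood. Each country's
likelihood contribution integrates the product of its individual likelihoods
over the random-intercept law; the integral is approximated by **adaptive
Gauss-Hermite quadrature** (AGHQ): nodes are recentred at each country's
posterior mode and rescaled by the posterior curvature at every likelihood
evaluation. Part I integrates in one dimension (15 nodes by default);
Part II uses a tensor-product grid over the three care-type intercepts
(7 nodes per dimension by default, $7^3$ points). Adaptivity matters here:
the care outcomes are rare (a few percent of the sample), so non-adaptive
grids centred at zero lose accuracy at moderate $\sigma$. With SDs at zero
the code evaluates the pooled logit / multinomial logit exactly — no
quadrature — which the test suite exploits as an equivalence oracle against
`stats::glm` and `nnet::multinom`.

Optimization is BFGS on $(\beta, \log\sigma)$ with analytic gradients of the
quadrature approximation, in a column-equilibrated design space (each design
column scaled by its maximum absolute value; estimates are reported on the
original scale). The $\log\sigma$ parameterization keeps the SDs positive;
$\hat\sigma < 10^{-4}$ is flagged as a boundary-zero estimate, which is a
real possibility with 18 countries. Numerical policies worth knowing:

* Convergence is declared when the largest score component is below
  `gradient_tolerance` $\times (1 + |\ell|)$ (default $10^{-5}$), after up
  to three BFGS restarts. Score components of boundary-zero $\log\sigma$
  coordinates are exempt — at a boundary MLE that score tends to a negative
  constant, not zero. If a restart improves the log-likelihood by less than
  $10^{-7}(1+|\ell|)$ the point is accepted as a (possibly flat) optimum;
  this arises in small bootstrap replicates where a care type has a handful
  of observations and its $\sigma$ is weakly identified.
* Apparent separation (any equilibrated coefficient beyond 30) stops with an
  error naming the covariate.
* The observed-information covariance matrix (central finite differences of
  the analytic gradient) is attached for diagnostics and simulation checks;
  **inference on margins uses the bootstrap**, not these SEs.

Country covariates are centred at fixed reference values and age enters as
$(\text{age}-65)$ and its square (`expand_covariates()`); centring changes
neither slopes nor marginal effects but keeps the optimizer and the rank
check well conditioned.

## Average marginal effects and the bootstrap

`ame()` reports sample-average marginal effects for seven columns: need, the
three conditional care types, and the three unconditional ones (their
products). For binary and grouped-dummy covariates the AME is the mean
counterfactual difference (the covariate set to its level versus the group
reference, all else observed); for continuous covariates a central
difference with step $10^{-5}\,\mathrm{sd}(x)$. Age and age squared are
reported as separate rows, matching the published table convention, and a
coherent joint perturbation (`"age_joint"`) is available as a diagnostic.

`bootstrap_margins()` resamples **individuals with replacement within each
country** (country sizes preserved; default $B = 100$), refits both parts
per replicate warm-started at the full-sample estimates, and reports the
replicate SD as the bootstrap SE together with basic (reverse-percentile,
labelled "inverted") or percentile intervals. A whole-country cluster
bootstrap is provided as an option but is not the default: with 18 clusters
it is unstable. Failed replicates are dropped and counted; more than 20%
failures is an error. Stars use the normal approximation
$z = \hat\theta/\widehat{SE}$ at the 10/5/1% thresholds.

Two prediction modes exist for all margins: `marginal` (population-averaged,
integrating over the random-intercept law; the default, as the natural
reading of "predictive margins") and `conditional_zero` (a median country,
$u = 0$). Validation runs report both; conditional-at-zero margins are
systematically further from one half than the marginal ones (the usual
attenuation of population-averaged logistic probabilities).

McFadden pseudo $R^2$ ($1 - \ell/\ell_0$, null = intercept plus random
intercept on the identical sample) and its increment from the country-level
covariate block are computed by `mcfadden_r2()` / `incremental_r2()` and by
the pipeline's `pseudo_r2.json` report.

## The synthetic study population

The generator (`generate_country_table()`, `generate_population()`) emulates
the hierarchical structure of a European ageing survey: 18 countries,
roughly 35,000 community-dwelling respondents aged 50+, rare outcomes. It
draws country covariates from simple laws centred on the published sample
composition (e.g. LTC beds $\sim N(44.9, 10^2)$ truncated at 0, half of
countries means-testing), individual covariates from independent laws (age
truncated-normal with mean 66.6 on [50, 100], uniform wealth quintiles
mirroring quintile construction, education 17/61/22%, partner 67%, children
88%), then need from the Part I model and — for needers only — care type
from the Part II model. Limitation counts are filled in *after* the latent
need draw so the generating definition ("1+ IADL") reproduces the latent
indicator exactly: needers receive $1 + \text{Poisson}(1)$ IADL limitations,
a thinned ADL measure and a GALI severity; non-needers receive zero counts.
Survey weights default to 1, with a Gamma option to exercise the weighted
descriptives.

The packaged calibration (`share_like_params()`) fixes slopes once, a
priori, with signs and magnitudes following the published gradients (wealth
and education reduce need; partners raise informal and depress formal use;
means testing depresses formal use; cash-for-care raises mixed use; LTC beds
raise formal use), with random-intercept SDs 0.30 (need) and 0.45/0.55/0.50
(care types). The four intercepts were then solved by Monte-Carlo root
finding (iterative proportional fitting on a fixed one-million-draw
covariate sample, expectations over the random intercepts taken by
quadrature) so the generator's expected composition is 16.2% need (1+
IADL) and 3.2/1.9/0.8% informal/formal/mixed overall — the composition of
the emulated survey sample.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: covariates are drawn independently (no
age-wealth or partner-age correlation; the published tables do not identify
a joint law), sampling design and weights are trivial, item non-response and
imputation are absent, and Part II random intercepts are independent across
care types. The recovery and coverage results certify the estimator under
its own assumptions, not robustness to their violation.

## Design choices on genuinely open points

* **Part II random structure.** Published phrasing ("the average level of
  each type of care varies randomly within countries") reads most naturally
  as type-specific intercepts, so `per_category_independent` (3-D
  quadrature) is the default; a `shared` single-intercept variant (1-D) is
  provided for sensitivity, and output labels the structure. Correlated
  type-specific intercepts are not estimated — 18 clusters cannot support a
  free 3×3 covariance — and this is a documented limitation.
* **"Inverted" bootstrap intervals** are read as the basic
  (reverse-percentile) interval $\left[2\hat\theta - q_{1-\alpha/2},\,
  2\hat\theta - q_{\alpha/2}\right]$; percentile intervals are the
  alternative.
* **Estimation is unweighted**; survey weights enter the descriptive table
  only (weighted means/percents with two-sample $z$ tests on Kish effective
  sample sizes against the "no care" column), since the published weights
  note attaches to the descriptives.
* **The collapsed (binary use) layout** is derived from the four-way Part II
  fit as $\Pr(\text{use} \mid \text{need}) = 1 - \Pr(\text{none} \mid
  \text{need})$ rather than refitting a binary Part II, keeping the two
  layouts mutually consistent.
* **Need definitions** `iadl1`, `iadl2`, `adl1`, `adl2`, `gali_any`,
  `gali_severe` support the severity-threshold and subjective-indicator
  sensitivity analyses; `run_pipeline(strata = "sex")` refits the whole
  chain per sex with the sex column dropped from the stratified designs.

## Problem sizes used in the shipped validation

The test suite exercises the estimators at sizes a laptop handles in
minutes, chosen to make the statistical checks sharp rather than to mimic
production scale: quadrature oracles on 4–5 clusters with dense
deterministic grids ($2\times 10^4$ trapezoid points in 1-D, $201^3$
midpoint cells in 3-D); 50-replication recovery studies at 50 clusters × 500
(Part I) and 40 clusters × 400 needers (Part II); interval calibration over
100 simulated datasets of 20 clusters × 300 with $B = 50$ (nominal 90%
coverage checked within three binomial SEs); and an end-to-end check on two
independently generated 18 × 1,950 synthetic populations with $B = 100$
each, comparing pipeline AMEs for the individual-level covariates against
ground-truth AMEs computed by a $10^6$-draw Monte-Carlo oracle *conditional
on each study's realized countries* (fresh individuals assigned to the
drawn country covariates and intercepts). Two design points matter there:
within-country bootstrap intervals deliberately do not propagate
country-level design noise, so neither country-covariate cells nor a
law-level truth — which adds exactly that noise — belong in the coverage
count; and cells within one population share reference-group fluctuations,
so the count pools two populations rather than leaning on a single draw.
Smaller quadrature sizes used inside the replication loops (5 nodes per
dimension, and 3 in the coverage loop) were verified against the default 7
on fixtures first: with adaptive recentring the log-likelihood differences
are below $10^{-5}$ relative.

## Known limitations

Cross-sectional only; no random slopes or crossed effects; no
survey-weighted pseudo-likelihood; no IIA testing or nested-logit
alternative; the multinomial quadrature cost grows as (nodes per
dimension)³, which is why very small node counts are used inside bootstrap
loops; pseudo-$R^2$ values depend on the null's random intercept being kept,
so they are comparable within this package but not across software that
drops it.

## A worked example

```{r example, eval = FALSE}
library(ltchurdle)

pars <- share_like_params()
ct <- generate_country_table(18, seed = 1)
pop <- generate_population(ct, pars, 1950, seed = 2)

sp1 <- binary_mixed_spec(fixed_effects = pars$covariates)
sp2 <- multinomial_mixed_spec(fixed_effects = pars$covariates,
                              quadrature_nodes_per_dim = 5)
fit <- fit_two_part(pop$data, sp1, sp2, need_definition = "iadl1")
fit

amt <- bootstrap_margins(pop$data, sp1, sp2, B = 100, seed = 3,
                         covariates = c("has_partner", "wealth_q5"))
amt

table_one(pop$data, pop$country_table)
```

The same chain, with artifacts written to disk, is one call:
`run_pipeline(run_config(outdir = "run1"))`, or from a shell,
`Rscript inst/cli/ltchurdle.R run --seed 1 --out run1`.
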