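---
title: "Counterfactual modelling of infant antibiotic exposure and pediatric asthma burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual modelling of infant antibiotic exposure and pediatric asthma burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxasthma)
```

## The question

Antibiotic prescribing to infants has fallen sharply in many
jurisdictions since the mid-2000s, driven by antimicrobial stewardship
programs. Because antibiotic exposure in the first year of life disturbs
gut-microbiome maturation and is associated, dose-dependently, with
childhood asthma, part of the concurrent decline in pediatric asthma
incidence is plausibly attributable to that reduced exposure. The
question this package operationalizes is a counterfactual one: *how much
asthma burden — person-years lived with asthma, incident cases,
exacerbations — would a pediatric population have accumulated had infant
antibiotic prescribing not declined?*

Answering it takes four linked pieces, each a module here:

1. **Exposure trend** (`fit_nb_trend`, `build_scenarios`): a smooth model
   of the observed annual prescription rate, from which the factual
   ("base"), no-decline ("flat"), and half-decline ("mid") exposure
   curves are constructed.
2. **Dose-response** (`fit_meta`, `or_at`): a Bayesian random-effects
   meta-regression pooling published study estimates of the association
   between the number of first-year antibiotic courses and childhood
   asthma, on the logit scale.
3. **Microsimulation** (`run_scenario`): an open-population discrete-time
   model that pushes each exposure curve through individual asthma
   natural histories.
4. **Reporting** (`compare`, `age_group_share`, `cost_savings`,
   `render_table2`): excess burden by age group, relative changes, and a
   direct-medical-cost translation.

A synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable end to end without access to
administrative data.

## Exposure trend model

Annual prescription counts $y_{ts}$ for year $t$ and sex $s$ are modeled
as negative binomial with a log link and an offset for the infant
population:

$$\log \mathbb{E}[y_{ts}] = \log(\text{births}_{ts}) + \beta_0 +
\beta_1 (t - 2001) + \beta_2 \mathbb{1}[t > 2005] +
\beta_3 (t - 2001)\,\mathbb{1}[t > 2005] + \beta_4 \text{male}_s .$$

The indicator-plus-interaction form gives distinct log-linear slopes
before and after a stewardship-program breakpoint. Choices worth
spelling out:

* **Centering.** Time is centered at 2001 so the intercept is the log
  rate in the anchor year of the counterfactual ("flat") scenario.
* **Breakpoint boundary.** "After 2005" is implemented as $t > 2005$,
  i.e. 2006 onward; the boundary year itself sits on the pre-break
  slope. Both the breakpoint and the boundary convention are arguments.
* **Offset, not rate regression.** Modelling counts with a
  $\log(\text{births})$ offset is the standard negative binomial
  treatment of a rate and makes the fit invariant to how rows are
  aggregated (exactly so in the Poisson limit; the package exposes
  `dispersion = Inf` for that case, and falls back to it automatically
  when no overdispersion is detectable, as with noise-free synthetic
  input).
* **Fit quality** is summarized as percentage deviance explained,
  $100(1 - D_{res}/D_{null})$, with the null model being intercept plus
  offset at the fitted dispersion. Values near 100 justify substituting
  smoothed rates for raw frequencies in the scenario curves.
* **Intervals.** The 95% bands on the base curve are Wald intervals on
  the linear predictor, exponentiated — the usual delta-method
  construction for GLM rate curves.

`build_scenarios` then defines, per sex and year: base = smoothed rate;
flat = the smoothed 2001 value held constant; mid = the pointwise mean of
the two. The flat and mid curves inherit no interval (they are policy
constructs, not estimates). By construction flat ≥ mid ≥ base pointwise
wherever the base declines after 2001.

## Dose-response meta-regression

Each eligible study contributes logit-scale effect estimates (log odds
ratios versus the zero-prescription reference; hazard ratios are treated
as odds ratios, acceptable at low event prevalence) at dose categories
$d \in \{1, \dots, 5\}$ ("5+" coded 5), for asthma diagnosed at an age
range narrower than 6 years, summarized by its midpoint. Harmonization
recodes reported dose ranges by their lower bound (1–2 → 1, 3–4 → 3) and
filters to original research, first-year exposure, and low risk of bias.

The pooled model for row $i$ of study $j$ is

$$y_{ij} \sim \mathcal{N}\!\left(\beta_0 + u_j + \beta_{age}\,a_{ij} +
\beta_{dose}\,d_{ij},\; se_{ij}^2\right), \qquad
u_j \sim \mathcal{N}(0, \sigma_u^2),$$

with the within-study standard errors treated as known (the classical
meta-analytic approximation). The Canada coefficient is the posterior of
the realized random intercept of the single Canada-flagged study, so the
pooled equation can be evaluated "for Canada" while still borrowing
strength from all studies.

One modelling ambiguity deserves a plain statement. Written as a
prevalence logit, an intercept near 1.7 would imply implausibly high
asthma prevalence at young ages; the only coherent reading is that study
baselines are absorbed into the intercept and study random effects, with
$\beta_{age}$ and $\beta_{dose}$ carrying the transportable structure.
The package therefore exposes two evaluation surfaces and does not
pretend they are the same thing: `or_at()` (the dose odds ratio
$e^{\beta_{dose} d}$, the quantity the simulator consumes) and
`prevalence_logit()` (the literal linear predictor). Relatedly, a visible
attenuation of the dose effect with age cannot be represented by this
linear predictor without an age-by-dose interaction; none is included.
Instead the attenuation is honored by a hard, conservative cutoff: the
dose odds ratio is exactly 1 beyond age 7 (`dose_response()`'s
`max_effect_age`), by which age the per-year ageing odds ratio of about
0.79 has in any case eroded most of the effect.

### Priors, sampling, and diagnostics

Defaults are weakly informative — $\mathcal{N}(0, 10^2)$ on fixed
effects, half-$\mathcal{N}(0, 5^2)$ on $\sigma_u$ — and configurable via
`meta_priors()`. Sampling is by JAGS (two chains by default) with two
internal reparameterizations that matter for mixing with a handful of
studies: covariates are centered, and the hierarchy is centered
($a_j \sim \mathcal{N}(\beta_{0c}, \sigma_u^2)$), with draws transformed
back to the uncentered scale afterwards.

Convergence is gated on *rank-normalized* split-$\hat R$ ≤ 1.01 per
reported parameter, with effective sample sizes attached. The rank
normalization is deliberate: with six studies the posterior of
$\sigma_u^2$ is strongly right-skewed, and raw split-$\hat R$ computed on
the squared draws flags healthy chains on a majority of seeds purely
through tail noise, while the rank-normalized statistic — the current
standard recommendation for exactly this reason — agrees with visual
trace diagnostics. If the gate fails, sampling is re-run with doubled
iterations (up to three attempts) before erroring with the offending
parameters named.

## Microsimulation

The simulator follows an open pediatric population year by year from
2001 to 2018. Each calendar year a birth cohort enters; infants draw a
first-year dose; from age 3 (asthma is not modeled earlier, reflecting
the unreliability of diagnosis under 3) agents face an annual onset
probability, prevalent agents face remission and Poisson exacerbations;
agents age out after 18. Events are attributed to the age attained in
the event year, and tallied in the groups 3–4, 5–9, 10–14, 15–18, with
the overall row an exact per-run sum of the groups.

Mechanics and the reasoning behind them:

* **Dose assignment.** A population rate $r$ per 1,000 becomes a
  per-infant count via a truncated Poisson with mean $r/1000$, capped at
  5 (a negative binomial option exists, with dispersion available from
  the trend fit). Counts are drawn by inverse CDF from a single uniform
  per infant, so a pointwise-larger exposure curve gives every agent a
  dose at least as large — the source of the exact agent-level ordering
  across scenarios.
* **Dose effect.** The meta-regression odds ratio multiplies the *odds*
  of the annual onset probability (`onset_probability`), for ages 3
  through 7 only. This odds-on-onset application is the module's central
  documented approximation: how the original policy platform internally
  converts a prevalence odds ratio into incidence dynamics is its own
  calibrated machinery and is not reproduced here. Consequently absolute
  simulated tallies are not comparable to published absolute numbers;
  within-pipeline contrasts between scenarios are the meaningful output.
* **Order within a year**: onset (for the non-asthmatic), then remission
  (for the previously asthmatic), then person-year counting, then
  exacerbation draws. A new onset therefore always contributes a
  person-year, giving the invariant person-years ≥ incident cases.
* **Common random numbers.** Replicate $r$ uses seed
  `base_seed + r - 1`, and every uniform is drawn for the full live
  population in a fixed order that does not depend on the scenario, so
  paired scenario runs differ only through the exposure curve. Paired
  differences then have far smaller Monte Carlo variance than
  independent runs, and `compare()` uses per-run paired differences for
  its SDs whenever run-level data are attached.
* **Standing population.** Agents aged 1–18 at 2001 are initialized by
  simulating each cohort forward from its third birthday under the
  base-year exposure value (the pre-2001 burn-in records no tallies).
  This gives prevalence at 2001 consistent with the same dynamics used
  afterwards, rather than an ad-hoc seed prevalence.
* **Omissions.** Death and migration are not modeled — pediatric
  mortality is negligible at this scale and no migration parameters are
  available; the cohort structure provides the hook if ever needed. No
  severity states, no under-3 disease, no sex-specific dose effect.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* `trend_truth()`: a continuous piecewise log-linear rate with a 2005
  break — female 2001 rate near 810 per 1,000, slopes −0.02/yr then
  −0.09/yr (about a 70% decline over 2001–2018), a +0.25 log male
  offset (matching males receiving roughly 28% more prescriptions),
  negative binomial dispersion 200, and 21,500 births per sex-year
  (43,000 per year, about 773k births over 18 years).
* `meta_truth()`: six studies, dose slope 0.05, ageing slope −0.23,
  intercept 1.71, between-study variance 0.93, a Canada intercept of
  0.12, and row-level standard errors in (0.05, 0.2) — magnitudes chosen
  to match the pooled-evidence scale on which the dose-response is
  reported.
* `calibration_shape()`: onset peaking at ~3.5%/yr around age 4.5 and
  declining through adolescence, remission rising logistic-wise to ~8%/yr
  in adolescence (so prevalence rises in early childhood and falls in
  adolescence), and exacerbation rates decaying from ~1.2 per
  person-year with asthma at age 3 to ~0.04 at 18 — consistent with the
  roughly 1.2 / 0.3 / 0.08 / 0.04 exacerbations-per-person-year gradient
  across the four reporting age groups in published burden tables.

A single global seed fans out to per-stage substreams through
`substream_seed()`, so any stage can be regenerated independently.

What passing tests on these inputs demonstrate: correct likelihoods and
estimators (parameters are recovered at the stated tolerances), correct
scenario algebra, exact accounting, and correctly ordered counterfactual
contrasts. What they cannot demonstrate: calibration to any real
registry, realistic secular trends in baseline asthma rates (the
calibration tables are age-shaped but time-constant), or the behavior of
the meta-regression under the messier heterogeneity of real study
designs.

## Numerical choices and problem sizes

* Reported rates and percentages round half-up (`round_half_up`), so
  522.5 → 523; shares are reported to one decimal.
* Noise-free trend input drives the estimated dispersion to infinity;
  the fit then switches to the exact Poisson limit rather than chasing a
  divergent dispersion estimate.
* Degenerate designs fail loudly: singular design matrices name the
  collinear columns, data entirely on one side of the breakpoint drop
  the breakpoint terms with a warning, and a single-study meta-table is
  rejected because $\sigma_u$ is unidentifiable.
* The test suite and the acceptance script run the microsimulation at
  `population_scale` 0.02–0.05 with 10–20 replicates, and the coverage
  study refits the meta-regression over 100 seeds — sizes chosen so the
  full validation completes on a laptop-class single core in a few
  minutes while keeping Monte Carlo error well below the contrasts being
  tested.

## Worked desk-scale example

The bundled three-scenario outcome summaries reproduce the headline
arithmetic exactly:

```{r desk}
bc <- bc_outcome_summaries()
cmp <- compare(bc$base, bc$flat)
cmp[cmp$age_group == "overall", c("outcome", "diff")]
age_group_share(cmp, c("3-4", "5-9"), "person_years")
cost_savings(37213, unit_cost = 550)
```

## Known limitations

The dose-response rests on observational studies; despite low
risk-of-bias filters, confounding by indication cannot be excluded by
this package — it propagates whatever causal strength the inputs carry.
The odds-on-onset approximation above means absolute burden levels
should be externally calibrated before being quoted. Exposure is annual
and aggregate: no antibiotic class, seasonality, or individual
prescribing correlates. Costs are a single constant per person-year with
no discounting or inflation adjustment.
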