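---
title: "Methods: a Markov cohort cost-utility and budget impact model of adjuvant trastuzumab"
author: "adjtrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility and budget impact model of adjuvant trastuzumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjtrast)
```

## The decision problem

`adjtrast` models the lifetime costs and health outcomes of adding one year
of adjuvant trastuzumab to standard chemotherapy, versus chemotherapy alone,
for women with HER2-positive early-stage breast cancer in the Philippine
setting. Trastuzumab reduces the hazard of disease recurrence, metastasis
and death while treatment benefit lasts, at a high acquisition cost and with
an increased risk of (largely reversible) cardiotoxicity. The package
quantifies that trade-off as an incremental cost-effectiveness ratio (ICER)
in 2017 Philippine pesos per life-year and per quality-adjusted life-year
(QALY), judged against a willingness-to-pay threshold of PHP 120,000 per
QALY, and projects the five-year fiscal cost of national coverage.

## Model structure

The core is a cohort state-transition (Markov) model over five clinical
states — disease-free survival (DFS), congestive heart failure (CHF), local
recurrence, distant metastasis, death — with annual cycles run for 49 cycles
(cohort entry at age 50, lifetime horizon). Internally the recurrence and
metastasis states are each split into a first-year tunnel sub-state and an
"after first year" state, because the published cost menu distinguishes
first-year work-up/radiotherapy costs from continuing treatment costs; the
tunnels carry no separate clinical meaning and share their parent state's
utility and exit probabilities. The cohort enters in DFS and the trace
records end-of-cycle occupancy.

Transitions are parameterised by annual baseline probabilities
(`default_parameters()` lists all of them with their standard errors and
sampling distributions). The trastuzumab arm differs from the comparator in
three ways:

* while efficacy lasts (cycles 1–11; the duration reflects the longest
  trial follow-up showing a sustained effect), the pooled DFS hazard ratio
  (0.65) scales the DFS→recurrence and DFS→metastasis exits and the pooled
  OS hazard ratio (0.67) the DFS→death exit;
* in the treatment year the CHF entry probability is multiplied by the
  pooled risk ratio 3.97;
* the treatment-course cost (PHP 1,076,607 vs 194,900) is charged once, to
  the entering cohort, at cycle 1.

Hazard ratios are applied through the constant-hazard conversion
`p' = 1 − (1 − p)^HR`, the standard transformation for annual probabilities
under proportional hazards; direct multiplication is available as
`cua_options(hr_method = "multiply")` because the source publication does
not state which was used. CHF is occupied for exactly one cycle: its
residual mass returns to DFS, consistent with trastuzumab cardiotoxicity
being predominantly a reversible decline in ventricular function, and entry
is restricted to the treatment year by default
(`cua_options(chf_entry = "every_cycle")` relaxes this). After the efficacy
window the two arms share identical transition matrices.

No additional background all-cause mortality is layered on top of the
trial-derived transition probabilities: the published parameter table
contains no life-table row, so adding one would introduce numbers the
source analysis does not document. This is a known structural difference
whose direction is to lengthen both arms' survival tails.

## Accounting

Costs and outcomes accrue per cycle as occupancy-weighted sums: direct
medical costs only under the publicly-funded healthcare-system perspective,
plus direct non-medical (food, transport) costs under the societal
perspective. Life-years count all alive states; QALYs weight occupancy by
EQ-5D-3L utilities (DFS 0.832, CHF 0.670, recurrence 0.828, metastasis
0.762). Both costs and outcomes are discounted at 3.5% per year with
first-year flows undiscounted (`discount_factor(t) = 1.035^-(t-1)`); the
alternative exponent-`t` convention is available and, because it rescales
every flow by the same factor, leaves the ICER unchanged. No half-cycle
correction is applied by default, matching a spreadsheet-style end-of-cycle
count; `cua_options(half_cycle = TRUE)` averages start- and end-of-cycle
occupancy instead.

The threshold price (`threshold_price()`) treats the whole trastuzumab-arm
therapy bundle cost as the decision variable and bisects until the
deterministic ICER equals the threshold, verifying the root through a net
monetary benefit of zero within one peso. Because outcomes do not depend on
the course cost, the cohort traces are computed once and the search is
exact and fast.

## Parameter uncertainty

Every uncertain parameter is summarised as mean (SE) and mapped onto the
conventional second-order distribution for its scale: beta for transition
probabilities and utilities (method of moments), gamma for costs (method of
moments), log-normal for hazard/risk ratios. For the ratios only a point
and SE on the ratio scale are published; the default sets the log-scale
location to the log point estimate and transfers the SE by the delta method
(`sigma = se/ratio`), so the sampling *median* equals the published point.
A moment-matched alternative (`lognormal_method = "moments"`) matches the
arithmetic mean and SD instead; the two differ by under 1% for these SEs.

Two published standard errors require interpretation. The CHF utility SE
is printed as 272.71 on a utility of 0.67, which cannot be a utility-scale
SE; the package defaults to 0.0262, the value shared by the other utility
rows, and exposes it as an argument. The SE of the non-medical cost at CHF
is not legible in the source table and is reconstructed as 5% of the mean,
the ratio every other non-medical cost row exhibits (4.6–5.1%); it affects
only the societal perspective and is numerically negligible. The published
cost menu also contains two distinct "recurrence, after first year" cost
pairs; the package defaults to the 182,437/17,817 pair and keeps the
516,904/5,939 pair selectable via `cua_options(rec_later_source =
"alternate")`, since the source does not say which entered the model.

The probabilistic sensitivity analysis (`run_psa()`, 50,000 replications by
default, seed 2019) draws every parameter independently, rejects and
redraws any parameter set whose state-exit probabilities would sum above
one (the count is reported; at the published SEs this affects well under
0.1% of draws and preserves the marginal distributions better than
renormalising), runs both arms per draw, and records incremental costs and
outcomes under both perspectives. The acceptability curve reports, per
threshold, the fraction of draws with positive net monetary benefit.
Because the recurrence→death and metastasis→death probabilities carry very
wide betas (mean 0.295, SE 0.2066, implying shape parameters near 1), the
model is markedly nonlinear in them and Monte-Carlo means of increments
differ visibly from the deterministic run at the means — the probabilistic
and deterministic base cases are therefore both exposed, and the
probabilistic one is the headline, matching the source's own reporting
convention.

One-way sensitivity (`one_way_sa()`) varies each parameter over its
normal-approximation 95% interval clipped to validity (the source prints
ranges only for the discount rate, 0–6%, and the efficacy duration, 5–49
years, which are both included); results confirm the ICER is driven by the
DFS hazard ratio, efficacy duration, discounting and the trastuzumab course
cost, and is insensitive to state costs and utilities. The two-way grid
over the DFS hazard ratio and efficacy duration finds chemotherapy
cost-effective at PHP 120,000/QALY everywhere except the extreme corner
(hazard ratio at the lower confidence edge combined with near-lifetime
efficacy). A `structural_sweep()` reruns the deterministic ICER under all
16 combinations of the flagged structural alternatives.

## Budget impact

The eligible population applies the national HER2-positivity (23.17%) and
early-stage (80%) fractions to prevalent (64,046) and incident (21,057)
breast-cancer cases, rounded to whole persons: 11,872 prevalent plus 3,903
incident cases per year, with the incident cohort held constant over the
five fiscal years (no growth rate is published). Year 1 treats the full
prevalent pool plus that year's incident cases at the course cost; each
later year treats a new incident cohort, while every previously treated
cohort accrues follow-up costs read off its arm's undiscounted cohort-trace
state costs aged by years since treatment (direct medical costs only,
consistent with a governmental budget holder). All budget streams are
undiscounted. The decomposition of later-year follow-up is a documented
reconstruction: the source prints year-1 totals exactly and later years
only as rounded bands.

## Synthetic parameter tables

`random_parameter_table()` generates structurally valid tables for
property testing: progression probabilities are drawn on bounded scales and
rescaled so that every state's worst-case exit sum (risk-ratio-inflated CHF
entry, hazard ratios above one applied through the rate conversion, which
is bounded by `HR * p`) stays below 0.95, SEs are drawn as a bounded
fraction of the mean and capped below the beta feasibility limit, and
epidemiology inputs stay fixed. These tables exercise the engine far
outside the published parameter neighbourhood — utilities down to 0.3,
exit probabilities up to 0.4 — but they are not calibrated to any disease;
passing them demonstrates conservation, row-stochasticity and accounting
identities, not clinical realism. `perturb_parameters()` jitters a table
multiplicatively and restores feasibility, for robustness checks around
the published values.

## Problem sizes and numerical choices

The default test and analysis configuration uses the full published run
sizes: 49 cycles, 50,000 PSA replications, 1,000 random tables for the
conservation property. Row sums of every transition matrix are exact by
construction and asserted to 1e-12; trace conservation is asserted to
1e-10; the threshold-price bisection stops at one peso. Ties in the
two-way analysis (net monetary benefit exactly zero) are labelled
chemotherapy, the incumbent. Degenerate inputs are handled explicitly:
zero SEs collapse distributions to fixed points (making the PSA reproduce
the deterministic run bit-for-bit), a certain transition (`p = 1`) rejects
any non-unit hazard ratio, and infeasible exit sums raise errors naming
the offending state or parameter.

## Known limitations

* The source under-specifies several structural choices (hazard-ratio
  application, CHF timing, counting convention, half-cycle, which
  recurrence cost row). The defaults documented here reproduce the
  published ICERs to within roughly 10–15%, and the structural sweep shows
  configurations closer than 10%; exact replication of the original
  spreadsheet is not claimed.
* The model inherits the source's assumptions: no baseline comorbidity, no
  hormonal therapy, no background mortality beyond the trial-derived
  probabilities, CHF experienced at most once.
* Budget-impact follow-up decomposition beyond year 1 is a reconstruction
  (see above).

## A worked run

```{r, eval = FALSE}
fit <- cua_model()                 # deterministic base case, both perspectives
summary(fit)
psa <- simulate(fit, nsim = 50000, seed = 2019)
summary(psa)                       # probabilistic base case
ceac(psa, thresholds = 120000)     # acceptability at the threshold
threshold_price(default_parameters())
budget_impact(default_parameters())
```
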