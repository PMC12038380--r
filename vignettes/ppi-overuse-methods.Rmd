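---
title: "Methods: recurrent-event analysis of PPI overuse after peptic ulcer disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent-event analysis of PPI overuse after peptic ulcer disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppioveruse)
```

## The problem

Proton pump inhibitors (PPIs) are approved for at most 8 weeks of treatment
after an acute peptic ulcer disease (PUD) diagnosis, yet prescriptions are
frequently renewed long past that point. Quantifying *which* patient,
provider, and facility factors drive these renewals — and how much of the
health-system burden each factor accounts for — requires three things: a
carefully constructed new-user cohort, an outcome definition at the level of
the individual prescription fill, and a recurrent-event model, because a
patient can receive many fills that extend treatment beyond the approved
duration.

`ppioveruse` implements that pipeline end to end. Because the health-system
records such analyses are run on are not public, the package also ships a
seeded synthetic EHR generator with the statistical structure the analysis
assumes, so every downstream stage is testable and the whole analysis is
reproducible from nothing.

## The synthetic EHR generator

`simulate_ehr()` draws, per patient:

* baseline factors (inpatient diagnosis, race, sex, any extra configured
  indicator) as independent Bernoulli draws at configured prevalences, and a
  five-level frailty category;
* co-medication treatment episodes (NSAIDs, aspirin, anticoagulants,
  antiplatelets, H2-receptor antagonists) as stationary Poisson processes of
  episodes with class-specific rates and durations. Episode starts are drawn
  on `[-duration, horizon)` so exposure prevalence is already at steady state
  on the index day — a deliberate deviation from "nothing before index":
  patients genuinely enter such cohorts already on aspirin or warfarin, and
  an all-unexposed start would distort early time-varying estimates;
* PPI fills from a multiplicative-intensity counting process
  $\lambda_i(t) = \lambda_0 \exp\{\beta^\top Z_i(t)\}$, realized by thinning a
  homogeneous Poisson process at the patient's maximal intensity. The initial
  qualifying 30-day course within 14 days of index is always dispensed;
* censoring-type events (a new chronic PPI indication, gastrointestinal
  bleeding) at exponential rates, an *H. pylori* diagnosis shortly after
  index for a configured fraction, and occasional follow-up endoscopies.

Two generator choices matter for interpreting test results. First, the
*generative* time-varying covariate is defined as the same
days-supply-plus-grace exposure indicator the analysis later reconstructs
from fills, so there is no exposure misclassification by construction;
recovery tests therefore demonstrate correctness of the estimation machinery,
not robustness to mismeasured exposure. Second, the intensity model contains
no patient-level random effect (frailty terms are out of scope), so the
generator cannot reproduce the overdispersed joint pattern seen in real
cohorts where a minority of patients accumulates long runs of fills: with the
default baseline intensity of 0.001 fills/day (about 1.2 exceeding fills per
patient over three years) the simulated *proportion* of patients with any
exceeding fill is higher, and the per-patient counts lower-variance, than in
real prescribing data. Descriptive outputs of simulated runs should be read
with that in mind; hazard-ratio recovery is unaffected.

Defaults encode the emulated study conditions: cohorts of 2000 patients
followed 3 years, 18% inpatient diagnoses, 18% Black race, 7% female,
frailty 24/43/22/8/3%, and true fill-intensity hazard ratios of 1.32
(inpatient), 0.83 (Black race), 0.91 (female), 1.06/1.11/1.15/1.08 (frailty
levels), 1.26 (NSAIDs), 1.25 (anticoagulants), 1.15 (aspirin). Identical
seeds give bit-identical tables.

## Cohort eligibility

`build_cohort()` applies, per patient and in a fixed order: earliest acute
PUD diagnosis as index; an upper endoscopy required within ±30 days of index
(the confirmation window is unspecified in source descriptions of such
cohorts, so it is a config knob); no prior chronic/unspecified PUD; no prior
PPI-indication condition over all available history; no PPI fill in the
closed washout interval `[index − 365, index − 14]`; and a PPI fill within
`[index, index + 14]`. The first failing rule is recorded, `attrition_table()`
reports counts in rule order, and eligibility is a pure function of one
patient's records (tested by permutation invariance).

## Classifying fills

A fill *exceeds* the approved duration when `fill day + days supply` passes
60 days after index — 8 weeks rounded up to the 30-day increments US
prescriptions are written in. Backstock from earlier fills is ignored by
construction, so a fill's class never depends on other fills. Exceptions:

* **H. pylori**: supply ending at or before `first H. pylori diagnosis + 60`
  is approved (inclusive at the boundary; only the first diagnosis counts).
  The threshold comparison at day 60 itself is strict: a supply ending
  exactly on day 60 is approved.
* **Gastroprotection (secondary analysis)**: six guideline rules, each active
  from January 1 of the year after its introduction, evaluated against the
  patient's age, active drug classes (supply + 30-day grace, half-open
  intervals), and history flags. Qualification both reclassifies fills toward
  approved and censors follow-up at the first qualifying moment. One emergent
  consequence: after 2010, any NSAID-exposed moment qualifies (post-index PUD
  history is automatic), so in cohorts indexed wholly after 2010 the NSAID
  covariate carries no variation under guideline censoring — the secondary
  NSAID effect is only estimable through pre-2010 person-time.

## Counting-process construction

Follow-up runs over `(0, censor]` with censoring at the earliest of: first
new PPI-indication diagnosis, the administrative cap (1095 days; 1825 in the
five-year sensitivity), the 2013-08-01 regional deprescribing cutoff for
network-17 patients, end of data, and (secondary analysis) first guideline
qualification. Ties resolve clinically — the administrative cap loses.

`build_intervals()` cuts each patient's follow-up at every exceeding-fill
date (event rows), every exposure change, and the censoring time. Intervals
are half-open `(start, stop]` with events at `stop`; the event time is the
*fill date* of the exceeding prescription, not the day its supply crosses day
60, matching the outcome definition "the fill dates ... were the outcomes".
Same-day conventions are deterministic: multiple exceeding fills on one day
collapse to one event; when an exposure changes on an event day the
pre-change value is in force (changes apply from the next interval); an
exceeding fill on the index day itself sits at day 0.5 so its interval is
well formed. Refining the partition at arbitrary extra cutpoints provably
leaves the partial likelihood unchanged, and the tests assert exactly that.

## The Andersen-Gill fitter

`ag_fit()` maximizes the counting-process Cox partial likelihood with
**Breslow** tie handling — the standard choice for recurrent-event data,
where ties are artifacts of day-resolution dates. Risk sets
$\{i: \text{start}_i < t \le \text{stop}_i\}$ are swept with sorted
cumulative sums rather than per-event scans, which is what makes
200-replicate calibration studies affordable in pure R. Covariates are
standardized internally for conditioning and back-transformed for reporting.

Newton-Raphson with step-halving stops on the gradient sup-norm
(`tol_grad = 1e-9`); a stalled log-likelihood only counts as convergence once
the gradient is below 1e-6, because on cohort-scale data the log-likelihood
(magnitude ~10^4) reaches its floating-point noise floor one iteration before
the gradient does. Every returned fit has gradient sup-norm below 1e-6;
anything else is an explicit error with diagnostics, and coefficients beyond
±15 on the standardized scale raise a separation warning.

Variance is the cluster-robust sandwich $I^{-1}(\sum_g U_g U_g^\top)I^{-1}$
with score residuals aggregated within patients, which is what makes the
intervals honest when one patient contributes several events; naive inverse
information is kept for diagnostics. On counting-process data the fitter
agrees with `survival::coxph(..., ties = "breslow", cluster(id))` to ~1e-14
in coefficients and both standard errors — `coxph` serves as the independent
oracle in the test suite, never as the implementation.

`ag_select()` provides a conventional, auditable default for the
"parsimonious final model": backward elimination on robust Wald p-values at
α = 0.05, with the elimination path logged. The true selection procedure used
on the original data is not published, so this is a declared replaceable
default, not an inference about it.

## The attributable-fraction curve

For a factor with reference level 0, the adjusted time-to-event population
attributable fraction is

$$\mathrm{PAF}(t) = 1 - \frac{\bar F_0(t)}{\bar F(t)}, \qquad
\bar F(t) = \frac1n \sum_i g\{\Lambda_i(t)\},$$

where $\Lambda_i(t)$ accumulates $\exp\{\beta^\top Z_i(s)\}\,d\Lambda_0(s)$
piecewise over the patient's observed covariate intervals (the Breslow
baseline supplies $\Lambda_0$), and $\bar F_0$ repeats the standardization
with the factor forced to its reference level everywhere. The published
analyses cite an external method without printing formulas, so two declared
variants are implemented: `cumulative_incidence`, $g(x) = 1 - e^{-x}$, the
probability of at least one exceeding fill by $t$ (default — its
rise-then-fall shape is what peaked attributable-fraction curves over
follow-up look like, since exposed and unexposed incidences both saturate);
and `expected_events`, $g(x) = x$, which with fixed covariates is constant in
$t$ and equals $1 - \sum e^{\beta^\top Z_i^0} / \sum e^{\beta^\top Z_i}$.
Where $\bar F(t) = 0$ (before the first event time) the fraction is
undefined and reported as `NA`, never as 0. Against the closed-form
exponential oracle (binary factor, prevalence 0.5, hazard ratio 2) the
implementation agrees to 1e-6, with the small-$t$ limit
$p(r-1)/\{1 + p(r-1)\} = 1/3$.

Uncertainty comes from a patient-resampling bootstrap: resample patients with
replacement, refit, recompute the curve, take percentile 2.5/97.5 bands.
Replicates that fail to fit (e.g., no events) are dropped and counted, with a
warning past 5%. Standardization extends each patient's last observed
covariate values across the grid, so the standardization population is the
analytic cohort with exposures held at their observed paths.

## Sensitivity analyses

Four variants mirror the study design probes: `followup_5y` (cap 1825 days),
`post_endoscopy_60d_approved` (fills within 60 days after a follow-up
endoscopy approved), `restrict_2010_plus` (drop pre-2010 index dates), and
`frailty_recomputed` (swap in the `frailty_alt` column, representing a
frailty index computed without cardiovascular anticoagulant/antiplatelet
indications — the index internals are out of scope, so the alternative
arrives precomputed). The secondary gastroprotection analysis is a flag, not
a code path: the rule set lives in configuration.

## Problem sizes and what the tests show

The recovery experiment fits 20 seeded replicates of n = 2000 patients over
a 3-year horizon (~2300 events each) and checks that mean estimated hazard
ratios sit within ±0.05 of the generative values (±0.07 for the 8%-prevalence
frailty level) with pooled robust-CI coverage between 0.90 and 0.99 — with 20
replicates per factor, per-factor coverage has granularity 0.05, so coverage
is pooled over the five tracked factors. Null calibration uses 200 replicates
at n = 1000 with a 50%-prevalence inert covariate, expecting 5% ± 2.5% Wald
rejections. These sizes were chosen so the Monte-Carlo error of each check is
several times smaller than its tolerance. Because the generator and the
analysis share exposure conventions, passing recovery says nothing about
robustness to misclassified exposure or to informative censoring; neither is
claimed.

## Known limitations

* Condition classes arrive pre-mapped; no ICD vocabularies.
* No patient-level frailty term in either the generator or the model, hence
  no claim about the real joint distribution of per-patient fill counts.
* Age is fixed at its index value when rules compare it to 65.
* Death is not modeled separately; end-of-data acts as administrative
  censoring.
* The PAF variants are declared assumptions about an estimator whose source
  formulas are unavailable; both are exposed so the choice is visible.
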