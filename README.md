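# ppioveruse

Proton pump inhibitors (PPIs) are approved for at most 8 weeks of treatment
after an acute peptic ulcer disease (PUD) diagnosis, yet renewals routinely
extend therapy for months or years. `ppioveruse` is an R package for
quantifying that overuse and what drives it: it builds a new-user PUD cohort
from longitudinal records, classifies every PPI fill against the approved
duration (with the *H. pylori* exception and calendar-activated
gastroprotection guideline criteria), and models the recurrent
exceeding-fill process. It is aimed at pharmacoepidemiologists working with
claims/EHR-style tables — and, because such data are not public, it includes
a seeded synthetic EHR generator so the full analysis is reproducible from
nothing.

## The model

Exceeding fills are recurrent events. The package fits the Andersen–Gill
multiplicative-intensity model on counting-process data
`(start, stop], event, Z(t)`:

```
lambda_i(t) = lambda_0(t) * exp(beta' Z_i(t))
```

by Cox partial likelihood (Breslow ties, Newton–Raphson), with the Breslow
baseline cumulative intensity and a cluster-robust sandwich variance
(score residuals aggregated within patients) for honest intervals under
within-patient event correlation. Adjusted hazard ratios are `exp(beta)`.

Health-system impact is summarized by the adjusted time-to-event population
attributable fraction,

```
PAF(t) = 1 - Fbar_0(t) / Fbar(t),   Fbar(t) = mean_i g(Lambda_i(t))
```

where `Lambda_i(t)` accumulates the fitted intensity over patient `i`'s
observed (time-varying) covariate path and `Fbar_0` repeats the
standardization with the factor forced to its reference level; `g(x) =
1 - exp(-x)` (probability of any exceeding fill, default) or `g(x) = x`
(expected count). Percentile bootstrap bands come from resampling patients.

## Worked example

Simulate a 2000-patient cohort under the default study conditions (with 5%
deliberately ineligible patients so the attrition report has content), run
the full pipeline, and inspect the results:

```r
library(ppioveruse)

cfg <- run_config(sim = sim_config(ineligible_fraction = 0.05), seed = 20)
b <- run_pipeline(cfg)

b
#> PPI overuse pipeline bundle (primary analysis, sensitivity: none)
#>   analytic cohort: 2000 patients; 1384 (69%) with exceeding fills
#>   counting process: 14447 rows, 2163 events

b$attrition
#>                step    n
#> 1          assessed 2100
#> 2      no_endoscopy   20
#> 3 prior_chronic_pud   20
#> 4  prior_indication   20
#> 5 prior_ppi_washout   20
#> 6    no_initial_ppi   20
#> 7          eligible 2000

b$fit
#> Andersen-Gill recurrent-event model: 2163 events, 1959 patients, 14447 rows
#> partial loglik -16189.9425 (null -16215.1062), 4 Newton iterations, |grad| 6.4e-14
#>            factor   ahr          ci            p
#>         inpatient 1.258 1.134-1.395 1.362151e-05
#>            female 0.880 0.749-1.034 1.199656e-01
#>             black 0.890 0.803-0.987 2.760658e-02
#>  frailty_prefrail 1.039 0.933-1.158 4.831750e-01
#>      frailty_mild 1.078 0.952-1.221 2.346357e-01
#>  frailty_moderate 1.230 1.040-1.455 1.564877e-02
#>    frailty_severe 0.925 0.692-1.237 6.002725e-01
#>             nsaid 1.230 1.096-1.381 4.534075e-04
#>     anticoagulant 1.175 1.022-1.351 2.333820e-02
#>           aspirin 1.075 0.970-1.190 1.668926e-01

paf_peak(b$paf$inpatient)
#> $time
#> [1] 9
#>
#> $value
#> [1] 0.04049254
```

Reading it: in this simulated cohort an inpatient index diagnosis carries an
adjusted hazard ratio of 1.26 (95% CI 1.13–1.40) for receiving a PPI fill
that extends treatment past the approved duration (the generative value is
1.32; single-replicate estimates scatter around it), active NSAID exposure
1.23, anticoagulants 1.18, while Black race is inversely associated (0.89).
The inpatient attributable-fraction curve peaks early: about 4% of patients
with an exceeding fill by day 9 would not have one if inpatient-diagnosed
patients were treated like outpatient-diagnosed ones.

One replicate is noisy by design; the package's acceptance machinery (below)
averages 20 seeded replicates, where the recovered hazard ratios land within
a few hundredths of the generative values.

A secondary analysis applying the gastroprotection guidelines is a flag
(`run_config(analysis = "gastroprotection")`), as are the four sensitivity
variants (`followup_5y`, `post_endoscopy_60d_approved`, `restrict_2010_plus`,
`frailty_recomputed`). A thin command-line wrapper lives at
`inst/scripts/ppi-pipeline.R` (`simulate` and `run-all` subcommands), and
simulation settings can come from a YAML file (see
`inst/extdata/demo_sim_config.yaml` and `read_sim_config()`).

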