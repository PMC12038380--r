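Package: ppioveruse
Title: Recurrent-Event Analysis of Proton Pump Inhibitor Overuse After Peptic Ulcer Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying proton pump inhibitor (PPI)
    prescriptions that extend treatment beyond the approved 8-week duration for
    peptic ulcer disease (PUD). Includes a seeded synthetic electronic-health-record
    generator with covariate-dependent recurrent prescription-fill intensities and
    time-varying co-medication episodes; new-user cohort eligibility with washout
    and endoscopy-confirmation rules and an attrition report; a prescription-duration
    rule engine with the H. pylori exception and calendar-activated gastroprotection
    guideline criteria; construction of Andersen-Gill counting-process data with
    time-varying drug exposures and multi-cause censoring; a Cox partial-likelihood
    fitter for the recurrent-event intensity model with Breslow baseline and
    cluster-robust (sandwich) variance; and adjusted time-to-event population
    attributable fraction curves with patient-resampling bootstrap intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), survival, jsonlite, ggplot2, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
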