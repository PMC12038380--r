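# Hand-built 12-patient fixture with known attrition and classification
# counts, exercising both washout boundaries, the H. pylori exception
# boundary, and every exclusion rule. Index day 4000 (study start 1999-01-01)
# for all patients except P11, whose first acute PUD diagnosis is day 4100.
golden_tables <- function() {
  idx <- 4000L
  pat <- data.frame(
    patient_id = 1:12, age = 70L, female = 0L, black = 0L,
    frailty = "nonfrail", frailty_alt = "nonfrail", charlson = 2L,
    facility = 1L, visn = 1L, index_day = idx, stringsAsFactors = FALSE
  )
  pat$index_day[11] <- 4100L

  dg <- function(id, day, condition, inpatient = 0L) {
    data.frame(patient_id = id, day = day, condition = condition,
               inpatient = inpatient, stringsAsFactors = FALSE)
  }
  diagnoses <- rbind(
    dg(c(1:8, 10, 12), idx, "acute_pud"),
    dg(10, idx, "acute_pud", 1L),           # P10: inpatient index diagnosis
    dg(11, c(4100L, 4300L), "acute_pud"),   # P11: earliest wins
    dg(9, idx, "chronic_pud"),              # P9: no acute PUD -> not emitted
    dg(6, idx - 300L, "chronic_pud"),
    dg(7, idx - 400L, "ppi_indication")
  )

  ts <- function(id, day, test, result) {
    data.frame(patient_id = id, day = day, test = test, result = result,
               stringsAsFactors = FALSE)
  }
  tests <- rbind(
    ts(setdiff(1:10, c(5, 9)), idx, "endoscopy", "performed"),  # P5: none
    ts(12, idx, "endoscopy", "performed"),
    ts(11, 4100L, "endoscopy", "performed"),
    ts(2, idx + 40L, "h_pylori", "positive")
  )

  fl <- function(id, day, supply) {
    data.frame(patient_id = id, drug_class = "ppi", day = day,
               days_supply = supply, prescriber_type = "primary_care",
               stringsAsFactors = FALSE)
  }
  fills <- rbind(
    fl(1, idx, 30L), fl(1, idx + 45L, 30L),              # exceeds (end 75)
    fl(2, idx, 30L),
    fl(2, idx + 50L, 30L),                               # end 80 <= hp+60
    fl(2, idx + 70L, 30L),                               # end 100 == hp+60
    fl(3, idx - 14L, 30L), fl(3, idx + 1L, 30L),         # washout boundary in
    fl(4, idx - 10L, 30L), fl(4, idx + 3L, 30L),         # washout boundary out
    fl(5, idx, 30L),
    fl(6, idx, 30L),
    fl(7, idx, 30L),
    # P8: no fills -> no_initial_ppi
    fl(10, idx, 30L),
    fl(11, 4100L, 30L), fl(11, 4190L, 60L),              # exceeds (end rel 150)
    fl(12, idx - 365L, 30L), fl(12, idx + 2L, 30L)       # washout far boundary
  )

  list(patients = pat, diagnoses = diagnoses, fills = fills, tests = tests)
}

golden_attrition <- data.frame(
  step = c("assessed", "no_endoscopy", "prior_chronic_pud", "prior_indication",
           "prior_ppi_washout", "no_initial_ppi", "eligible"),
  n = c(11L, 1L, 1L, 1L, 2L, 1L, 5L),
  stringsAsFactors = FALSE
)

golden_reason_counts <- c(exceeds = 2L, hp_exception = 2L, within_60d = 5L)

# minimal single-patient tables for classification / interval unit tests
one_patient_tables <- function(ppi_fills, index_day = 1000L, extra_fills = NULL,
                               hp_day = NULL, diagnoses_extra = NULL,
                               visn = 1L, age = 70L) {
  pat <- data.frame(patient_id = 1L, age = age, female = 0L, black = 0L,
                    frailty = "nonfrail", frailty_alt = "nonfrail",
                    charlson = 2L, facility = 1L, visn = visn,
                    index_day = index_day, stringsAsFactors = FALSE)
  diagnoses <- data.frame(patient_id = 1L, day = index_day,
                          condition = "acute_pud", inpatient = 0L,
                          stringsAsFactors = FALSE)
  if (!is.null(diagnoses_extra)) diagnoses <- rbind(diagnoses, diagnoses_extra)
  tests <- data.frame(patient_id = 1L, day = index_day, test = "endoscopy",
                      result = "performed", stringsAsFactors = FALSE)
  if (!is.null(hp_day)) {
    tests <- rbind(tests, data.frame(patient_id = 1L, day = hp_day,
                                     test = "h_pylori", result = "positive",
                                     stringsAsFactors = FALSE))
  }
  fills <- ppi_fills
  if (!is.null(extra_fills)) fills <- rbind(fills, extra_fills)
  list(patients = pat, diagnoses = diagnoses, fills = fills, tests = tests)
}

ppi_fill <- function(day, supply, id = 1L, prescriber = "primary_care") {
  data.frame(patient_id = id, drug_class = "ppi", day = as.integer(day),
             days_supply = as.integer(supply), prescriber_type = prescriber,
             stringsAsFactors = FALSE)
}

med_fill <- function(day, supply, class, id = 1L) {
  data.frame(patient_id = id, drug_class = class, day = as.integer(day),
             days_supply = as.integer(supply), prescriber_type = "primary_care",
             stringsAsFactors = FALSE)
}

# run the data stages (cohort -> classify -> censor -> intervals) in one go
run_stages <- function(tables, covariates = "inpatient",
                       med_classes = character(0), gastroprotection = FALSE,
                       plan = censor_plan(), grace_days = 30) {
  cohort <- build_cohort(tables)
  classified <- classify_fills(tables$fills, cohort, tables,
                               gastroprotection = gastroprotection,
                               grace_days = grace_days)
  censor <- censor_times(cohort, tables, plan, grace_days = grace_days)
  intervals <- build_intervals(cohort, classified, tables, censor,
                               covariates = covariates,
                               med_classes = med_classes,
                               grace_days = grace_days)
  list(cohort = cohort, classified = classified, censor = censor,
       intervals = intervals)
}
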