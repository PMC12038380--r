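#' Cohort eligibility configuration
#'
#' @param endoscopy_window_days window (± days around index) within which an
#'   upper endoscopy confirms the index diagnosis; default 30.
#' @param washout_days closed pre-index interval, in days before index, in
#'   which any PPI fill excludes the patient; default `c(365, 14)`.
#' @param initial_fill_days the index PPI course must be filled within this
#'   many days of index (inclusive); default 14.
#' @param gi_bleed_window_days window (± days) for flagging a GI bleed as
#'   associated with the index diagnosis; default 7.
#' @param condition_classes named list mapping the roles `acute_pud`,
#'   `chronic_pud`, `ppi_indication`, `gi_bleed` to vectors of condition
#'   labels as they appear in the diagnoses table.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(endoscopy_window_days = 30,
                          washout_days = c(365, 14),
                          initial_fill_days = 14,
                          gi_bleed_window_days = 7,
                          condition_classes = list(
                            acute_pud = "acute_pud",
                            chronic_pud = c("chronic_pud", "unspecified_pud"),
                            ppi_indication = "ppi_indication",
                            gi_bleed = "gi_bleed"
                          )) {
  structure(list(endoscopy_window_days = endoscopy_window_days,
                 washout_days = washout_days,
                 initial_fill_days = initial_fill_days,
                 gi_bleed_window_days = gi_bleed_window_days,
                 condition_classes = condition_classes),
            class = "cohort_config")
}

# fixed evaluation order of the exclusion rules; attrition reports follow it
exclusion_order <- c("no_endoscopy", "prior_chronic_pud", "prior_indication",
                     "prior_ppi_washout", "no_initial_ppi")

#' Find the index acute PUD diagnosis per patient
#'
#' The earliest acute PUD diagnosis is the cohort entry date; patients with no
#' acute PUD event are not emitted. The inpatient flag is taken from the index
#' event (any inpatient diagnosis on the index day counts).
#'
#' @param diagnoses the diagnoses table.
#' @param config a [cohort_config()].
#' @return draft cohort data.frame: `patient_id`, `index_day`,
#'   `inpatient_index`.
#' @export
find_index <- function(diagnoses, config = cohort_config()) {
  acute <- diagnoses[diagnoses$condition %in% config$condition_classes$acute_pud, ,
                     drop = FALSE]
  if (!nrow(acute)) {
    return(data.frame(patient_id = integer(), index_day = integer(),
                      inpatient_index = logical()))
  }
  idx <- tapply(acute$day, acute$patient_id, min)
  draft <- data.frame(patient_id = as.integer(names(idx)), index_day = as.integer(idx))
  key <- paste(acute$patient_id, acute$day)
  at_index <- acute[key %in% paste(draft$patient_id, draft$index_day), , drop = FALSE]
  inp <- tapply(at_index$inpatient, at_index$patient_id, max)
  draft$inpatient_index <- as.integer(inp[as.character(draft$patient_id)]) == 1L
  draft[order(draft$patient_id), , drop = FALSE]
}

#' Apply the eligibility exclusions
#'
#' Exclusions are evaluated per patient in a fixed order, and the first
#' failing rule is recorded: (1) no upper endoscopy within the confirmation
#' window around index; (2) any chronic/unspecified PUD diagnosis before
#' index; (3) any other PPI-indication diagnosis before index (all available
#' history); (4) any PPI fill in the washout interval `[index - 365,
#' index - 14]`, closed on both ends; (5) no PPI fill within 14 days after
#' index (inclusive). Eligibility is a pure function of one patient's records.
#'
#' @param draft output of [find_index()].
#' @param tables the `ehr_tables` list.
#' @param config a [cohort_config()].
#' @return cohort data.frame adding `gi_bleed_at_index`, `age`, `visn`,
#'   `eligible`, `exclusion_reason` (NA when eligible).
#' @export
apply_exclusions <- function(draft, tables, config = cohort_config()) {
  cc <- config$condition_classes
  d <- tables$diagnoses
  f <- tables$fills
  te <- tables$tests
  n <- nrow(draft)
  pid <- draft$patient_id
  idx <- draft$index_day

  has_in_window <- function(sub_id, sub_day, lo, hi) {
    # any record per patient with day in [lo, hi] (patient-aligned bounds)
    m <- match(sub_id, pid)
    keep <- !is.na(m) & sub_day >= lo[m] & sub_day <= hi[m]
    pid %in% sub_id[keep]
  }

  endo <- te[te$test == "endoscopy", , drop = FALSE]
  w <- config$endoscopy_window_days
  ok_endo <- has_in_window(endo$patient_id, endo$day, idx - w, idx + w)

  chronic <- d[d$condition %in% cc$chronic_pud, , drop = FALSE]
  prior_chronic <- has_in_window(chronic$patient_id, chronic$day, rep(-Inf, n), idx - 1L)

  indic <- d[d$condition %in% cc$ppi_indication, , drop = FALSE]
  prior_indic <- has_in_window(indic$patient_id, indic$day, rep(-Inf, n), idx - 1L)

  ppi <- f[f$drug_class == "ppi", , drop = FALSE]
  washout <- has_in_window(ppi$patient_id, ppi$day,
                           idx - config$washout_days[1L], idx - config$washout_days[2L])
  initial <- has_in_window(ppi$patient_id, ppi$day, idx, idx + config$initial_fill_days)

  reason <- rep(NA_character_, n)
  fail <- cbind(no_endoscopy = !ok_endo,
                prior_chronic_pud = prior_chronic,
                prior_indication = prior_indic,
                prior_ppi_washout = washout,
                no_initial_ppi = !initial)[, exclusion_order, drop = FALSE]
  first_fail <- apply(fail, 1L, function(r) if (any(r)) exclusion_order[which(r)[1L]] else NA_character_)
  reason <- first_fail

  gib <- d[d$condition %in% cc$gi_bleed, , drop = FALSE]
  gw <- config$gi_bleed_window_days
  gi_at_index <- has_in_window(gib$patient_id, gib$day, idx - gw, idx + gw)

  out <- draft
  out$gi_bleed_at_index <- gi_at_index
  pm <- match(pid, tables$patients$patient_id)
  out$age <- tables$patients$age[pm]
  out$visn <- tables$patients$visn[pm]
  out$eligible <- is.na(reason)
  out$exclusion_reason <- reason
  out
}

#' Build the analytic cohort
#'
#' Convenience wrapper: [find_index()] then [apply_exclusions()].
#'
#' @param tables an `ehr_tables` list.
#' @param config a [cohort_config()].
#' @return the cohort data.frame.
#' @export
build_cohort <- function(tables, config = cohort_config()) {
  apply_exclusions(find_index(tables$diagnoses, config), tables, config)
}

#' Attrition table
#'
#' Counts patients assessed, excluded at each rule (first-failing, in rule
#' order) and finally eligible. Counts are invariant to input ordering and sum
#' to the number assessed.
#'
#' @param cohort output of [build_cohort()].
#' @return data.frame with `step` and `n`.
#' @export
attrition_table <- function(cohort) {
  steps <- c("assessed", exclusion_order, "eligible")
  n <- c(nrow(cohort),
         vapply(exclusion_order,
                function(r) sum(!is.na(cohort$exclusion_reason) & cohort$exclusion_reason == r),
                1L),
         sum(cohort$eligible))
  data.frame(step = steps, n = as.integer(n), row.names = NULL)
}
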