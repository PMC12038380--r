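#' Descriptive summary of PPI overuse
#'
#' Per-patient and cohort-level descriptives of fills exceeding the approved
#' duration: whether any exceeding fill occurred, how many, days of excess
#' exposure, and the prescriber-type mix of exceeding fills. Excess exposure
#' defaults to the total days supply dispensed across exceeding fills; the
#' alternative counts distinct covered days after day 60 post-index (merged
#' across fills, so overlapping supplies are not double counted).
#'
#' @param cohort cohort records (eligible rows are summarized).
#' @param classified classified fills from [classify_fills()].
#' @param excess_mode `"supply_days"` (default) or `"covered_after_60"`.
#' @param threshold_days approved-duration threshold used for the covered-day
#'   alternative, default 60.
#' @return `list(patient = per-patient data.frame, summary = one-row
#'   data.frame, prescribers = prescriber proportions of exceeding fills)`.
#'   Medians and IQRs are `NA` when no patient has an exceeding fill.
#' @export
describe_overuse <- function(cohort, classified,
                             excess_mode = c("supply_days", "covered_after_60"),
                             threshold_days = 60) {
  excess_mode <- match.arg(excess_mode)
  elig <- cohort[cohort$eligible, , drop = FALSE]
  ex <- classified[classified$status == "exceeds", , drop = FALSE]

  n_ex <- table(factor(ex$patient_id, levels = elig$patient_id))
  patient <- data.frame(
    patient_id = elig$patient_id,
    any_exceed = as.integer(n_ex > 0L),
    n_exceed = as.integer(n_ex)
  )
  if (excess_mode == "supply_days") {
    agg <- tapply(ex$days_supply, factor(ex$patient_id, levels = elig$patient_id), sum)
  } else {
    cov_start <- pmax(ex$rel_day, threshold_days)
    m <- merge_intervals_by(ex$patient_id, cov_start, ex$rel_day + ex$days_supply)
    m <- m[m$end > m$start, , drop = FALSE]
    agg <- tapply(m$end - m$start, factor(m$patient_id, levels = elig$patient_id), sum)
  }
  patient$excess_days <- as.integer(ifelse(is.na(agg), 0L, agg))

  q <- function(x) if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
                   else rep(NA_real_, 3)
  pos <- patient[patient$any_exceed == 1L, , drop = FALSE]
  qn <- q(pos$n_exceed)
  qd <- q(pos$excess_days)
  summary <- data.frame(
    n_patients = nrow(elig),
    n_any_exceed = nrow(pos),
    prop_any_exceed = if (nrow(elig)) nrow(pos) / nrow(elig) else NA_real_,
    median_n_exceed = qn[2L], iqr_lo_n_exceed = qn[1L], iqr_hi_n_exceed = qn[3L],
    median_excess_days = qd[2L], iqr_lo_excess_days = qd[1L], iqr_hi_excess_days = qd[3L]
  )

  prescribers <- if (nrow(ex)) {
    tb <- sort(table(ex$prescriber_type), decreasing = TRUE)
    data.frame(prescriber_type = names(tb), n = as.integer(tb),
               proportion = as.numeric(tb) / nrow(ex), row.names = NULL)
  } else {
    data.frame(prescriber_type = character(), n = integer(), proportion = numeric())
  }

  list(patient = patient, summary = summary, prescribers = prescribers)
}

#' Table-1-style baseline characteristics of the analytic cohort
#'
#' @param cohort cohort records.
#' @param patients the patients table.
#' @return data.frame of characteristic, value pairs.
#' @export
describe_baseline <- function(cohort, patients) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  pm <- match(elig$patient_id, patients$patient_id)
  p <- patients[pm, , drop = FALSE]
  qa <- stats::quantile(p$age, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- list(
    c("n", nrow(elig)),
    c("age_median", qa[2L]), c("age_iqr_lo", qa[1L]), c("age_iqr_hi", qa[3L]),
    c("inpatient_pct", round(100 * mean(elig$inpatient_index), 1))
  )
  for (f in intersect(c("female", "black"), names(p))) {
    rows[[length(rows) + 1L]] <- c(paste0(f, "_pct"), round(100 * mean(p[[f]]), 1))
  }
  for (l in unique(p$frailty)) {
    rows[[length(rows) + 1L]] <- c(paste0("frailty_", l, "_pct"),
                                   round(100 * mean(p$frailty == l), 1))
  }
  data.frame(characteristic = vapply(rows, `[`, "", 1L),
             value = as.numeric(vapply(rows, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}
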