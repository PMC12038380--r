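# --- medication exposure -----------------------------------------------------

# merge half-open intervals [start, end) within groups; touching intervals fuse
merge_intervals_by <- function(id, start, end) {
  if (!length(id)) {
    return(data.frame(patient_id = integer(), start = numeric(), end = numeric()))
  }
  o <- order(id, start)
  id <- id[o]; start <- start[o]; end <- end[o]
  # running maximum of end within each id
  keep_start <- rep(TRUE, length(id))
  run_end <- end
  for (i in seq_along(id)[-1L]) {
    if (id[i] == id[i - 1L] && start[i] <= run_end[i - 1L]) {
      keep_start[i] <- FALSE
      run_end[i] <- max(run_end[i - 1L], end[i])
    }
  }
  grp <- cumsum(keep_start)
  data.frame(
    patient_id = id[keep_start],
    start = start[keep_start],
    end = tapply(run_end, grp, max)[as.character(seq_len(max(grp)))],
    row.names = NULL
  )
}

#' Merged drug-exposure intervals from dispensing records
#'
#' Converts fills of one or more drug classes into merged half-open exposure
#' intervals `[fill day, fill day + days supply + grace)`. The grace period
#' absorbs imperfect refill adherence, the standard convention when inferring
#' continuous drug exposure from pharmacy claims.
#'
#' @param fills a fills data.frame (`patient_id`, `drug_class`, `day`,
#'   `days_supply`).
#' @param grace_days days appended to each supply (default 30).
#' @param classes drug classes to keep; default all except `"ppi"`.
#' @return data.frame `patient_id`, `drug_class`, `start`, `end` (same day
#'   scale as `fills$day`; intervals are half-open on the right).
#' @export
exposure_intervals <- function(fills, grace_days = 30, classes = NULL) {
  if (is.null(classes)) classes <- setdiff(unique(fills$drug_class), "ppi")
  out <- lapply(classes, function(cls) {
    sub <- fills[fills$drug_class == cls, , drop = FALSE]
    m <- merge_intervals_by(sub$patient_id, sub$day, sub$day + sub$days_supply + grace_days)
    if (nrow(m)) m$drug_class <- cls
    m
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (!length(out)) {
    return(data.frame(patient_id = integer(), start = numeric(), end = numeric(),
                      drug_class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$patient_id, res$drug_class, res$start), , drop = FALSE]
}

#' Is a medication active on a given day?
#'
#' A day counts as exposed when it falls in `[fill day, fill day + days supply
#' + grace)` for any fill, half-open on the right: the day a supply (plus
#' grace) runs out is no longer exposed.
#'
#' @param fills fills of a single drug class for a single patient.
#' @param day study day (scalar).
#' @param grace_days grace period, default 30.
#' @return logical scalar.
#' @export
medication_active <- function(fills, day, grace_days = 30) {
  if (!nrow(fills)) return(FALSE)
  any(day >= fills$day & day < fills$day + fills$days_supply + grace_days)
}

# --- gastroprotection guideline rules ---------------------------------------

#' Gastroprotection guideline rule set
#'
#' Guideline criteria under which long-term PPI use is considered indicated
#' for gastrointestinal prophylaxis. Each rule carries the calendar date from
#' which it is assessed (January 1 of the year after the guideline's
#' introduction) and a predicate over the patient's state: age, active drug
#' classes, and history flags. PUD history is true for every post-index date
#' in this cohort by construction.
#'
#' Default rules: (2009) PUD history and NSAID use; (2010) history of GI
#' bleeding; (2010) antiplatelet use plus any of age > 65, anticoagulant,
#' NSAID, or aspirin use; (2017) concurrent aspirin and antiplatelet;
#' (2018) concurrent aspirin and anticoagulant; (2020) two or more of aspirin,
#' NSAIDs, anticoagulants, antiplatelets.
#'
#' @return a list of rules, each `list(rule_id, active_from, predicate)`;
#'   `predicate(state)` takes `state` with elements `age`, `active` (named
#'   logical over drug classes), `pud_history`, `gi_bleed_history`.
#' @export
gastroprotection_rules <- function() {
  act <- function(state, cls) isTRUE(unname(state$active[cls]))
  list(
    list(rule_id = "pud_nsaid_2009", active_from = as.Date("2010-01-01"),
         predicate = function(state) isTRUE(state$pud_history) && act(state, "nsaid")),
    list(rule_id = "gi_bleed_2010", active_from = as.Date("2011-01-01"),
         predicate = function(state) isTRUE(state$gi_bleed_history)),
    list(rule_id = "antiplatelet_plus_2010", active_from = as.Date("2011-01-01"),
         predicate = function(state) act(state, "antiplatelet") &&
           (state$age > 65 || act(state, "anticoagulant") || act(state, "nsaid") ||
              act(state, "aspirin"))),
    list(rule_id = "aspirin_antiplatelet_2017", active_from = as.Date("2018-01-01"),
         predicate = function(state) act(state, "aspirin") && act(state, "antiplatelet")),
    list(rule_id = "aspirin_anticoagulant_2018", active_from = as.Date("2019-01-01"),
         predicate = function(state) act(state, "aspirin") && act(state, "anticoagulant")),
    list(rule_id = "two_or_more_2020", active_from = as.Date("2021-01-01"),
         predicate = function(state) {
           sum(vapply(c("aspirin", "nsaid", "anticoagulant", "antiplatelet"),
                      function(cl) act(state, cl), logical(1))) >= 2L
         })
  )
}

#' Evaluate gastroprotection qualification at a date
#'
#' @param state patient state at the date: `list(age, active, pud_history,
#'   gi_bleed_history)` as documented in [gastroprotection_rules()].
#' @param date calendar `Date` of assessment.
#' @param rules rule set; defaults to [gastroprotection_rules()].
#' @return `list(qualifies = logical, rule_id = first satisfied rule or NA)`.
#' @export
gastroprotection_qualifies <- function(state, date, rules = gastroprotection_rules()) {
  for (r in rules) {
    if (date >= r$active_from && isTRUE(r$predicate(state))) {
      return(list(qualifies = TRUE, rule_id = r$rule_id))
    }
  }
  list(qualifies = FALSE, rule_id = NA_character_)
}

# patient state at an absolute study day, from precomputed exposure intervals
patient_state_at <- function(day, age, expo_flat, gi_bleed_days, gi_bleed_at_index) {
  active <- vapply(expo_flat, function(b) {
    length(b) > 0L && findInterval(day, b) %% 2L == 1L
  }, logical(1))
  list(age = age, active = active, pud_history = TRUE,
       gi_bleed_history = isTRUE(gi_bleed_at_index) || any(gi_bleed_days <= day))
}

# --- fill classification -----------------------------------------------------

#' Classify PPI fills against the approved treatment duration
#'
#' A fill exceeds the approved duration when its supply end
#' (`fill day + days supply`) passes 60 days after the index PUD diagnosis —
#' the 8-week approved course rounded up to the 30-day increments US
#' prescriptions are written in. Two exceptions reclassify such fills as
#' approved: supply ending within 60 days of the patient's first *H. pylori*
#' diagnosis (treatment-delay margin), and, in the secondary analysis, the
#' patient meeting any active gastroprotection guideline at the fill date.
#' Backstock from earlier fills is deliberately ignored: each fill is judged
#' on its own dates, so classification of one fill never depends on another.
#'
#' @param fills PPI fills (`patient_id`, `day`, `days_supply`,
#'   `prescriber_type`) at or after each patient's index.
#' @param cohort cohort records from [build_cohort()] (eligible rows are used).
#' @param tables the full `ehr_tables` list (for *H. pylori* dates, GI-bleed
#'   history, co-medication exposure and, under the endoscopy sensitivity,
#'   follow-up endoscopies).
#' @param gastroprotection apply the guideline reclassification (secondary
#'   analysis)?
#' @param rules gastroprotection rule set.
#' @param grace_days grace period for co-medication exposure.
#' @param threshold_days approved-duration threshold after index, default 60.
#' @param hp_margin_days margin after first *H. pylori* diagnosis, default 60.
#' @param post_endoscopy_days when `> 0`, fills dispensed within this many
#'   days after a follow-up endoscopy (strictly after index) are approved —
#'   the delayed-ulcer-healing sensitivity analysis.
#' @param study_start epoch for converting study days to calendar dates.
#' @return data.frame of classified fills: `patient_id`, `day`, `rel_day`
#'   (days since index), `days_supply`, `supply_end`, `status`
#'   (`approved`/`exceeds`), `reason` (`within_60d`, `hp_exception`,
#'   `gastroprotection`, `post_endoscopy`, `exceeds`), `prescriber_type`.
#' @export
classify_fills <- function(fills, cohort, tables,
                           gastroprotection = FALSE,
                           rules = gastroprotection_rules(),
                           grace_days = 30,
                           threshold_days = 60,
                           hp_margin_days = 60,
                           post_endoscopy_days = 0,
                           study_start = "1999-01-01") {
  if (any(fills$days_supply < 0)) stop("data error: negative days_supply", call. = FALSE)
  elig <- cohort[cohort$eligible, , drop = FALSE]
  f <- fills[fills$drug_class == "ppi" &
               fills$patient_id %in% elig$patient_id, , drop = FALSE]
  mi <- match(f$patient_id, elig$patient_id)
  index <- elig$index_day[mi]
  f <- f[f$day >= index, , drop = FALSE]
  mi <- match(f$patient_id, elig$patient_id)
  index <- elig$index_day[mi]

  hp_first <- first_hp_day(tables)
  hp <- hp_first[match(f$patient_id, hp_first$patient_id), "day"]

  supply_end <- f$day + f$days_supply
  exceeds <- supply_end > index + threshold_days
  hp_ok <- exceeds & !is.na(hp) & supply_end <= hp + hp_margin_days
  reason <- ifelse(!exceeds, "within_60d", ifelse(hp_ok, "hp_exception", "exceeds"))

  if (post_endoscopy_days > 0) {
    endo <- tables$tests[tables$tests$test == "endoscopy", , drop = FALSE]
    endo_idx <- elig$index_day[match(endo$patient_id, elig$patient_id)]
    endo <- endo[!is.na(endo_idx) & endo$day > endo_idx, , drop = FALSE]
    if (nrow(endo)) {
      post <- vapply(seq_len(nrow(f)), function(i) {
        ed <- endo$day[endo$patient_id == f$patient_id[i]]
        any(f$day[i] >= ed & f$day[i] <= ed + post_endoscopy_days)
      }, logical(1))
      reclass <- reason == "exceeds" & post
      reason[reclass] <- "post_endoscopy"
    }
  }

  if (gastroprotection && any(reason == "exceeds")) {
    gp <- gastroprotection_flags(f[reason == "exceeds", , drop = FALSE],
                                 elig, tables, rules, grace_days, study_start)
    reason[reason == "exceeds"][gp] <- "gastroprotection"
  }

  data.frame(
    patient_id = f$patient_id,
    day = f$day,
    rel_day = f$day - index,
    days_supply = f$days_supply,
    supply_end = supply_end,
    status = ifelse(reason == "exceeds", "exceeds", "approved"),
    reason = reason,
    prescriber_type = f$prescriber_type,
    stringsAsFactors = FALSE
  )
}

# first H. pylori day per patient, pooled over test results and coded diagnoses
first_hp_day <- function(tables) {
  days <- c()
  ids <- c()
  tt <- tables$tests
  if (!is.null(tt)) {
    sub <- tt[tt$test == "h_pylori" & tt$result == "positive", , drop = FALSE]
    ids <- c(ids, sub$patient_id); days <- c(days, sub$day)
  }
  dd <- tables$diagnoses
  if (!is.null(dd)) {
    sub <- dd[dd$condition == "h_pylori", , drop = FALSE]
    ids <- c(ids, sub$patient_id); days <- c(days, sub$day)
  }
  if (!length(ids)) return(data.frame(patient_id = integer(), day = integer()))
  agg <- tapply(days, ids, min)
  data.frame(patient_id = as.integer(names(agg)), day = as.integer(agg))
}

# gastroprotection qualification per fill row (logical vector)
gastroprotection_flags <- function(f, elig, tables, rules, grace_days, study_start) {
  expo <- exposure_intervals(tables$fills, grace_days = grace_days,
                             classes = c("nsaid", "aspirin", "anticoagulant", "antiplatelet"))
  gi <- tables$diagnoses[tables$diagnoses$condition == "gi_bleed", , drop = FALSE]
  out <- logical(nrow(f))
  for (pid in unique(f$patient_id)) {
    rows <- which(f$patient_id == pid)
    e <- elig[elig$patient_id == pid, , drop = FALSE]
    flat <- lapply(c(nsaid = "nsaid", aspirin = "aspirin",
                     anticoagulant = "anticoagulant", antiplatelet = "antiplatelet"),
                   function(cls) {
                     sub <- expo[expo$patient_id == pid & expo$drug_class == cls, , drop = FALSE]
                     if (!nrow(sub)) numeric(0) else as.numeric(rbind(sub$start, sub$end))
                   })
    gi_days <- gi$day[gi$patient_id == pid]
    for (r in rows) {
      st <- patient_state_at(f$day[r], e$age, flat, gi_days, e$gi_bleed_at_index)
      q <- gastroprotection_qualifies(st, as_calendar_date(f$day[r], study_start), rules)
      out[r] <- q$qualifies
    }
  }
  out
}
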