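#' Censoring plan
#'
#' Follow-up ends at the earliest of: a new chronic PPI indication, the
#' administrative follow-up cap (3 years by default; 5 years in sensitivity
#' analysis), the regional deprescribing cutoff for patients diagnosed in
#' network (VISN) 17, the end of available data, and — in the secondary
#' analysis — first qualification under a gastroprotection guideline.
#'
#' @param max_followup_days administrative cap, default 1095.
#' @param visn17_cutoff calendar date of the network-17 deprescribing program.
#' @param indication_censoring censor at new PPI-indication diagnoses?
#' @param guideline_censoring censor at first gastroprotection qualification
#'   (secondary analysis)?
#' @param study_start,study_end calendar anchors of the data.
#' @return a `censor_plan` list.
#' @export
censor_plan <- function(max_followup_days = 1095,
                        visn17_cutoff = "2013-08-01",
                        indication_censoring = TRUE,
                        guideline_censoring = FALSE,
                        study_start = "1999-01-01",
                        study_end = "2022-12-31") {
  stopifnot(max_followup_days > 0)
  structure(list(max_followup_days = max_followup_days,
                 visn17_cutoff = as.Date(visn17_cutoff),
                 indication_censoring = indication_censoring,
                 guideline_censoring = guideline_censoring,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end)),
            class = "censor_plan")
}

# tie priority: administrative causes lose ties to clinical ones
censor_priority <- c(new_indication = 1, guideline = 2, visn17 = 3,
                     end_of_data = 4, max_followup = 5)

#' Censoring time and cause per patient
#'
#' @param cohort cohort records (eligible rows are used).
#' @param tables the `ehr_tables` list.
#' @param plan a [censor_plan()].
#' @param rules gastroprotection rules (used when `guideline_censoring`).
#' @param grace_days exposure grace period for guideline evaluation.
#' @return data.frame `patient_id`, `censor_day` (days since index; can be
#'   `<= 0` for patients whose follow-up is exhausted at entry), `cause`.
#' @export
censor_times <- function(cohort, tables, plan = censor_plan(),
                         rules = gastroprotection_rules(), grace_days = 30) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  n <- nrow(elig)
  cand <- matrix(Inf, n, 5L,
                 dimnames = list(NULL, names(censor_priority)))
  cand[, "max_followup"] <- plan$max_followup_days
  end_day <- as_study_day(plan$study_end, plan$study_start)
  cand[, "end_of_data"] <- end_day - elig$index_day

  if (plan$indication_censoring) {
    ind <- tables$diagnoses[tables$diagnoses$condition == "ppi_indication", , drop = FALSE]
    m <- match(ind$patient_id, elig$patient_id)
    keep <- !is.na(m) & ind$day > elig$index_day[m]
    if (any(keep)) {
      rel <- ind$day[keep] - elig$index_day[m[keep]]
      agg <- tapply(rel, ind$patient_id[keep], min)
      cand[match(as.integer(names(agg)), elig$patient_id), "new_indication"] <- agg
    }
  }

  cutoff_day <- as_study_day(plan$visn17_cutoff, plan$study_start)
  in17 <- !is.na(elig$visn) & elig$visn == 17L
  cand[in17, "visn17"] <- cutoff_day - elig$index_day[in17]

  if (plan$guideline_censoring) {
    cand[, "guideline"] <- guideline_qualification_times(elig, tables, rules,
                                                         grace_days, plan)
  }

  t_min <- do.call(pmin, as.data.frame(cand))
  cause <- character(n)
  for (i in seq_len(n)) {
    hit <- which(cand[i, ] == t_min[i])
    cause[i] <- names(censor_priority)[hit[which.min(censor_priority[hit])]]
  }
  data.frame(patient_id = elig$patient_id,
             censor_day = as.numeric(t_min),
             cause = cause,
             stringsAsFactors = FALSE)
}

# first post-index day (relative) at which any active gastroprotection rule is
# satisfied; Inf when never. State can flip to TRUE only when an exposure
# starts, a GI bleed occurs, or a rule activates, so only those times are
# evaluated (plus exposure ends, after which a later start may re-qualify).
guideline_qualification_times <- function(elig, tables, rules, grace_days, plan) {
  expo <- exposure_intervals(tables$fills, grace_days = grace_days,
                             classes = c("nsaid", "aspirin", "anticoagulant", "antiplatelet"))
  gi <- tables$diagnoses[tables$diagnoses$condition == "gi_bleed", , drop = FALSE]
  act_rel <- function(idx) {
    vapply(rules, function(r) as.numeric(as_study_day(r$active_from, plan$study_start)) - idx,
           numeric(1))
  }
  out <- rep(Inf, nrow(elig))
  for (i in seq_len(nrow(elig))) {
    pid <- elig$patient_id[i]
    idx <- elig$index_day[i]
    sub <- expo[expo$patient_id == pid, , drop = FALSE]
    flat <- lapply(c(nsaid = "nsaid", aspirin = "aspirin",
                     anticoagulant = "anticoagulant", antiplatelet = "antiplatelet"),
                   function(cls) {
                     s <- sub[sub$drug_class == cls, , drop = FALSE]
                     if (!nrow(s)) numeric(0) else as.numeric(rbind(s$start, s$end))
                   })
    gi_days <- gi$day[gi$patient_id == pid]
    cands <- c(0, sub$start - idx, gi_days - idx, act_rel(idx))
    cands <- sort(unique(cands[cands >= 0 & cands <= plan$max_followup_days]))
    for (t in cands) {
      st <- patient_state_at(idx + t, elig$age[i], flat, gi_days,
                             elig$gi_bleed_at_index[i])
      q <- gastroprotection_qualifies(st, as_calendar_date(idx + t, plan$study_start), rules)
      if (q$qualifies) { out[i] <- t; break }
    }
  }
  out
}

# baseline covariate columns for the model, one row per cohort patient
baseline_covariates <- function(cohort, patients, covariates,
                                med_classes = character(),
                                frailty_col = "frailty") {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  pm <- match(elig$patient_id, patients$patient_id)
  out <- data.frame(patient_id = elig$patient_id)
  for (cv in setdiff(covariates, med_classes)) {
    if (cv == "inpatient") {
      out[[cv]] <- as.integer(elig$inpatient_index)
    } else if (grepl("^frailty_", cv)) {
      lev <- sub("^frailty_", "", cv)
      out[[cv]] <- as.integer(patients[[frailty_col]][pm] == lev)
    } else if (cv %in% names(patients)) {
      out[[cv]] <- as.numeric(patients[[cv]][pm])
    } else {
      stop("unknown baseline covariate: ", cv, call. = FALSE)
    }
  }
  out
}

#' Build Andersen-Gill counting-process data
#'
#' Expands each eligible patient's follow-up `(0, censor]` into half-open risk
#' intervals `(start, stop]` cut at every exceeding-fill date (event rows),
#' every time-varying exposure change, and the censoring time. Covariates are
#' constant within an interval; when an exposure changes on the same day as an
#' event, the pre-change value is in force (changes apply from the next
#' interval). Multiple exceeding fills on one day collapse to a single event;
#' fills after the censoring time are excluded. An exceeding fill on the index
#' day itself is placed at day 0.5 so the interval (0, 0.5] is well formed.
#'
#' @param cohort cohort records.
#' @param classified classified fills from [classify_fills()].
#' @param tables the `ehr_tables` list.
#' @param censor output of [censor_times()].
#' @param covariates character vector of model covariate names; names matching
#'   `med_classes` become time-varying exposure indicators.
#' @param med_classes drug classes treated as time-varying exposures.
#' @param grace_days exposure grace period.
#' @param frailty_col patients column holding the frailty category (swap in
#'   `"frailty_alt"` for the recomputed-frailty sensitivity analysis).
#' @return data.frame `patient_id`, `start`, `stop`, `event` plus one column
#'   per covariate, with attribute `covariates`.
#' @export
build_intervals <- function(cohort, classified, tables, censor,
                            covariates = default_covariates(),
                            med_classes = c("nsaid", "anticoagulant", "aspirin"),
                            grace_days = 30,
                            frailty_col = "frailty") {
  med_classes <- intersect(med_classes, covariates)
  elig <- cohort[cohort$eligible, , drop = FALSE]
  cm <- match(elig$patient_id, censor$patient_id)
  cens <- censor$censor_day[cm]
  keep <- !is.na(cens) & cens > 0
  elig <- elig[keep, , drop = FALSE]
  cens <- cens[keep]
  n <- nrow(elig)

  ex <- classified[classified$status == "exceeds", , drop = FALSE]
  ev_by <- split(pmax(ex$rel_day, 0.5), factor(ex$patient_id, levels = elig$patient_id))

  pid_levels <- as.character(elig$patient_id)
  flat_m <- list()
  for (cls in med_classes) {
    sub <- tables$fills[tables$fills$drug_class == cls, , drop = FALSE]
    rel0 <- sub$day - elig$index_day[match(sub$patient_id, elig$patient_id)]
    ok <- !is.na(rel0)
    ivl <- merge_intervals_by(sub$patient_id[ok], rel0[ok],
                              rel0[ok] + sub$days_supply[ok] + grace_days)
    flat_m[[cls]] <- split_interval_bounds(ivl, pid_levels)
  }

  starts <- vector("list", n); stops <- vector("list", n); events <- vector("list", n)
  meds <- lapply(med_classes, function(cls) vector("list", n))
  names(meds) <- med_classes
  for (i in seq_len(n)) {
    ci <- cens[i]
    ev <- sort(unique(ev_by[[i]]))
    ev <- ev[ev <= ci]
    cuts <- numeric(0)
    for (cls in med_classes) {
      b <- flat_m[[cls]][[i]]
      cuts <- c(cuts, b[b > 0 & b < ci])
    }
    bounds <- sort(unique(c(ev, cuts, ci)))
    st <- c(0, bounds[-length(bounds)])
    starts[[i]] <- st
    stops[[i]] <- bounds
    events[[i]] <- as.integer(bounds %in% ev)
    mid <- (st + bounds) / 2
    for (cls in med_classes) {
      b <- flat_m[[cls]][[i]]
      meds[[cls]][[i]] <- if (length(b)) as.integer(findInterval(mid, b) %% 2L == 1L)
                          else integer(length(mid))
    }
  }
  counts <- lengths(stops)
  out <- data.frame(
    patient_id = rep.int(elig$patient_id, counts),
    start = unlist(starts, use.names = FALSE),
    stop = unlist(stops, use.names = FALSE),
    event = unlist(events, use.names = FALSE)
  )
  base <- baseline_covariates(cohort, tables$patients, covariates, med_classes,
                              frailty_col)
  bm <- match(elig$patient_id, base$patient_id)
  for (cv in setdiff(covariates, med_classes)) {
    out[[cv]] <- rep.int(base[[cv]][bm], counts)
  }
  for (cls in med_classes) {
    out[[cls]] <- unlist(meds[[cls]], use.names = FALSE)
  }
  attr(out, "covariates") <- covariates
  out
}

#' Default model covariates
#'
#' Baseline factors (inpatient diagnosis, female sex, Black race, frailty
#' dummies against a nonfrail reference) plus the time-varying drug exposure
#' indicators.
#'
#' @return character vector.
#' @export
default_covariates <- function() {
  c("inpatient", "female", "black",
    "frailty_prefrail", "frailty_mild", "frailty_moderate", "frailty_severe",
    "nsaid", "anticoagulant", "aspirin")
}
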