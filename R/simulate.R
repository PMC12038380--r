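#' Generate baseline patient records
#'
#' Draws demographics, baseline risk-factor indicators, a five-level frailty
#' category and facility assignments at the configured prevalences. Every
#' binary factor named in `factor_prevalences` becomes a 0/1 column, so extra
#' covariates (for example a pure-noise factor in calibration experiments) can
#' be added purely through configuration.
#'
#' @param config a [sim_config()] object.
#' @param n optional override of `config$n_patients`.
#' @param id_offset first patient id minus one.
#' @return a data.frame with one row per patient: `patient_id`, `age`,
#'   factor indicator columns, `race`, `frailty`, `frailty_alt` (the frailty
#'   category recomputed without cardiovascular anticoagulant/antiplatelet
#'   indications, for sensitivity use), `charlson`, `facility`, `visn`, and
#'   `index_day` (study-day of the index PUD diagnosis).
#' @export
generate_patients <- function(config, n = config$n_patients, id_offset = 0L) {
  cfg <- validate_sim_config(config)
  age <- pmin(pmax(round(stats::rnorm(n, 78, 9)), 40L), 100L)
  out <- data.frame(patient_id = id_offset + seq_len(n), age = as.integer(age))
  for (f in base_factor_names(cfg)) {
    out[[f]] <- stats::rbinom(n, 1L, cfg$factor_prevalences[[f]])
  }
  out$race <- if ("black" %in% names(out)) ifelse(out$black == 1L, "black", "white") else "white"
  lev <- names(cfg$frailty_prevalences)
  out$frailty <- sample(lev, n, replace = TRUE, prob = cfg$frailty_prevalences)
  # alternative frailty: a subset of frail patients drop one level when the
  # cardiovascular deficit items are removed from the index
  shift <- stats::runif(n) < 0.15 & out$frailty != lev[1L]
  out$frailty_alt <- ifelse(shift, lev[pmax(match(out$frailty, lev) - 1L, 1L)], out$frailty)
  out$charlson <- pmin(stats::rpois(n, 2.5), 12L)
  out$facility <- sample.int(cfg$n_facilities, n, replace = TRUE)
  n17 <- max(round(cfg$visn17_fraction * cfg$n_facilities), if (cfg$visn17_fraction > 0) 1L else 0L)
  visn_of_facility <- c(rep(17L, n17), rep(seq_len(16L), length.out = cfg$n_facilities - n17))
  out$visn <- visn_of_facility[out$facility]
  rng <- as_study_day(cfg$index_date_range, cfg$study_start)
  out$index_day <- as.integer(sample(seq(rng[1L], rng[2L]), n, replace = TRUE))
  out
}

#' Simulate co-medication dispensing episodes
#'
#' Each drug class with a positive episode rate generates a stationary Poisson
#' process of treatment episodes per patient; episode starts are drawn on
#' `[-duration, horizon)` relative to index so that exposure prevalence is at
#' steady state from day 0. Each episode is dispensed as a single fill whose
#' days supply equals the episode duration.
#'
#' @param patients output of [generate_patients()].
#' @param config a [sim_config()] object.
#' @return a fills data.frame: `patient_id`, `drug_class`, `day` (study day),
#'   `days_supply`, `prescriber_type`.
#' @export
simulate_med_fills <- function(patients, config) {
  cfg <- validate_sim_config(config)
  n <- nrow(patients)
  res <- list()
  for (cls in names(cfg$med_episode_rates)) {
    rate <- cfg$med_episode_rates[[cls]]
    if (rate <= 0) next
    dur <- cfg$med_episode_duration[[cls]]
    span <- cfg$horizon_days + dur
    counts <- stats::rpois(n, rate * span / 365.25)
    m <- sum(counts)
    if (m == 0L) next
    pid <- rep.int(patients$patient_id, counts)
    idx <- rep.int(patients$index_day, counts)
    start_rel <- floor(stats::runif(m, -dur, cfg$horizon_days))
    res[[cls]] <- data.frame(
      patient_id = pid,
      drug_class = cls,
      day = as.integer(idx + start_rel),
      days_supply = as.integer(dur),
      prescriber_type = sample(names(cfg$prescriber_mix), m, replace = TRUE,
                               prob = cfg$prescriber_mix),
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) {
    return(data.frame(patient_id = integer(), drug_class = character(),
                      day = integer(), days_supply = integer(),
                      prescriber_type = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$patient_id, out$day), , drop = FALSE]
}

# linear predictor contribution of baseline covariates, per patient
baseline_eta <- function(patients, cfg) {
  beta <- cfg$true_log_hazards
  eta <- numeric(nrow(patients))
  for (f in intersect(base_factor_names(cfg), names(beta))) {
    eta <- eta + beta[[f]] * patients[[f]]
  }
  lev <- names(cfg$frailty_prevalences)
  for (l in lev[-1L]) {
    nm <- paste0("frailty_", l)
    if (nm %in% names(beta)) eta <- eta + beta[[nm]] * (patients$frailty == l)
  }
  eta
}

#' Simulate the recurrent PPI fill process
#'
#' PPI fills are drawn per patient from a multiplicative-intensity counting
#' process, `lambda_i(t) = lambda0 * exp(beta' Z_i(t))`, by thinning a
#' homogeneous Poisson process at the patient's maximal intensity. Baseline
#' factors and frailty enter as fixed covariates; co-medication classes enter
#' through their time-varying exposure indicator, derived from the simulated
#' fills with the same days-supply-plus-grace convention the downstream
#' analysis uses, so the generative covariate path and the ascertained one
#' coincide. The initial qualifying PPI course (a 30-day supply dispensed
#' within 14 days of index) is always emitted.
#'
#' @param patients output of [generate_patients()].
#' @param med_fills co-medication fills from [simulate_med_fills()].
#' @param config a [sim_config()] object.
#' @return a PPI fills data.frame with the same columns as
#'   [simulate_med_fills()].
#' @export
simulate_fill_process <- function(patients, med_fills, config) {
  cfg <- validate_sim_config(config)
  n <- nrow(patients)
  beta <- cfg$true_log_hazards
  eta_b <- baseline_eta(patients, cfg)
  mc <- med_factor_names(cfg)

  # merged exposure intervals per class, relative to each patient's index
  flat <- vector("list", length(mc))
  names(flat) <- mc
  pid_levels <- as.character(patients$patient_id)
  for (cls in mc) {
    sub <- med_fills[med_fills$drug_class == cls, , drop = FALSE]
    rel <- sub$day - patients$index_day[match(sub$patient_id, patients$patient_id)]
    ivl <- merge_intervals_by(sub$patient_id, rel, rel + sub$days_supply + cfg$med_grace_days)
    flat[[cls]] <- split_interval_bounds(ivl, pid_levels)
  }

  lam0 <- cfg$baseline_intensity
  lam_max <- lam0 * exp(eta_b + sum(pmax(beta[mc], 0)))
  res <- vector("list", n)
  bmc <- beta[mc]
  for (i in seq_len(n)) {
    nb <- stats::rpois(1L, lam_max[i] * cfg$horizon_days)
    init_day <- sample(0:14, 1L)
    if (nb > 0L && lam0 > 0) {
      tt <- stats::runif(nb, 0, cfg$horizon_days)
      eta_t <- rep(eta_b[i], nb)
      for (cls in mc) {
        b <- flat[[cls]][[i]]
        if (length(b)) {
          eta_t <- eta_t + bmc[[cls]] * (findInterval(tt, b) %% 2L == 1L)
        }
      }
      keep <- stats::runif(nb) < lam0 * exp(eta_t) / lam_max[i]
      days <- floor(tt[keep])
    } else {
      days <- numeric(0)
    }
    res[[i]] <- c(init_day, days)
  }
  counts <- lengths(res)
  m <- sum(counts)
  pid <- rep.int(patients$patient_id, counts)
  idx <- rep.int(patients$index_day, counts)
  rel <- unlist(res, use.names = FALSE)
  supply <- integer(m)
  is_init <- sequence(counts) == 1L
  supply[is_init] <- 30L
  n_later <- sum(!is_init)
  supply[!is_init] <- sample(cfg$days_supply_values, n_later, replace = TRUE,
                             prob = cfg$days_supply_probs)
  out <- data.frame(
    patient_id = pid,
    drug_class = "ppi",
    day = as.integer(idx + rel),
    days_supply = supply,
    prescriber_type = sample(names(cfg$prescriber_mix), m, replace = TRUE,
                             prob = cfg$prescriber_mix),
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$day), , drop = FALSE]
}

# flattened interval bounds per patient for fast odd/even membership tests
split_interval_bounds <- function(ivl, pid_levels) {
  sp <- split(seq_len(nrow(ivl)), factor(as.character(ivl$patient_id), levels = pid_levels))
  lapply(sp, function(ix) {
    if (!length(ix)) return(numeric(0))
    o <- ix[order(ivl$start[ix])]
    as.numeric(rbind(ivl$start[o], ivl$end[o]))
  })
}

#' Simulate post-index censoring and exception events
#'
#' Draws, per patient, exponential times to a new chronic PPI indication and
#' to a gastrointestinal bleed (diagnosis events), plus an *H. pylori*
#' diagnosis shortly after index for the configured positive fraction (a test
#' event). Events beyond the follow-up horizon are not emitted.
#'
#' @param patients output of [generate_patients()].
#' @param config a [sim_config()] object.
#' @return `list(diagnoses = ..., tests = ...)` in the standard table layouts.
#' @export
simulate_censoring_events <- function(patients, config) {
  cfg <- validate_sim_config(config)
  n <- nrow(patients)
  diag_rows <- list()
  cause_condition <- c(new_indication = "ppi_indication", gi_bleed = "gi_bleed")
  for (cause in names(cfg$censor_rates)) {
    r <- cfg$censor_rates[[cause]]
    if (r <= 0) next
    tt <- stats::rexp(n, r / 365.25)
    keep <- tt <= cfg$horizon_days
    if (!any(keep)) next
    diag_rows[[cause]] <- data.frame(
      patient_id = patients$patient_id[keep],
      day = as.integer(patients$index_day[keep] + ceiling(tt[keep])),
      condition = cause_condition[[cause]] %||% cause,
      inpatient = 0L,
      stringsAsFactors = FALSE
    )
  }
  diagnoses <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(patient_id = integer(), day = integer(), condition = character(),
               inpatient = integer(), stringsAsFactors = FALSE)
  rownames(diagnoses) <- NULL

  hp <- stats::runif(n) < cfg$hp_positive_fraction
  tests <- data.frame(
    patient_id = patients$patient_id[hp],
    day = as.integer(patients$index_day[hp] +
                       ceiling(stats::rexp(sum(hp), 1 / cfg$hp_delay_mean_days))),
    test = rep("h_pylori", sum(hp)),
    result = rep("positive", sum(hp)),
    stringsAsFactors = FALSE
  )
  if (cfg$endoscopy_followup_rate > 0) {
    te <- stats::rexp(n, cfg$endoscopy_followup_rate / 365.25)
    keep <- te <= cfg$horizon_days
    if (any(keep)) {
      tests <- rbind(tests, data.frame(
        patient_id = patients$patient_id[keep],
        day = as.integer(patients$index_day[keep] + ceiling(te[keep])),
        test = "endoscopy",
        result = "performed",
        stringsAsFactors = FALSE
      ))
    }
  }
  list(diagnoses = diagnoses, tests = tests)
}

#' Simulate a complete synthetic EHR extract
#'
#' Runs the full generator and assembles the four flat tables the analysis
#' pipeline consumes: `patients`, `diagnoses` (index acute PUD event per
#' patient plus censoring-cause diagnoses), `fills` (PPI and co-medication
#' dispensings) and `tests` (index upper endoscopy for everyone, *H. pylori*
#' results for positives). When `ineligible_fraction > 0`, extra patients with
#' a cycled eligibility violation (washout PPI fill, prior chronic PUD, prior
#' PPI indication, missing endoscopy, or no initial PPI fill) are appended so
#' attrition reporting has something to count.
#'
#' Identical `config` and `seed` yield bit-identical tables.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `ehr_tables`: a list with elements `patients`,
#'   `diagnoses`, `fills`, `tests` and the `config` used.
#' @export
simulate_ehr <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  if (is.null(seed)) stop("simulate_ehr() needs a seed (argument or config$seed)", call. = FALSE)
  set.seed(as.integer(seed))
  n_extra <- as.integer(round(cfg$ineligible_fraction * cfg$n_patients))
  patients <- generate_patients(cfg, n = cfg$n_patients + n_extra)
  violation <- rep(NA_character_, nrow(patients))
  if (n_extra > 0L) {
    kinds <- c("washout_fill", "chronic_pud", "prior_indication", "no_endoscopy",
               "no_initial_fill")
    violation[cfg$n_patients + seq_len(n_extra)] <- rep_len(kinds, n_extra)
  }

  med_fills <- simulate_med_fills(patients, cfg)
  ppi_fills <- simulate_fill_process(patients, med_fills, cfg)
  cens <- simulate_censoring_events(patients, cfg)

  index_diag <- data.frame(
    patient_id = patients$patient_id,
    day = patients$index_day,
    condition = "acute_pud",
    inpatient = if ("inpatient" %in% names(patients)) patients$inpatient else 0L,
    stringsAsFactors = FALSE
  )
  endo <- data.frame(
    patient_id = patients$patient_id,
    day = patients$index_day,
    test = "endoscopy",
    result = "performed",
    stringsAsFactors = FALSE
  )

  extra_diag <- list()
  extra_fills <- list()
  if (n_extra > 0L) {
    v <- violation
    w <- which(v == "washout_fill")
    if (length(w)) extra_fills$washout <- data.frame(
      patient_id = patients$patient_id[w], drug_class = "ppi",
      day = patients$index_day[w] - 100L, days_supply = 30L,
      prescriber_type = "primary_care", stringsAsFactors = FALSE)
    w <- which(v == "chronic_pud")
    if (length(w)) extra_diag$chronic <- data.frame(
      patient_id = patients$patient_id[w], day = patients$index_day[w] - 200L,
      condition = "chronic_pud", inpatient = 0L, stringsAsFactors = FALSE)
    w <- which(v == "prior_indication")
    if (length(w)) extra_diag$indic <- data.frame(
      patient_id = patients$patient_id[w], day = patients$index_day[w] - 300L,
      condition = "ppi_indication", inpatient = 0L, stringsAsFactors = FALSE)
    w <- which(v == "no_endoscopy")
    if (length(w)) {
      endo <- endo[!(endo$patient_id %in% patients$patient_id[w]), , drop = FALSE]
      drop_endo <- cens$tests$test == "endoscopy" &
        cens$tests$patient_id %in% patients$patient_id[w]
      cens$tests <- cens$tests[!drop_endo, , drop = FALSE]
    }
    w <- which(v == "no_initial_fill")
    if (length(w)) ppi_fills <- ppi_fills[!(ppi_fills$patient_id %in% patients$patient_id[w]), , drop = FALSE]
  }

  diagnoses <- do.call(rbind, c(list(index_diag, cens$diagnoses), extra_diag))
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$day), , drop = FALSE]
  rownames(diagnoses) <- NULL
  fills <- do.call(rbind, c(list(ppi_fills, med_fills), extra_fills))
  fills <- fills[order(fills$patient_id, fills$day, fills$drug_class), , drop = FALSE]
  rownames(fills) <- NULL
  tests <- rbind(endo, cens$tests)
  tests <- tests[order(tests$patient_id, tests$day, tests$test), , drop = FALSE]
  rownames(tests) <- NULL

  out <- list(patients = patients, diagnoses = diagnoses, fills = fills,
              tests = tests, config = cfg)
  class(out) <- "ehr_tables"
  out
}

#' Write / read the four flat tables as tab-delimited text
#'
#' @param tables an `ehr_tables` list (or any list with the four data.frames).
#' @param dir output directory (created if missing).
#' @return `write_ehr_tables()` returns the directory invisibly;
#'   `read_ehr_tables()` returns an `ehr_tables` list (without a config).
#' @export
write_ehr_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("patients", "diagnoses", "fills", "tests")) {
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  out <- lapply(c(patients = "patients", diagnoses = "diagnoses",
                  fills = "fills", tests = "tests"),
                function(nm) utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                                               stringsAsFactors = FALSE))
  class(out) <- "ehr_tables"
  out
}
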