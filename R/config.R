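#' Simulation configuration for the synthetic EHR generator
#'
#' Bundles every knob of the generator: cohort size, follow-up horizon,
#' the true multiplicative effects on the PPI fill intensity (log hazard-ratio
#' scale), prevalences of the baseline factors, co-medication episode rates and
#' durations, censoring-event rates, and calendar anchors.
#'
#' Defaults encode the study conditions the generator emulates: a cohort of
#' older adults with an incident peptic ulcer disease (PUD) diagnosis, an 18%
#' inpatient-diagnosis fraction, 18% Black race, 7% female, a five-level
#' frailty distribution of 24/43/22/8/3%, and true fill-intensity hazard
#' ratios of 1.32 (inpatient diagnosis), 0.83 (Black race), 0.91 (female),
#' 1.06/1.11/1.15/1.08 (prefrail through severely frail vs nonfrail), 1.26
#' (NSAID use), 1.25 (anticoagulant use) and 1.15 (aspirin use).
#'
#' @param n_patients number of patients.
#' @param horizon_days maximum simulated follow-up after the index diagnosis.
#' @param baseline_intensity baseline PPI fill intensity, fills/day, for a
#'   patient with all covariates at reference level.
#' @param true_log_hazards named numeric vector of log hazard ratios. Names
#'   matching `med_episode_rates` act on the time-varying exposure indicator
#'   of that drug class; `frailty_*` names act on the frailty dummies; all
#'   other names are binary baseline factors drawn at `factor_prevalences`.
#' @param factor_prevalences named probabilities for the binary baseline
#'   factors (must cover every non-frailty, non-medication name in
#'   `true_log_hazards`).
#' @param frailty_prevalences probabilities over the five frailty levels
#'   (nonfrail, prefrail, mild, moderate, severe); must sum to 1.
#' @param med_episode_rates named episodes/year per co-medication class.
#' @param med_episode_duration named episode duration in days per class.
#' @param med_grace_days grace period (days) appended to each dispensed supply
#'   when deriving the true exposure path; the analysis uses the same
#'   convention, so the generative covariate equals the ascertained one.
#' @param days_supply_values,days_supply_probs the dispensing mix for PPI
#'   fills after the initial course (US prescriptions cluster on 30/60/90).
#' @param censor_rates named events/year for post-index censoring causes:
#'   `new_indication` (a new chronic PPI indication) and `gi_bleed`
#'   (gastrointestinal bleeding, used by the gastroprotection rules).
#' @param hp_positive_fraction fraction of patients with an *H. pylori*
#'   diagnosis around the index date.
#' @param hp_delay_mean_days mean (exponential) delay from index to the
#'   *H. pylori* diagnosis.
#' @param endoscopy_followup_rate events/year of repeat upper endoscopies
#'   after index (used by the delayed-healing sensitivity analysis).
#' @param prescriber_mix named probabilities of prescriber type per fill.
#' @param n_facilities,visn17_fraction number of facilities and the fraction
#'   belonging to regional network 17 (subject to a deprescribing cutoff).
#' @param study_start,study_end,index_date_range calendar anchors; index dates
#'   are drawn uniformly over `index_date_range`.
#' @param ineligible_fraction extra patients, as a fraction of `n_patients`,
#'   injected with a randomly chosen eligibility violation so attrition
#'   reporting can be exercised.
#' @param seed optional integer; `simulate_ehr()` uses it when no explicit
#'   seed is passed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 2000L,
                       horizon_days = 1095L,
                       baseline_intensity = 0.001,
                       true_log_hazards = c(
                         inpatient = log(1.32),
                         black = log(0.83),
                         female = log(0.91),
                         frailty_prefrail = log(1.06),
                         frailty_mild = log(1.11),
                         frailty_moderate = log(1.15),
                         frailty_severe = log(1.08),
                         nsaid = log(1.26),
                         anticoagulant = log(1.25),
                         aspirin = log(1.15)
                       ),
                       factor_prevalences = c(
                         inpatient = 0.18,
                         black = 0.18,
                         female = 0.07
                       ),
                       frailty_prevalences = c(
                         nonfrail = 0.24, prefrail = 0.43, mild = 0.22,
                         moderate = 0.08, severe = 0.03
                       ),
                       med_episode_rates = c(
                         nsaid = 0.6, aspirin = 0.4, anticoagulant = 0.15,
                         antiplatelet = 0.15, h2ra = 0.2
                       ),
                       med_episode_duration = c(
                         nsaid = 60, aspirin = 180, anticoagulant = 180,
                         antiplatelet = 180, h2ra = 30
                       ),
                       med_grace_days = 30L,
                       days_supply_values = c(30L, 60L, 90L),
                       days_supply_probs = c(0.7, 0.2, 0.1),
                       censor_rates = c(new_indication = 0.05, gi_bleed = 0.02),
                       hp_positive_fraction = 0.05,
                       hp_delay_mean_days = 14,
                       endoscopy_followup_rate = 0.15,
                       prescriber_mix = c(
                         primary_care = 0.44, resident = 0.18,
                         advanced_practice = 0.16, gastroenterology = 0.16,
                         other = 0.06
                       ),
                       n_facilities = 20L,
                       visn17_fraction = 0.05,
                       study_start = "1999-01-01",
                       study_end = "2022-12-31",
                       index_date_range = c("2002-01-01", "2019-12-31"),
                       ineligible_fraction = 0,
                       seed = NULL) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    horizon_days = as.integer(horizon_days),
    baseline_intensity = baseline_intensity,
    true_log_hazards = true_log_hazards,
    factor_prevalences = factor_prevalences,
    frailty_prevalences = frailty_prevalences,
    med_episode_rates = med_episode_rates,
    med_episode_duration = med_episode_duration,
    med_grace_days = as.integer(med_grace_days),
    days_supply_values = as.integer(days_supply_values),
    days_supply_probs = days_supply_probs,
    censor_rates = censor_rates,
    hp_positive_fraction = hp_positive_fraction,
    hp_delay_mean_days = hp_delay_mean_days,
    endoscopy_followup_rate = endoscopy_followup_rate,
    prescriber_mix = prescriber_mix,
    n_facilities = as.integer(n_facilities),
    visn17_fraction = visn17_fraction,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    index_date_range = as.Date(index_date_range),
    ineligible_fraction = ineligible_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("configuration error: n_patients must be >= 1", call. = FALSE)
  if (cfg$horizon_days <= 0L) stop("configuration error: horizon_days must be > 0", call. = FALSE)
  check_nonneg(cfg$baseline_intensity, "baseline_intensity")
  check_prob(cfg$factor_prevalences, "factor_prevalences")
  check_prob(cfg$frailty_prevalences, "frailty_prevalences")
  if (abs(sum(cfg$frailty_prevalences) - 1) > 1e-8) {
    stop("configuration error: frailty_prevalences must sum to 1", call. = FALSE)
  }
  check_nonneg(cfg$med_episode_rates, "med_episode_rates")
  check_nonneg(cfg$med_episode_duration, "med_episode_duration")
  check_nonneg(cfg$censor_rates, "censor_rates")
  check_nonneg(cfg$endoscopy_followup_rate, "endoscopy_followup_rate")
  check_prob(cfg$hp_positive_fraction, "hp_positive_fraction")
  check_prob(cfg$ineligible_fraction, "ineligible_fraction")
  check_prob(cfg$days_supply_probs, "days_supply_probs")
  if (abs(sum(cfg$days_supply_probs) - 1) > 1e-8) {
    stop("configuration error: days_supply_probs must sum to 1", call. = FALSE)
  }
  if (!all(is.finite(cfg$true_log_hazards))) {
    stop("configuration error: true_log_hazards must be finite", call. = FALSE)
  }
  base_factors <- setdiff(names(cfg$true_log_hazards),
                          c(names(cfg$med_episode_rates),
                            paste0("frailty_", names(cfg$frailty_prevalences))))
  missing_prev <- setdiff(base_factors, names(cfg$factor_prevalences))
  if (length(missing_prev)) {
    stop("configuration error: no prevalence configured for factor(s): ",
         paste(missing_prev, collapse = ", "), call. = FALSE)
  }
  cfg
}

# names of binary baseline factors (drawn at factor_prevalences)
base_factor_names <- function(cfg) names(cfg$factor_prevalences)

# drug classes whose exposure indicator enters the fill intensity
med_factor_names <- function(cfg) {
  intersect(names(cfg$med_episode_rates), names(cfg$true_log_hazards))
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds the same fields as [sim_config()]; unset fields keep the
#' defaults. A `seed` argument overrides any seed in the file.
#'
#' @param path YAML file.
#' @param seed optional integer overriding the file's seed.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("configuration error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # yaml reads named maps as lists; flatten to named numeric vectors
  vec_fields <- c("true_log_hazards", "factor_prevalences", "frailty_prevalences",
                  "med_episode_rates", "med_episode_duration", "censor_rates",
                  "prescriber_mix")
  for (f in intersect(vec_fields, names(raw))) raw[[f]] <- unlist(raw[[f]])
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EHR simulation configuration\n")
  cat(sprintf("  patients: %d, horizon: %d days, baseline intensity: %g fills/day\n",
              x$n_patients, x$horizon_days, x$baseline_intensity))
  cat("  true hazard ratios:\n")
  hr <- exp(x$true_log_hazards)
  for (nm in names(hr)) cat(sprintf("    %-20s %.3f\n", nm, hr[[nm]]))
  invisible(x)
}
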