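test_that("identical seed reproduces identical tables bit for bit", {
  cfg <- sim_config(n_patients = 120, seed = 11, ineligible_fraction = 0.1)
  a <- simulate_ehr(cfg)
  b <- simulate_ehr(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$fills, b$fills)
  expect_identical(a$tests, b$tests)
})

test_that("factor indicators match configured prevalences", {
  cfg <- sim_config(n_patients = 10000, seed = 3)
  set.seed(cfg$seed)
  pat <- generate_patients(cfg)
  expect_lt(abs(mean(pat$inpatient) - 0.18), 0.01)
  expect_lt(abs(mean(pat$black) - 0.18), 0.01)
  expect_lt(abs(mean(pat$frailty == "moderate") - 0.08), 0.01)

  cfg0 <- sim_config(n_patients = 500,
                     true_log_hazards = c(inpatient = 0, black = 0),
                     factor_prevalences = c(inpatient = 0, black = 0),
                     seed = 3)
  set.seed(3)
  pat0 <- generate_patients(cfg0)
  expect_true(all(pat0$inpatient == 0L))
  expect_true(all(pat0$black == 0L))
})

test_that("invalid probabilities are rejected as configuration errors", {
  expect_error(sim_config(factor_prevalences = c(inpatient = 1.2)),
               "configuration error")
  expect_error(sim_config(hp_positive_fraction = -0.1), "configuration error")
  expect_error(sim_config(baseline_intensity = -1), "configuration error")
})

test_that("zero baseline intensity leaves only the initial qualifying fill", {
  cfg <- sim_config(n_patients = 80, baseline_intensity = 0, seed = 5)
  tab <- simulate_ehr(cfg)
  ppi <- tab$fills[tab$fills$drug_class == "ppi", ]
  expect_equal(nrow(ppi), 80L)
  rel <- ppi$day - tab$patients$index_day[match(ppi$patient_id, tab$patients$patient_id)]
  expect_true(all(rel >= 0 & rel <= 14))
  expect_true(all(ppi$days_supply == 30L))
})

test_that("with all effects null the fill count is Poisson at the base rate", {
  lam0 <- 0.002
  cfg <- sim_config(n_patients = 3000, baseline_intensity = lam0,
                    true_log_hazards = c(noise = 0),
                    factor_prevalences = c(noise = 0.5),
                    med_episode_rates = c(nsaid = 0),
                    hp_positive_fraction = 0, seed = 21)
  tab <- simulate_ehr(cfg)
  ppi <- tab$fills[tab$fills$drug_class == "ppi", ]
  n_process <- nrow(ppi) - cfg$n_patients  # one guaranteed initial fill each
  mu <- cfg$n_patients * lam0 * cfg$horizon_days
  expect_lt(abs(n_process - mu), 3 * sqrt(mu))
})

test_that("a log(2) covariate effect doubles the observed fill rate", {
  cfg <- sim_config(n_patients = 5000, baseline_intensity = 0.002,
                    true_log_hazards = c(inpatient = log(2)),
                    factor_prevalences = c(inpatient = 0.3),
                    med_episode_rates = c(nsaid = 0),
                    hp_positive_fraction = 0, seed = 8)
  set.seed(cfg$seed)
  pat <- generate_patients(cfg)
  fills <- simulate_fill_process(pat, simulate_med_fills(pat, cfg), cfg)
  # drop the guaranteed initial fill: it is not part of the intensity process
  counts <- table(factor(fills$patient_id, levels = pat$patient_id)) - 1L
  rate1 <- sum(counts[pat$inpatient == 1]) / sum(pat$inpatient == 1)
  rate0 <- sum(counts[pat$inpatient == 0]) / sum(pat$inpatient == 0)
  expect_lt(abs(rate1 / rate0 - 2), 0.15)
})

test_that("thinning yields exponential first event times in each covariate group", {
  lam0 <- 0.003
  cfg <- sim_config(n_patients = 10000, baseline_intensity = lam0,
                    true_log_hazards = c(inpatient = log(2)),
                    factor_prevalences = c(inpatient = 0.5),
                    med_episode_rates = c(nsaid = 0),
                    days_supply_values = c(60L, 90L),  # initial fill (30d) stays identifiable
                    days_supply_probs = c(0.5, 0.5),
                    hp_positive_fraction = 0, seed = 13)
  set.seed(cfg$seed)
  pat <- generate_patients(cfg)
  fills <- simulate_fill_process(pat, simulate_med_fills(pat, cfg), cfg)
  proc <- fills[fills$days_supply != 30L, ]
  rel <- proc$day - pat$index_day[match(proc$patient_id, pat$patient_id)]
  first <- tapply(rel, proc$patient_id, min) + 0.5  # day-midpoint correction
  H <- cfg$horizon_days
  for (z in 0:1) {
    rate <- lam0 * 2^z
    ids <- pat$patient_id[pat$inpatient == z]
    x <- first[as.character(ids)]
    x <- x[!is.na(x)]
    cdf <- function(t) (1 - exp(-rate * t)) / (1 - exp(-rate * H))
    D <- suppressWarnings(stats::ks.test(x, cdf))$statistic
    expect_lt(D, 1.63 / sqrt(length(x)))  # alpha = 0.01 critical value
  }
})

test_that("censoring event times are exponential with the configured rate", {
  r <- 0.5  # events/year
  cfg <- sim_config(n_patients = 4000, horizon_days = 365 * 40,
                    censor_rates = c(new_indication = r),
                    true_log_hazards = c(noise = 0),
                    factor_prevalences = c(noise = 0.5),
                    med_episode_rates = c(nsaid = 0),
                    hp_positive_fraction = 0, seed = 17)
  set.seed(cfg$seed)
  pat <- generate_patients(cfg)
  ev <- simulate_censoring_events(pat, cfg)
  rel <- ev$diagnoses$day - pat$index_day[match(ev$diagnoses$patient_id, pat$patient_id)]
  expect_lt(abs(mean(rel) - 365.25 / r), 40)

  cfg0 <- sim_config(n_patients = 200, censor_rates = c(new_indication = 0),
                     hp_positive_fraction = 0, endoscopy_followup_rate = 0,
                     seed = 17)
  set.seed(17)
  pat0 <- generate_patients(cfg0)
  ev0 <- simulate_censoring_events(pat0, cfg0)
  expect_equal(nrow(ev0$diagnoses), 0L)
  expect_equal(nrow(ev0$tests), 0L)
})

test_that("hp_positive_fraction = 1 gives every patient an H. pylori result", {
  cfg <- sim_config(n_patients = 150, hp_positive_fraction = 1, seed = 19)
  tab <- simulate_ehr(cfg)
  hp <- tab$tests[tab$tests$test == "h_pylori", ]
  expect_setequal(hp$patient_id, tab$patients$patient_id)
})

test_that("no outcome or censoring event predates the index date", {
  cfg <- sim_config(n_patients = 250, seed = 23)
  tab <- simulate_ehr(cfg)
  idx <- tab$patients$index_day[match(tab$fills$patient_id, tab$patients$patient_id)]
  ppi <- tab$fills$drug_class == "ppi"
  expect_true(all(tab$fills$day[ppi] >= idx[ppi]))
  idx_d <- tab$patients$index_day[match(tab$diagnoses$patient_id, tab$patients$patient_id)]
  expect_true(all(tab$diagnoses$day >= idx_d))
  idx_t <- tab$patients$index_day[match(tab$tests$patient_id, tab$patients$patient_id)]
  expect_true(all(tab$tests$day >= idx_t))
})

test_that("tables survive a write/read round trip", {
  cfg <- sim_config(n_patients = 40, seed = 29)
  tab <- simulate_ehr(cfg)
  dir <- withr::local_tempdir()
  write_ehr_tables(tab, dir)
  back <- read_ehr_tables(dir)
  for (nm in c("patients", "diagnoses", "fills", "tests")) {
    expect_equal(back[[nm]], tab[[nm]], ignore_attr = TRUE)
  }
})
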