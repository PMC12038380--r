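#' Analysis run configuration
#'
#' Bundles everything one end-to-end run needs: where the input tables come
#' from (a directory of the four flat tables, or a simulation config to
#' generate them), the analysis mode, an optional sensitivity variant, the
#' model covariates, and the factors to attribute.
#'
#' @param sim a [sim_config()] used when `tables_dir` is `NULL`.
#' @param tables_dir directory with `patients.tsv`, `diagnoses.tsv`,
#'   `fills.tsv`, `tests.tsv`; overrides simulation when given.
#' @param analysis `"primary"` or `"gastroprotection"` (the secondary analysis:
#'   guideline-qualifying fills are approved and patients are censored at
#'   first qualification).
#' @param sensitivity one of `"none"`, `"followup_5y"`,
#'   `"post_endoscopy_60d_approved"`, `"restrict_2010_plus"`,
#'   `"frailty_recomputed"`.
#' @param covariates model covariates, default [default_covariates()].
#' @param med_classes drug classes used as time-varying exposures.
#' @param paf_factors factors for attributable-fraction curves; `NULL` skips
#'   the PAF stage.
#' @param paf_variant estimator variant for [paf_curve()].
#' @param grace_days exposure grace period.
#' @param seed integer seed for simulation (and any resampling).
#' @param output_dir optional directory for [write_bundle()].
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       tables_dir = NULL,
                       analysis = c("primary", "gastroprotection"),
                       sensitivity = c("none", "followup_5y",
                                       "post_endoscopy_60d_approved",
                                       "restrict_2010_plus",
                                       "frailty_recomputed"),
                       covariates = default_covariates(),
                       med_classes = c("nsaid", "anticoagulant", "aspirin"),
                       paf_factors = "inpatient",
                       paf_variant = "cumulative_incidence",
                       grace_days = 30,
                       seed = 1L,
                       output_dir = NULL) {
  analysis <- match.arg(analysis)
  sensitivity <- match.arg(sensitivity)
  structure(list(sim = sim, tables_dir = tables_dir, analysis = analysis,
                 sensitivity = sensitivity, covariates = covariates,
                 med_classes = med_classes, paf_factors = paf_factors,
                 paf_variant = paf_variant, grace_days = grace_days,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: obtain the four tables (simulate or read), build
#' the cohort and attrition report, classify fills, derive censoring times,
#' expand counting-process intervals, fit the Andersen-Gill model, summarize
#' overuse, and (optionally) compute attributable-fraction curves. Identical
#' configuration and seed give identical output.
#'
#' @param config a [run_config()].
#' @return an object of class `ppi_bundle`: a list with `tables`, `cohort`,
#'   `attrition`, `classified`, `censor`, `intervals`, `fit`, `hr` (the
#'   aHR table), `describe`, `baseline_table`, `paf` (named list of curves),
#'   and `meta` (mode, sensitivity, seed, stage timings).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  stage <- function(name, expr) {
    r <- tryCatch(clock(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- r$secs
    r$value
  }

  sens <- config$sensitivity
  tables <- stage("tables", {
    if (!is.null(config$tables_dir)) read_ehr_tables(config$tables_dir)
    else simulate_ehr(config$sim, seed = config$seed)
  })
  study_start <- if (!is.null(tables$config)) tables$config$study_start else "1999-01-01"
  study_end <- if (!is.null(tables$config)) tables$config$study_end else "2022-12-31"

  cohort <- stage("cohort", build_cohort(tables))
  if (sens == "restrict_2010_plus") {
    yr <- study_year(cohort$index_day, study_start)
    drop <- cohort$eligible & yr < 2010L
    cohort$eligible[drop] <- FALSE
    cohort$exclusion_reason[drop] <- "index_before_2010"
  }
  attrition <- attrition_table(cohort)

  classified <- stage("classify", classify_fills(
    tables$fills, cohort, tables,
    gastroprotection = config$analysis == "gastroprotection",
    grace_days = config$grace_days,
    post_endoscopy_days = if (sens == "post_endoscopy_60d_approved") 60 else 0,
    study_start = study_start
  ))

  plan <- censor_plan(
    max_followup_days = if (sens == "followup_5y") 1825 else 1095,
    guideline_censoring = config$analysis == "gastroprotection",
    study_start = study_start, study_end = study_end
  )
  censor <- stage("censor", censor_times(cohort, tables, plan,
                                         grace_days = config$grace_days))

  frailty_col <- if (sens == "frailty_recomputed") "frailty_alt" else "frailty"
  intervals <- stage("intervals", build_intervals(
    cohort, classified, tables, censor,
    covariates = config$covariates, med_classes = config$med_classes,
    grace_days = config$grace_days, frailty_col = frailty_col
  ))

  fit <- stage("fit", ag_fit(intervals, covariates = config$covariates))
  desc <- stage("describe", describe_overuse(cohort, classified))
  base_tab <- describe_baseline(cohort, tables$patients)

  paf <- list()
  if (!is.null(config$paf_factors)) {
    paf <- stage("paf", {
      out <- lapply(config$paf_factors, function(f)
        paf_curve(fit, intervals, f, variant = config$paf_variant))
      names(out) <- config$paf_factors
      out
    })
  }

  bundle <- list(
    tables = tables, cohort = cohort, attrition = attrition,
    classified = classified, censor = censor, intervals = intervals,
    fit = fit, hr = fit$hr, describe = desc, baseline_table = base_tab,
    paf = paf,
    meta = list(analysis = config$analysis, sensitivity = sens,
                seed = config$seed, covariates = config$covariates,
                timings = unlist(timings))
  )
  class(bundle) <- "ppi_bundle"
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' Write a pipeline bundle as delimited text
#'
#' Emits the attrition table, baseline characteristics, classified fills,
#' counting-process intervals, the aHR table, overuse summaries, PAF curves
#' and a YAML metadata block. Output is deterministic given the bundle.
#'
#' @param bundle a `ppi_bundle` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(bundle$attrition, "attrition.tsv")
  wt(bundle$baseline_table, "baseline_characteristics.tsv")
  wt(bundle$classified, "classified_fills.tsv")
  wt(bundle$intervals, "counting_process.tsv")
  wt(bundle$hr, "hazard_ratios.tsv")
  wt(bundle$describe$summary, "overuse_summary.tsv")
  wt(bundle$describe$patient, "overuse_per_patient.tsv")
  wt(bundle$describe$prescribers, "prescriber_mix.tsv")
  for (f in names(bundle$paf)) {
    wt(as.data.frame(bundle$paf[[f]]), paste0("paf_", f, ".tsv"))
  }
  meta <- bundle$meta
  meta$timings <- NULL  # timings vary run to run; keep files reproducible
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}

#' @export
print.ppi_bundle <- function(x, ...) {
  cat(sprintf("PPI overuse pipeline bundle (%s analysis, sensitivity: %s)\n",
              x$meta$analysis, x$meta$sensitivity))
  s <- x$describe$summary
  cat(sprintf("  analytic cohort: %d patients; %d (%.0f%%) with exceeding fills\n",
              s$n_patients, s$n_any_exceed, 100 * s$prop_any_exceed))
  cat(sprintf("  counting process: %d rows, %d events\n",
              nrow(x$intervals), x$fit$n_events))
  invisible(x)
}
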