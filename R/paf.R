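#' Default time grid for attributable-fraction curves
#'
#' Daily resolution over the first 180 days (where the curves move fastest),
#' weekly thereafter.
#'
#' @param max_days end of the grid.
#' @return numeric vector of days.
#' @export
paf_grid <- function(max_days = 1095) {
  if (max_days <= 180) return(seq(1, max_days))
  c(seq(1, 180), seq(187, max_days, by = 7))
}

#' Standardized attributable-fraction engine
#'
#' Computes `PAF(t) = 1 - Fbar0(t) / Fbar(t)` where `Fbar(t)` averages
#' `g(Lambda_i(t))` over patients under the factual linear predictors and
#' `Fbar0(t)` under counterfactual ones. Each patient's cumulative intensity
#' accumulates piecewise over their covariate intervals:
#' `Lambda_i(t) = sum_rows exp(eta_row) * (Lambda0(min(stop, t)) -
#' Lambda0(min(start, t)))`, so time-varying covariate paths are respected.
#' `variant = "cumulative_incidence"` uses `g(x) = 1 - exp(-x)` (probability
#' of at least one event by `t`); `variant = "expected_events"` uses
#' `g(x) = x` (mean cumulative event count).
#'
#' @param cumhaz baseline cumulative intensity: a function of time, or a
#'   data.frame with `time` and `cumhaz` (treated as a right-continuous step
#'   function starting at 0).
#' @param id patient identifier per row.
#' @param start,stop interval bounds per row (`Inf` allowed for the last row).
#' @param eta,eta0 factual and counterfactual linear predictors per row.
#' @param grid evaluation times.
#' @param variant `"cumulative_incidence"` or `"expected_events"`.
#' @return data.frame `time`, `paf` (`NA` where the factual standardized
#'   quantity is zero, where the fraction is undefined).
#' @export
paf_standardize <- function(cumhaz, id, start, stop, eta, eta0, grid,
                            variant = c("cumulative_incidence", "expected_events")) {
  variant <- match.arg(variant)
  L <- if (is.function(cumhaz)) cumhaz else {
    stats::stepfun(cumhaz$time, c(0, cumhaz$cumhaz))
  }
  g <- if (variant == "cumulative_incidence") function(x) 1 - exp(-x) else identity
  tmax <- max(grid)
  La <- L(pmin(start, tmax))
  Lb <- L(pmin(stop, tmax))
  w <- exp(eta)
  w0 <- exp(eta0)
  fid <- factor(id)
  paf <- vapply(grid, function(t) {
    Lt <- L(t)
    inc <- pmin(Lb, Lt) - pmin(La, Lt)
    lam <- rowsum(w * inc, fid, reorder = FALSE)
    lam0 <- rowsum(w0 * inc, fid, reorder = FALSE)
    fbar <- mean(g(lam))
    if (fbar <= 0) return(NA_real_)
    1 - mean(g(lam0)) / fbar
  }, numeric(1))
  data.frame(time = grid, paf = paf)
}

#' Adjusted time-to-event population attributable fraction curve
#'
#' The proportion of exceeding PPI prescriptions that would be eliminated if
#' patients with the factor were treated like patients without it: the cohort
#' is standardized under the fitted model twice — factually, and with the
#' factor set to its reference level in every covariate path — and the curve
#' is one minus their ratio over time. Time-varying exposures stay at their
#' observed paths except for the factor under study.
#'
#' @param fit a converged [ag_fit()].
#' @param intervals the counting-process data the model was fit on (or any
#'   compatible covariate-path data).
#' @param factor name of the model covariate to attribute.
#' @param grid evaluation times; default [paf_grid()] to the data horizon.
#' @param variant see [paf_standardize()]; the cumulative-incidence variant is
#'   the default (its rise-and-fall shape matches how attributable fractions
#'   behave when exposed patients saturate early).
#' @param ref reference level the factor is set to, default 0.
#' @return an object of class `paf_curve`: data.frame `time`, `paf` with
#'   attributes `factor`, `variant`.
#' @export
paf_curve <- function(fit, intervals, factor,
                      grid = NULL,
                      variant = c("cumulative_incidence", "expected_events"),
                      ref = 0) {
  variant <- match.arg(variant)
  if (!factor %in% fit$covariates) {
    stop("factor is not a model covariate: ", factor, call. = FALSE)
  }
  if (is.null(grid)) grid <- paf_grid(max(intervals$stop))
  beta <- fit$coefficients
  X <- as.matrix(intervals[, fit$covariates, drop = FALSE])
  eta <- drop(X %*% beta)
  X0 <- X
  X0[, factor] <- ref
  eta0 <- drop(X0 %*% beta)

  # extend each patient's final interval so standardization covers the grid
  stop_ <- intervals$stop
  o <- order(intervals$patient_id, intervals$stop)
  last <- o[!duplicated(intervals$patient_id[o], fromLast = TRUE)]
  stop_[last] <- Inf

  out <- paf_standardize(breslow_stepfun(fit), intervals$patient_id,
                         intervals$start, stop_, eta, eta0, grid, variant)
  attr(out, "factor") <- factor
  attr(out, "variant") <- variant
  class(out) <- c("paf_curve", class(out))
  out
}

#' Patient-resampling bootstrap bands for a PAF curve
#'
#' Resamples patients with replacement, refits the model and recomputes the
#' curve per replicate, and returns percentile 2.5/97.5 bands. Replicates
#' whose fit fails (for example a degenerate resample with no events) are
#' dropped and counted; a warning is raised when more than 5% drop.
#'
#' @param intervals counting-process data.
#' @param factor factor to attribute.
#' @param covariates model covariates.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed; bands are reproducible given the seed.
#' @param grid,variant,ref as in [paf_curve()].
#' @param cluster patient identifier column.
#' @return a `paf_curve` data.frame with `paf` (point estimate on the original
#'   data), `ci_low`, `ci_high`, and attributes `n_boot`, `n_dropped`, `seed`.
#' @export
paf_bootstrap <- function(intervals, factor,
                          covariates = attr(intervals, "covariates"),
                          n_boot = 200, seed = 1,
                          grid = NULL,
                          variant = c("cumulative_incidence", "expected_events"),
                          ref = 0, cluster = "patient_id") {
  variant <- match.arg(variant)
  stopifnot(n_boot >= 2)
  if (is.null(grid)) grid <- paf_grid(max(intervals$stop))
  fit <- ag_fit(intervals, covariates = covariates, cluster = cluster)
  point <- paf_curve(fit, intervals, factor, grid = grid, variant = variant, ref = ref)

  ids <- unique(intervals[[cluster]])
  rows_by <- split(seq_len(nrow(intervals)), factor(intervals[[cluster]], levels = ids))
  set.seed(as.integer(seed))
  mat <- matrix(NA_real_, length(grid), n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample.int(length(ids), replace = TRUE)
    take <- rows_by[pick]
    dat <- intervals[unlist(take, use.names = FALSE), , drop = FALSE]
    dat[[cluster]] <- rep.int(seq_along(pick), lengths(take))
    curve_b <- tryCatch({
      fb <- ag_fit(dat, covariates = covariates, cluster = cluster)
      paf_curve(fb, dat, factor, grid = grid, variant = variant, ref = ref)$paf
    }, error = function(e) NULL)
    if (is.null(curve_b)) dropped <- dropped + 1L else mat[, b] <- curve_b
  }
  if (dropped > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates dropped (non-convergence)",
                    dropped, n_boot), call. = FALSE)
  }
  qs <- apply(mat, 1L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- point
  out$ci_low <- qs[1L, ]
  out$ci_high <- qs[2L, ]
  attr(out, "n_boot") <- n_boot
  attr(out, "n_dropped") <- dropped
  attr(out, "seed") <- seed
  out
}

#' Peak of a PAF curve
#'
#' @param curve a `paf_curve` (or any data.frame with `time` and `paf`).
#' @return `list(time, value)` at the curve maximum; ties and plateaus resolve
#'   to the earliest grid time.
#' @export
paf_peak <- function(curve) {
  ok <- which(!is.na(curve$paf))
  if (!length(ok)) return(list(time = NA_real_, value = NA_real_))
  i <- ok[which.max(curve$paf[ok])]
  list(time = curve$time[i], value = curve$paf[i])
}

#' Plot a PAF curve
#'
#' @param curve a `paf_curve`, optionally with bootstrap bands.
#' @return a ggplot object.
#' @export
plot_paf <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$paf))
  if (all(c("ci_low", "ci_high") %in% names(curve))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                                  alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Days since PUD diagnosis",
                  y = "Adjusted population attributable fraction",
                  title = attr(curve, "factor"))
}
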