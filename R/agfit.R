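# Internal engine for the counting-process partial likelihood.
#
# Risk sets R(t) = {rows: start < t <= stop} are swept with sorted cumulative
# sums rather than per-event scans: a row contributes to every event time in
# (start, stop], so S0/S1/S2 at the j-th event time are differences of
# cumulative sums taken at findInterval() cutpoints. Breslow tie handling
# throughout.

ag_prepare <- function(data, covariates) {
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  start <- as.numeric(data$start)
  stop_ <- as.numeric(data$stop)
  event <- as.integer(data$event)
  if (any(stop_ <= start)) stop("invalid intervals: need start < stop", call. = FALSE)
  if (!any(event == 1L)) stop("no events in the data", call. = FALSE)
  erow <- which(event == 1L)
  tt <- sort(unique(stop_[erow]))
  d <- as.numeric(table(factor(stop_[erow], levels = tt)))
  list(
    X = X, start = start, stop = stop_, event = event, erow = erow,
    tt = tt, d = d, m = length(tt),
    ord_s = order(start), ord_t = order(stop_),
    cnt_in = findInterval(tt, sort(start), left.open = TRUE),
    cnt_out = findInterval(tt, sort(stop_), left.open = TRUE),
    ev_tidx = match(stop_[erow], tt),
    sum_x_ev = colSums(X[erow, , drop = FALSE]),
    sum_eta_rows = erow
  )
}

# cumulative-sum lookup with zero at index 0
cs_at <- function(cs, k) ifelse(k == 0L, 0, cs[pmax(k, 1L)])

ag_eval <- function(prep, beta, need_info = TRUE) {
  X <- prep$X
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)

  cw_s <- cumsum(w[prep$ord_s]); cw_t <- cumsum(w[prep$ord_t])
  S0 <- cs_at(cw_s, prep$cnt_in) - cs_at(cw_t, prep$cnt_out)

  WX <- w * X
  S1 <- matrix(0, prep$m, p)
  for (k in seq_len(p)) {
    ck_s <- cumsum(WX[prep$ord_s, k]); ck_t <- cumsum(WX[prep$ord_t, k])
    S1[, k] <- cs_at(ck_s, prep$cnt_in) - cs_at(ck_t, prep$cnt_out)
  }
  Zbar <- S1 / S0

  loglik <- sum(eta[prep$erow]) - sum(prep$d * log(S0))
  grad <- prep$sum_x_ev - colSums(Zbar * prep$d)

  info <- NULL
  if (need_info) {
    info <- matrix(0, p, p)
    for (k in seq_len(p)) {
      for (l in k:p) {
        q <- WX[, k] * X[, l]
        cq_s <- cumsum(q[prep$ord_s]); cq_t <- cumsum(q[prep$ord_t])
        S2kl <- cs_at(cq_s, prep$cnt_in) - cs_at(cq_t, prep$cnt_out)
        v <- sum(prep$d * (S2kl / S0 - Zbar[, k] * Zbar[, l]))
        info[k, l] <- v; info[l, k] <- v
      }
    }
  }
  list(loglik = loglik, grad = grad, info = info, S0 = S0, Zbar = Zbar,
       w = w, eta = eta)
}

# per-row score residuals, then collapsed within clusters
ag_score_residuals <- function(prep, ev, cluster) {
  dlam <- prep$d / ev$S0
  p <- ncol(prep$X)
  cumA <- c(0, cumsum(dlam))
  cumB <- rbind(0, apply(ev$Zbar * dlam, 2, cumsum))
  hi <- findInterval(prep$stop, prep$tt)
  lo <- findInterval(prep$start, prep$tt)
  A <- cumA[hi + 1L] - cumA[lo + 1L]
  B <- cumB[hi + 1L, , drop = FALSE] - cumB[lo + 1L, , drop = FALSE]
  U <- -ev$w * (prep$X * A - B)
  idx <- match(prep$stop[prep$erow], prep$tt)
  U[prep$erow, ] <- U[prep$erow, , drop = FALSE] +
    prep$X[prep$erow, , drop = FALSE] - ev$Zbar[idx, , drop = FALSE]
  rowsum(U, group = cluster, reorder = FALSE)
}

#' Partial log-likelihood of the recurrent-event intensity model
#'
#' Evaluates the Cox/Andersen-Gill counting-process partial likelihood with
#' Breslow tie handling at a given coefficient vector. Exposed mainly so the
#' likelihood itself can be inspected and property-tested (for example,
#' refinement invariance under extra interval cutpoints).
#'
#' @param data counting-process data (`start`, `stop`, `event`, covariates).
#' @param covariates covariate column names.
#' @param beta coefficient vector (original covariate scale).
#' @return the partial log-likelihood (scalar).
#' @export
ag_partial_loglik <- function(data, covariates, beta) {
  prep <- ag_prepare(data, covariates)
  ag_eval(prep, beta, need_info = FALSE)$loglik
}

#' Fit the Andersen-Gill recurrent-event model
#'
#' Maximizes the counting-process partial likelihood (Breslow ties) by
#' Newton-Raphson with step-halving, on internally standardized covariates.
#' Inference uses the cluster-robust sandwich variance with score residuals
#' aggregated within patients, which accounts for within-patient correlation
#' of recurrent events; naive (inverse-information) variances are retained for
#' diagnostics. Reported hazard ratios are `exp(beta)` with 95% Wald intervals
#' on the robust standard errors.
#'
#' @param data counting-process data from [build_intervals()] (or any
#'   data.frame with `start`, `stop`, `event` and covariate columns).
#' @param covariates covariate names; defaults to the data's `covariates`
#'   attribute.
#' @param cluster column identifying independent sampling units (patients).
#' @param init optional starting coefficients (original scale).
#' @param max_iter,tol_grad,tol_loglik Newton-Raphson controls: stop when the
#'   gradient sup-norm falls below `tol_grad` or the relative log-likelihood
#'   change falls below `tol_loglik`.
#' @return an object of class `ag_fit`: coefficients, `hr` table (factor, aHR,
#'   CI bounds, robust and naive SEs, z, p), `naive_cov`, `robust_cov`,
#'   `loglik`, `loglik_null`, Breslow `baseline` (event times, hazard
#'   increments, cumulative hazard at reference covariates), convergence
#'   diagnostics, and bookkeeping fields.
#' @export
ag_fit <- function(data, covariates = attr(data, "covariates"),
                   cluster = "patient_id", init = NULL,
                   max_iter = 30L, tol_grad = 1e-9, tol_loglik = 1e-12) {
  if (is.null(covariates)) stop("covariates must be given (or set as attribute)", call. = FALSE)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  prep <- ag_prepare(data, covariates)
  p <- ncol(prep$X)

  ctr <- colMeans(prep$X)
  scl <- apply(prep$X, 2, stats::sd)
  flat <- scl == 0 | !is.finite(scl)
  if (any(flat)) {
    stop("covariate(s) constant across the data: ",
         paste(covariates[flat], collapse = ", "), call. = FALSE)
  }
  prep_s <- prep
  prep_s$X <- sweep(sweep(prep$X, 2, ctr, "-"), 2, scl, "/")
  prep_s$sum_x_ev <- colSums(prep_s$X[prep$erow, , drop = FALSE])

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init) * scl
  ev <- ag_eval(prep_s, beta)
  ll <- ev$loglik
  iter <- 0L
  converged <- max(abs(ev$grad)) < tol_grad
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    delta <- solve(ev$info, ev$grad)
    step <- 1
    # tolerate rounding noise in the loglik near the optimum: its absolute
    # error scales with |ll|, so the acceptance slack must too
    slack <- 1e-9 * (abs(ll) + 1)
    repeat {
      cand <- beta + step * delta
      ev_new <- ag_eval(prep_s, cand)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ll - slack) break
      step <- step / 2
      if (step < 2^-20) stop("step-halving failed: partial likelihood not improving",
                             call. = FALSE)
    }
    rel_change <- abs(ev_new$loglik - ll) / (abs(ll) + 1e-8)
    beta <- cand; ev <- ev_new; ll <- ev$loglik
    # gradient is the primary criterion; a loglik stall only counts once the
    # gradient is already small (the loglik hits its noise floor first)
    if (max(abs(ev$grad)) < tol_grad ||
        (rel_change < tol_loglik && max(abs(ev$grad)) < 1e-6)) converged <- TRUE
  }
  grad_norm <- max(abs(ev$grad))
  if (!converged || grad_norm > 1e-6) {
    stop(sprintf(
      "Andersen-Gill fit did not converge: %d iterations, gradient sup-norm %.3e, loglik %.6f",
      iter, grad_norm, ll), call. = FALSE)
  }
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("possible separation (monotone likelihood): very large coefficient(s)",
            call. = FALSE)
  }

  naive_s <- solve(ev$info)
  G <- ag_score_residuals(prep_s, ev, data[[cluster]])
  meat <- crossprod(G)
  robust_s <- naive_s %*% meat %*% naive_s

  beta_o <- beta / scl
  names(beta_o) <- covariates
  sc_out <- outer(1 / scl, 1 / scl)
  naive_cov <- naive_s * sc_out
  robust_cov <- robust_s * sc_out
  dimnames(naive_cov) <- dimnames(robust_cov) <- list(covariates, covariates)

  se_r <- sqrt(diag(robust_cov))
  se_n <- sqrt(diag(naive_cov))
  z <- beta_o / se_r
  hr <- data.frame(
    factor = covariates,
    ahr = exp(beta_o),
    ci_low = exp(beta_o - 1.959963984540054 * se_r),
    ci_high = exp(beta_o + 1.959963984540054 * se_r),
    se_robust = se_r,
    se_naive = se_n,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  # Breslow baseline at the reference covariate level (all zero)
  shift <- sum(beta_o * ctr)
  dlam0 <- (prep$d / ev$S0) * exp(-shift)
  baseline <- data.frame(time = prep$tt, hazard = dlam0, cumhaz = cumsum(dlam0))

  ll_null <- ag_eval(prep_s, rep(0, p), need_info = FALSE)$loglik
  out <- list(
    coefficients = beta_o, hr = hr,
    naive_cov = naive_cov, robust_cov = robust_cov,
    loglik = ll, loglik_null = ll_null,
    baseline = baseline,
    n_rows = nrow(data), n_events = sum(prep$d),
    n_clusters = length(unique(data[[cluster]])),
    iter = iter, grad_norm = grad_norm,
    converged = TRUE, separation = separation,
    covariates = covariates, center = ctr, scale = scl,
    cluster = cluster
  )
  class(out) <- "ag_fit"
  out
}

#' @export
coef.ag_fit <- function(object, ...) object$coefficients

#' @export
vcov.ag_fit <- function(object, ...) object$robust_cov

#' @export
logLik.ag_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.ag_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Andersen-Gill recurrent-event model: %d events, %d patients, %d rows\n",
    x$n_events, x$n_clusters, x$n_rows))
  cat(sprintf("partial loglik %.4f (null %.4f), %d Newton iterations, |grad| %.1e\n",
              x$loglik, x$loglik_null, x$iter, x$grad_norm))
  tab <- x$hr
  tab$ahr <- round(tab$ahr, digits)
  tab$ci <- sprintf(paste0("%.", digits, "f-%.", digits, "f"), tab$ci_low, tab$ci_high)
  print(tab[, c("factor", "ahr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Breslow baseline cumulative intensity
#'
#' The nondecreasing step function `Lambda0(t) = sum over event times <= t of
#' d_j / sum at-risk exp(beta'Z)`, evaluated at the reference covariate level.
#'
#' @param fit an `ag_fit`.
#' @return `breslow_baseline()` returns a data.frame (`time`, `hazard`,
#'   `cumhaz`); `breslow_stepfun()` the corresponding right-continuous step
#'   function with `Lambda0(0) = 0`.
#' @export
breslow_baseline <- function(fit) fit$baseline

#' @rdname breslow_baseline
#' @export
breslow_stepfun <- function(fit) {
  b <- fit$baseline
  stats::stepfun(b$time, c(0, b$cumhaz))
}

#' Backward elimination to a parsimonious model
#'
#' Repeatedly drops the covariate with the largest robust Wald p-value above
#' `alpha` and refits, until every retained covariate has p <= `alpha`. The
#' elimination path is returned so the procedure is auditable; it is a
#' conventional default, not a canonical one, and can be replaced wholesale.
#'
#' @param data counting-process data.
#' @param candidates candidate covariate names.
#' @param cluster cluster column.
#' @param alpha retention threshold, default 0.05.
#' @return `list(retained, path, fit)`; `fit` is `NULL` when nothing is
#'   retained, and `path` logs each dropped covariate with its p-value.
#' @export
ag_select <- function(data, candidates, cluster = "patient_id", alpha = 0.05) {
  current <- candidates
  path <- data.frame(step = integer(), dropped = character(), p = numeric(),
                     stringsAsFactors = FALSE)
  step <- 0L
  fit <- NULL
  while (length(current)) {
    fit <- ag_fit(data, covariates = current, cluster = cluster)
    pv <- fit$hr$p
    worst <- which.max(pv)
    if (pv[worst] <= alpha) {
      return(list(retained = current, path = path, fit = fit))
    }
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = current[worst],
                                   p = pv[worst], stringsAsFactors = FALSE))
    current <- current[-worst]
    fit <- NULL
  }
  list(retained = character(0), path = path, fit = NULL)
}
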