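# Independent oracles: naive risk-set enumeration for the counting-process
# partial likelihood and Breslow increments. Deliberately written as plain
# double loops over event times and rows, sharing no code with the package's
# cumulative-sum sweep.

brute_loglik <- function(data, covariates, beta) {
  X <- as.matrix(data[, covariates, drop = FALSE])
  eta <- drop(X %*% beta)
  tt <- sort(unique(data$stop[data$event == 1]))
  ll <- 0
  for (t in tt) {
    risk <- data$start < t & data$stop >= t
    ev <- data$event == 1 & data$stop == t
    ll <- ll + sum(eta[ev]) - sum(ev) * log(sum(exp(eta[risk])))
  }
  ll
}

brute_breslow <- function(data, covariates, beta) {
  X <- as.matrix(data[, covariates, drop = FALSE])
  eta <- drop(X %*% beta)
  tt <- sort(unique(data$stop[data$event == 1]))
  vapply(tt, function(t) {
    risk <- data$start < t & data$stop >= t
    sum(data$event == 1 & data$stop == t) / sum(exp(eta[risk]))
  }, numeric(1))
}

# refine counting-process rows at extra cut times (event stays on final piece)
split_intervals_at <- function(data, times) {
  out <- list()
  for (i in seq_len(nrow(data))) {
    r <- data[i, , drop = FALSE]
    cuts <- sort(unique(times[times > r$start & times < r$stop]))
    bounds <- c(r$start, cuts, r$stop)
    for (k in seq_len(length(bounds) - 1L)) {
      rr <- r
      rr$start <- bounds[k]
      rr$stop <- bounds[k + 1L]
      rr$event <- if (k == length(bounds) - 1L) r$event else 0L
      out[[length(out) + 1L]] <- rr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 4-row toy with a finite maximum: two events, mixed covariate groups
toy_finite <- function() {
  d <- data.frame(
    patient_id = 1:4,
    start = 0, stop = c(1, 2, 3, 3),
    event = c(1L, 1L, 0L, 0L),
    z = c(1, 0, 1, 0)
  )
  attr(d, "covariates") <- "z"
  d
}

# 3-patient toy: A event t=2 (z=1), B censored t=3 (z=0), C event t=4 (z=0);
# hand-enumerated loglik is beta - log(exp(beta) + 2)
toy_three <- function() {
  d <- data.frame(
    patient_id = 1:3,
    start = 0, stop = c(2, 3, 4),
    event = c(1L, 0L, 1L),
    z = c(1, 0, 0)
  )
  attr(d, "covariates") <- "z"
  d
}
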