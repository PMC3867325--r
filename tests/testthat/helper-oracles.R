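# Independent oracles: naive re-implementations used only to check the
# package's computational paths. They deliberately share no code with R/.

# Product-limit estimator by an explicit loop over distinct times.
naive_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group logrank by direct summation over risk sets with the
# hypergeometric variance.
naive_logrank <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- c(event1, event2)
  g1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  ets <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ets) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
       O = O, E = E, V = V)
}

# Nearest-rank percentiles 25..75 by direct enumeration.
naive_quartile_percentiles <- function(values) {
  srt <- sort(values)
  n <- length(values)
  out <- numeric(0)
  for (p in 25:75) {
    v <- srt[ceiling(p * n / 100)]
    if (!length(out) || v != out[length(out)]) out <- c(out, v)
  }
  out
}

# Exhaustive cutoff scan: enumerate candidates, logrank each split, pick the
# minimal p with the closest-to-median-then-smaller tie-break.
naive_cutoff_scan <- function(values, time, event) {
  cands <- naive_quartile_percentiles(values)
  best <- NULL
  med <- median(values)
  for (cc in cands) {
    low <- values <= cc
    if (!any(low) || all(low)) next
    lr <- naive_logrank(time[!low], event[!low], time[low], event[low])
    rec <- list(cutoff = cc, chisq = lr$chisq, p = lr$p,
                dist = abs(cc - med))
    if (is.null(best) ||
        rec$p < best$p ||
        (rec$p == best$p && rec$dist < best$dist) ||
        (rec$p == best$p && rec$dist == best$dist && rec$cutoff < best$cutoff))
      best <- rec
  }
  best
}

# Hand-written Cox log partial likelihood for untied event times, maximized
# numerically on a grid refined by optimize().
naive_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

naive_cox_beta <- function(x, time, event) {
  grid <- seq(-4, 4, by = 0.05)
  lls <- vapply(grid, naive_cox_loglik, 0, x = x, time = time, event = event)
  k <- which.max(lls)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  optimize(naive_cox_loglik, c(lo, hi), x = x, time = time, event = event,
           maximum = TRUE, tol = 1e-9)$maximum
}
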