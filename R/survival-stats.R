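# Core survival estimators and tests, thin wrappers around the survival
# package plus the pairwise rank randomness test.

#' Construct a validated survival vector
#'
#' @param time Follow-up times in months, positive and finite. Zero times
#'   are bumped to half the smallest positive time with a warning, so that
#'   every sample contributes risk time.
#' @param event Event indicators: 1 = death/progression, 0 = censored.
#' @return A `SurvivalVector` (list with `time`, `event`).
#' @export
survival_vector <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(event))
    stopf("time and event must have equal length",
          class = "survcutoff_validation_error")
  if (any(!is.finite(time)) || any(time < 0))
    stopf("survival times must be finite and non-negative",
          class = "survcutoff_validation_error")
  if (any(!event %in% c(0, 1)))
    stopf("event indicators must be 0/1", class = "survcutoff_validation_error")
  if (any(time == 0)) {
    pos <- time[time > 0]
    if (length(pos) == 0)
      stopf("all survival times are zero", class = "survcutoff_validation_error")
    warnf("%d zero survival time(s) bumped to half the smallest positive time",
          sum(time == 0))
    time[time == 0] <- min(pos) / 2
  }
  structure(list(time = time, event = event), class = "SurvivalVector")
}

as_Surv <- function(surv) survival::Surv(surv$time, surv$event)

#' Kaplan-Meier product-limit estimate
#'
#' Ties are handled by simultaneous multiplication at each distinct event
#' time, the standard product-limit convention.
#'
#' @param surv A [survival_vector()].
#' @return A `KMCurve`: data frame with `time` (distinct observed times,
#'   ascending), `n_risk`, `n_event`, `n_censor` and the survival estimate
#'   `surv`, starting from S(0) = 1.
#' @export
km_estimate <- function(surv) {
  stopifnot(inherits(surv, "SurvivalVector"))
  if (length(surv$time) == 0) stopf("empty survival vector")
  fit <- survival::survfit(as_Surv(surv) ~ 1, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Two-group logrank test
#'
#' The classical logrank statistic: over the distinct event times, observed
#' minus expected events in group A with the hypergeometric variance of the
#' risk-set table, squared and summed; chi-square with 1 df.
#'
#' @param groupA,groupB [survival_vector()]s for the two groups.
#' @return List with `chisq`, `p` (and the observed/expected table as
#'   attribute `"table"`).
#' @export
logrank_test <- function(groupA, groupB) {
  stopifnot(inherits(groupA, "SurvivalVector"), inherits(groupB, "SurvivalVector"))
  if (length(groupA$time) == 0 || length(groupB$time) == 0)
    stopf("both groups must be non-empty")
  if (sum(groupA$event) + sum(groupB$event) == 0)
    stopf("no events in either group: logrank undefined",
          class = "survcutoff_degenerate_error")
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  grp <- rep(c(0L, 1L), c(length(groupA$time), length(groupB$time)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  res <- list(chisq = unname(sd$chisq),
              p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  attr(res, "table") <- data.frame(n = sd$n, observed = sd$obs, expected = sd$exp)
  res
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for
#' tied event times (the default of the survival package, so results are
#' reproducible bit-wise across runs). Reported p-values are Wald tests per
#' covariate; the global score statistic is exposed because on a tie-free
#' binary split it equals the logrank chi-square.
#'
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (one column per covariate; no covariate may be constant).
#' @param surv A [survival_vector()].
#' @return A `CoxResult`: data frame `coefficients` with per-covariate
#'   `beta`, `hr`, `ci_low`, `ci_high` (95% Wald), `se`, `p`; plus `n`,
#'   `n_events`, `score_chisq` and the fitted `coxph` object.
#' @export
cox_fit <- function(covariates, surv) {
  stopifnot(inherits(surv, "SurvivalVector"))
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || any(colnames(x) == ""))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) < 1) stopf("need at least one covariate")
  if (nrow(x) != length(surv$time))
    stopf("covariate rows must match the survival vector",
          class = "survcutoff_validation_error")
  const <- apply(x, 2, function(v) length(unique(v)) < 2)
  if (any(const))
    stopf("degenerate covariate '%s' is constant", colnames(x)[const][1],
          class = "survcutoff_degenerate_covariate_error")
  if (sum(surv$event) < ncol(x))
    stopf("fewer events (%d) than covariates (%d)", sum(surv$event), ncol(x),
          class = "survcutoff_degenerate_error")
  fit <- withCallingHandlers(
    survival::coxph(as_Surv(surv) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        stopf("monotone partial likelihood (perfect separation); coefficient for '%s' diverges",
              colnames(x)[which.max(abs(stats::coef(
                suppressWarnings(survival::coxph(as_Surv(surv) ~ x)))))],
              class = "survcutoff_nonconvergence_error")
      }
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  coefs <- data.frame(term = colnames(x), beta = beta, hr = exp(beta),
                      ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                      se = se, p = 2 * pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = fit$n, n_events = fit$nevent,
                 score_chisq = unname(fit$score), fit = fit),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf("Cox model: n = %d, events = %d, score chi-square = %.3f\n",
              x$n, x$n_events, x$score_chisq))
  df <- x$coefficients
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-16s HR = %.2f (%.2f-%.2f), p = %.2g\n", df$term[i],
                df$hr[i], df$ci_low[i], df$ci_high[i], df$p[i]))
  invisible(x)
}

# Exact null distribution of the number of inversions of a permutation of n
# (Mahonian numbers), as probabilities indexed 0..choose(n,2).
inversion_distribution <- function(n) {
  dp <- 1
  for (i in seq_len(n)) {
    new <- numeric(length(dp) + i - 1)
    for (k in 0:(i - 1))
      new[k + seq_along(dp)] <- new[k + seq_along(dp)] + dp
    dp <- new
  }
  dp / sum(dp)
}

#' Pairwise rank randomness test
#'
#' Checks whether a clinical variable drifts along the assembly order of a
#' multi-cohort database. Each sample X is compared with all samples Y that
#' occur later in the list; under randomness the probability of X > Y is
#' 1/2. The statistic S = (#pairs with X > Y) - (#pairs with X < Y) is
#' referred to the Mann-Kendall-type normal approximation with variance
#' n(n-1)(2n+5)/18 and a continuity correction; for fewer than 10 tie-free
#' values the exact permutation distribution of S is used instead.
#'
#' @param values Numeric vector in database assembly order; missing values
#'   are dropped.
#' @return List with `fraction_concordant` (share of pairs with the earlier
#'   value larger, ties counting 1/2), `S`, `z` and the two-sided `p`.
#' @export
pairwise_rank_test <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stopf("need at least 3 non-missing values",
                   class = "survcutoff_validation_error")
  d <- outer(values, values, `-`)  # d[i,j] = X_i - X_j
  up <- upper.tri(d)               # pairs i < j
  conc <- sum(d[up] > 0)
  disc <- sum(d[up] < 0)
  ties <- sum(d[up] == 0)
  M <- n * (n - 1) / 2
  fraction <- (conc + ties / 2) / M
  S <- conc - disc
  if (n < 10 && ties == 0) {
    probs <- inversion_distribution(n)
    s_of <- 2 * (seq_along(probs) - 1) - M  # S for each inversion count
    p <- sum(probs[abs(s_of) >= abs(S)])
    v <- n * (n - 1) * (2 * n + 5) / 18
    z <- if (S == 0) 0 else (S - sign(S)) / sqrt(v)
  } else {
    v <- n * (n - 1) * (2 * n + 5) / 18
    z <- if (S == 0) 0 else (S - sign(S)) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(fraction_concordant = fraction, S = S, z = z, p = min(p, 1))
}

#' Summarize a cohort
#'
#' @param cohort A `Cohort` from [filter_cohort()].
#' @return List with `n`, `n_events`, `median_followup` (median observed
#'   time, in months, over all samples of the endpoint) and per-covariate
#'   completeness counts.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "Cohort"))
  if (ncol(cohort$expr) == 0) stopf("empty cohort")
  covs <- c("age", "sex", "smoking", "histology", "stage", "grade",
            "margins_negative", "chemo", "radio")
  completeness <- vapply(covs, function(f) sum(!is.na(cohort$clinical[[f]])), 0L)
  list(endpoint = cohort$endpoint,
       n = length(cohort$time),
       n_events = sum(cohort$event),
       median_followup = median(cohort$time),
       completeness = completeness)
}
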