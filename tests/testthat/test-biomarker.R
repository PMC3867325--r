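test_that("candidate cutoffs are the nearest-rank percentiles between the quartiles", {
  expect_equal(candidate_cutoffs(1:100), 25:75)
  expect_length(candidate_cutoffs(1:100), 51)
  expect_error(candidate_cutoffs(rep(5, 20)),
               class = "survcutoff_no_candidates_error")
  expect_error(candidate_cutoffs(1:5), class = "survcutoff_degenerate_error")

  # heavy ties: de-duplicated, bounded by the 75th percentile, matches
  # direct enumeration
  set.seed(3)
  v <- c(rep(0, 30), rlnorm(30, log(200), 1))
  cands <- candidate_cutoffs(v)
  expect_false(any(duplicated(cands)))
  expect_true(all(diff(cands) > 0))
  expect_equal(cands, naive_quartile_percentiles(v))
  expect_true(all(cands <= sort(v)[ceiling(75 * length(v) / 100)]))
})

test_that("a planted expression gap is recovered as the selected cutoff", {
  set.seed(50)
  n <- 80
  low_expr <- runif(n / 2, 50, 100)    # long survivors
  high_expr <- runif(n / 2, 200, 300)  # short survivors; gap in (100, 200)
  values <- c(low_expr, high_expr)
  rate <- c(rep(0.01, n / 2), rep(0.08, n / 2))
  time <- rexp(n, rate)
  res <- best_cutoff_analysis(values, survival_vector(time, rep(1, n)))
  # the selected cutoff separates the two planted components exactly
  expect_gte(res$selected_cutoff, max(low_expr))
  expect_lt(res$selected_cutoff, min(high_expr))
  expect_identical(c(res$n_low, res$n_high), c(40L, 40L))
  expect_gt(res$hr, 1)
  expect_lt(res$selected_p, 1e-6)
})

test_that("the scan equals an independent exhaustive oracle on random instances", {
  set.seed(60)
  for (i in 1:25) {
    n <- 60
    values <- rlnorm(n, log(300), 0.7)
    time <- rexp(n, 0.02 * exp(0.4 * (values > median(values))))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 3) next
    res <- best_cutoff_analysis(values, survival_vector(time, event))
    ref <- naive_cutoff_scan(values, time, event)
    expect_identical(res$selected_cutoff, ref$cutoff)
    expect_equal(res$selected_chisq, ref$chisq, tolerance = 1e-10)
    expect_equal(res$selected_p, ref$p, tolerance = 1e-10)
  }
})

test_that("strictly increasing transforms change cutoff values but not the split", {
  set.seed(61)
  n <- 70
  values <- rlnorm(n, log(300), 0.7)
  time <- rexp(n, 0.02 * exp(0.6 * (values > 250)))
  surv <- survival_vector(time, rbinom(n, 1, 0.85))
  base <- best_cutoff_analysis(values, surv)
  for (f in list(function(x) x^2, log, function(x) 3 * x + 11)) {
    tr <- best_cutoff_analysis(f(values), surv)
    expect_equal(tr$n_low, base$n_low)
    expect_equal(tr$n_high, base$n_high)
    expect_equal(tr$hr, base$hr, tolerance = 1e-9)
    expect_equal(tr$selected_p, base$selected_p, tolerance = 1e-12)
  }
})

test_that("signature scores are per-sample means of member probes", {
  m <- toy_matrix(c("a", "b", "c"), c("s1", "s2"),
                  c(10, 20, 30, 40, 7, 7))
  sig2 <- signature_definition("sig2", c("a", "b"))
  expect_equal(signature_score(m, sig2),
               c(s1 = mean(c(10, 30)), s2 = mean(c(20, 40))))
  expect_equal(unname(signature_score(m, signature_definition("one", "c"))),
               unname(m["c", ]))
  const <- toy_matrix(c("a", "b"), c("s1", "s2"), rep(5, 4))
  expect_true(all(signature_score(const, sig2) == 5))
  expect_message(partial <- signature_score(m, signature_definition("px", c("a", "zzz"))),
                 "1 of 2")
  expect_equal(unname(partial), unname(m["a", ]))
  expect_error(signature_score(m, signature_definition("none", "zzz")),
               class = "survcutoff_empty_signature_error")
  expect_error(signature_definition("dup", c("a", "a")),
               class = "survcutoff_validation_error")
})

test_that("signature files load into definitions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("signature_id\tprobe_id", "sigA\tp1", "sigA\tp2", "sigB\tp3"),
             path)
  sigs <- load_signatures(path)
  expect_named(sigs, c("sigA", "sigB"))
  expect_identical(sigs$sigA$probe_ids, c("p1", "p2"))
})

# A collection with a planted effect strong enough (or weak enough) to sit
# on either side of the significance gate.
gate_collection <- function(beta, n = 300, seed = 70) {
  sim <- simulate_collection(simulation_config(
    n_datasets = 1, samples_per_dataset = n, n_probes = 20,
    beta = beta, censoring_target = 0.15, seed = seed))
  integrate_datasets(sim$datasets, sim$clinical)
}

test_that("the multivariate block appears exactly when the gate is passed", {
  coll <- gate_collection(beta = log(2.5))
  strong <- validate_biomarker(coll, "probe_0001", cohort_filter("OS"),
                               covariates = c("sex", "stage"))
  expect_lt(strong$analysis$selected_p, 0.01)
  expect_false(is.null(strong$multivariate))
  expect_true("high" %in% strong$multivariate$coefficients$term)
  expect_lte(strong$multivariate$n, strong$n)

  null_coll <- gate_collection(beta = 0, seed = 71)
  weak <- validate_biomarker(null_coll, "probe_0002", cohort_filter("OS"),
                             covariates = c("sex", "stage"))
  expect_identical(is.null(weak$multivariate),
                   !(weak$analysis$selected_p < 0.01))
  # force the gate shut: even a strong marker yields no multivariate block
  gated <- validate_biomarker(coll, "probe_0001", cohort_filter("OS"),
                              covariates = c("sex", "stage"), gate = 1e-300)
  expect_null(gated$multivariate)
})

test_that("cohorts below 50 patients carry a small-cohort warning", {
  coll <- gate_collection(beta = log(2), n = 40, seed = 72)
  expect_warning(validate_biomarker(coll, "probe_0001", cohort_filter("OS")),
                 "below the usual inclusion floor")
})

test_that("per-dataset analysis reduces to the pooled result for one dataset", {
  coll <- gate_collection(beta = log(2), seed = 73)
  pooled <- validate_biomarker(coll, "probe_0001", cohort_filter("OS"))
  records <- per_dataset_analysis(coll, "probe_0001", cohort_filter("OS"))
  expect_identical(nrow(records), 1L)
  expect_equal(records$hr, pooled$analysis$hr, tolerance = 1e-12)
  expect_equal(records$cutoff, pooled$analysis$selected_cutoff)
  expect_equal(records$n, pooled$n)
})

test_that("degenerate datasets are skipped with a logged reason", {
  sim <- simulate_collection(simulation_config(
    n_datasets = 2, samples_per_dataset = c(150, 4), n_probes = 20,
    beta = log(2), seed = 74))
  coll <- integrate_datasets(sim$datasets, sim$clinical)
  records <- per_dataset_analysis(coll, "probe_0001", cohort_filter("OS"))
  expect_identical(records$dataset_id, "SIM01")
  skipped <- attr(records, "skipped")
  expect_identical(skipped$dataset_id, "SIM02")
  expect_gt(nchar(skipped$reason), 0)
  # all degenerate: error
  sim2 <- simulate_collection(simulation_config(
    n_datasets = 1, samples_per_dataset = 4, n_probes = 20, seed = 75))
  coll2 <- integrate_datasets(sim2$datasets, sim2$clinical)
  expect_error(per_dataset_analysis(coll2, "probe_0001", cohort_filter("OS")),
               class = "survcutoff_degenerate_error")
})

test_that("funnel spread shrinks as per-dataset sample size grows", {
  sizes <- c(50, 200, 800)
  spread <- vapply(seq_along(sizes), function(k) {
    sim <- simulate_collection(simulation_config(
      n_datasets = 3, samples_per_dataset = sizes[k], n_probes = 5,
      beta = log(2), censoring_target = 0.2, with_fp = FALSE,
      seed = 80 + k))
    coll <- integrate_datasets(sim$datasets, sim$clinical)
    rec <- per_dataset_analysis(coll, "probe_0001", cohort_filter("OS"))
    stats::sd(log(rec$hr))
  }, 0)
  expect_lt(spread[3], spread[1])
})
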