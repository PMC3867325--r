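test_that("expression TSVs round-trip through write and load at full precision", {
  d <- toy_dataset("GSEX", n_probes = 3, n_samples = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(d, path)
  d2 <- load_expression_dataset(path, "GSEX", "GPL96")
  expect_equal(d2$values, d$values)
  expect_identical(colnames(d2$values), colnames(d$values))
  expect_identical(dim(d2), c(3L, 2L))
})

test_that("malformed expression files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), path)
  expect_error(load_expression_dataset(path, "X"), "duplicate probe",
               class = "survcutoff_validation_error")

  writeLines(c("probe_id\ts1\ts2", "a\t1\t2", "b\tNA\t4"), path)
  err <- expect_error(load_expression_dataset(path, "X"),
                      class = "survcutoff_format_error")
  expect_match(conditionMessage(err), "probe 'b'")
  expect_match(conditionMessage(err), "sample 's1'")

  writeLines(c("probe_id\ts1\ts2", "a\t1\t2", "b\t-3\t4"), path)
  expect_error(load_expression_dataset(path, "X"), "negative",
               class = "survcutoff_format_error")
})

test_that("clinical loading types, normalizes vocabulary, and validates endpoints", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("dataset_id\tsample_id\tos_time\tos_event\tstage\thistology\tsex",
               "D1\ts1\t34.5\t1\tIIIa\tSCC\tM",
               "D1\ts2\t\t\t1\tadeno\tfemale"), path)
  ct <- load_clinical_table(path)
  expect_equal(ct$os_time[1], 34.5)
  expect_equal(ct$os_event[1], 1)
  expect_identical(ct$stage, c(3L, 1L))
  expect_identical(ct$histology, c("scc", "adeno"))
  expect_identical(ct$sex, c("male", "female"))
  expect_true(is.na(ct$os_time[2]) && is.na(ct$os_event[2]))

  writeLines(c("dataset_id\tsample_id\tos_time\tos_event",
               "D1\ts1\t10\t"), path)
  expect_error(load_clinical_table(path), "present together",
               class = "survcutoff_validation_error")
})

test_that("unmappable vocabulary tokens become missing with a warning, not an error", {
  raw <- data.frame(dataset_id = "D", sample_id = c("a", "b"),
                    os_time = c(5, 6), os_event = c(1, 0),
                    histology = c("adeno", "weird-token"))
  expect_warning(ct <- clinical_table(raw), "unmappable")
  expect_identical(ct$histology, c("adeno", NA))
})

test_that("time units are converted to months", {
  raw <- data.frame(dataset_id = "D", sample_id = "a",
                    os_time = 2, os_event = 1)
  expect_equal(clinical_table(raw, time_unit = "years")$os_time, 24)
  expect_equal(clinical_table(raw, time_unit = "days")$os_time, 2 / 30.44)
})

test_that("integration keeps only the probes common to all datasets", {
  m1 <- toy_matrix(c("a", "b", "c"), c("s1", "s2"), 1:6)
  m2 <- toy_matrix(c("b", "c", "d"), c("t1", "t2", "t3"), 1:9)
  d1 <- expression_dataset(m1, "D1"); d2 <- expression_dataset(m2, "D2")
  clin <- toy_clinical(rep(c("D1", "D2"), c(2, 3)),
                       c("s1", "s2", "t1", "t2", "t3"))
  coll <- integrate_datasets(list(d1, d2), clin)
  expect_setequal(coll$common_probes, c("b", "c"))
  expect_identical(unname(coll$n_samples), c(2L, 3L))
  # order independence
  coll2 <- integrate_datasets(list(d2, d1), clin)
  expect_setequal(coll2$common_probes, coll$common_probes)
  # single dataset: identity
  expect_setequal(integrate_datasets(list(d1), clin)$common_probes,
                  c("a", "b", "c"))
  # disjoint probes: explicit error
  m3 <- toy_matrix(c("x", "y", "z"), c("u1",  "u2"), 1:6)
  expect_error(integrate_datasets(list(d1, expression_dataset(m3, "D3")),
                                  clin),
               class = "survcutoff_empty_intersection_error")
})

test_that("samples without any survival endpoint are retained but flagged unusable", {
  d <- toy_dataset("D1", n_samples = 4, seed = 11)
  clin <- clinical_table(data.frame(
    dataset_id = "D1", sample_id = colnames(d$values),
    os_time = c(10, 20, NA, NA), os_event = c(1, 0, NA, NA)))
  coll <- integrate_datasets(list(d), clin)
  expect_identical(sum(coll$n_samples), 4L)
  expect_identical(coll$usable, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("cohort filtering honours endpoints, constraints and missingness", {
  d <- toy_dataset("D1", n_samples = 6, seed = 5)
  clin <- clinical_table(data.frame(
    dataset_id = "D1", sample_id = colnames(d$values),
    os_time = c(10, 20, 30, 40, NA, NA),
    os_event = c(1, 0, 1, 1, NA, NA),
    histology = c("adeno", "adeno", "scc", NA, "adeno", "scc")))
  coll <- integrate_datasets(list(d), clin)
  expect_equal(length(filter_cohort(coll, cohort_filter("OS"))$time), 4)
  # active filter drops missing-field samples
  adeno <- filter_cohort(coll, cohort_filter("OS", histology = "adeno"))
  expect_equal(length(adeno$time), 2)
  expect_error(filter_cohort(coll, cohort_filter("OS", histology = "large")),
               class = "survcutoff_empty_cohort_error")
  expect_error(filter_cohort(coll, cohort_filter("FP")),
               class = "survcutoff_empty_cohort_error")
})

test_that("adding a constraint never enlarges the cohort", {
  coll <- toy_collection(n_samples = 40, seed = 21)
  set.seed(99)
  for (i in 1:20) {
    base_f <- cohort_filter("OS", histology = sample(c("adeno", "scc"),
                                                     sample(1:2, 1)))
    n_base <- length(filter_cohort(coll, base_f)$time)
    f2 <- base_f
    f2$constraints$sex <- sample(c("male", "female"), 1)
    n_tight <- tryCatch(length(filter_cohort(coll, f2)$time),
                        survcutoff_empty_cohort_error = function(e) 0L)
    expect_lte(n_tight, n_base)
  }
})

test_that("probe quality follows the mean/max rules with high taking precedence", {
  expect_identical(classify_probe_quality(c(600, 600, 800)), "high")
  expect_identical(classify_probe_quality(c(rep(5, 19), 900)), "low")
  expect_identical(classify_probe_quality(c(200, 200, 900)), "intermediate")
  # mean < 100 but max > 1000: the high rule wins
  expect_identical(classify_probe_quality(c(10, 20, 1200)), "high")
  expect_error(classify_probe_quality(numeric(0)))
})

test_that("scaling intensities upward can only raise the quality tier", {
  tiers <- c(low = 1, intermediate = 2, high = 3)
  set.seed(31)
  for (i in 1:50) {
    v <- rlnorm(20, runif(1, log(20), log(800)), 1)
    expect_gte(tiers[classify_probe_quality(v * 10)],
               tiers[classify_probe_quality(v)])
  }
})

test_that("probe selection prefers quality tier, then best cutoff performance", {
  set.seed(17)
  n <- 60
  probes <- c("pA", "pB", "pC", "pLow")
  vals <- rbind(pA = rlnorm(n, log(700), 0.5),
                pB = rlnorm(n, log(700), 0.5),
                pC = rlnorm(n, log(700), 0.5),
                pLow = rlnorm(n, log(40), 0.3))
  colnames(vals) <- sprintf("s%02d", 1:n)
  # survival driven by pA only
  rate <- 0.02 * exp(log(3) * (vals["pA", ] > median(vals["pA", ])))
  time <- rexp(n, rate)
  d <- expression_dataset(vals, "D1")
  clin <- clinical_table(data.frame(dataset_id = "D1",
                                    sample_id = colnames(vals),
                                    os_time = round(time, 3), os_event = 1))
  coll <- integrate_datasets(list(d), clin)
  cohort <- filter_cohort(coll, cohort_filter("OS"))
  ann <- data.frame(probe_id = c("pA", "pB", "pC", "pLow"),
                    gene_symbol = c("G1", "G1", "G2", "G2"))
  # two high-quality probes: planted effect decides
  expect_identical(as.character(
    select_probe_for_gene(coll, "G1", ann, cohort)), "pA")
  # high beats low regardless of performance
  expect_identical(as.character(
    select_probe_for_gene(coll, "G2", ann, cohort)), "pC")
  # singletons returned unconditionally
  ann2 <- rbind(ann, data.frame(probe_id = "pLow", gene_symbol = "G3"))
  expect_identical(as.character(
    select_probe_for_gene(coll, "G3", ann2, cohort)), "pLow")
  err <- expect_error(select_probe_for_gene(coll, "NOPE", ann, cohort),
                      class = "survcutoff_unknown_gene_error")
  expect_match(conditionMessage(err), "G1")
})
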