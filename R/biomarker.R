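# Cutoff-optimized dichotomization, signature scoring, the univariate ->
# multivariate validation workflow and per-dataset funnel meta-analysis.

#' Candidate cutoffs between the quartiles
#'
#' Candidate thresholds are the expression values at every integer
#' percentile from the 25th to the 75th, by the nearest-rank definition
#' (the p-th percentile of n sorted values is the value at index
#' ceiling(p*n/100)). Duplicate values arising from ties are collapsed,
#' preserving order.
#'
#' @param values Numeric vector of expression values (>= 8 samples, not all
#'   identical).
#' @return Non-decreasing numeric vector of candidate cutoffs.
#' @export
candidate_cutoffs <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8) stopf("need at least 8 samples for a cutoff scan",
                   class = "survcutoff_degenerate_error")
  if (length(unique(values)) < 2)
    stopf("all expression values identical: no candidate cutoffs",
          class = "survcutoff_no_candidates_error")
  srt <- sort(values)
  idx <- ceiling((25:75) * n / 100)
  unique(srt[idx])
}

#' Best-cutoff survival analysis
#'
#' The core scan: for every candidate cutoff between the lower and upper
#' expression quartiles, samples are dichotomized into low (value <= cutoff)
#' and high (value > cutoff) groups and the two groups are compared by the
#' logrank test; the best performing threshold — the one with the smallest
#' logrank p — is used as the final cutoff in a univariate Cox regression
#' of high vs. low. Candidates leaving a group empty are skipped; exact ties
#' in p are broken toward the candidate closest to the median, then the
#' smaller value, so reruns are deterministic. The reported p is the nominal
#' p at the selected cutoff, uncorrected for the scan's multiplicity
#' (see [simulate_null_pvalue_study()] for the optimism this induces).
#'
#' @param values Numeric expression vector, one value per sample.
#' @param surv Matching [survival_vector()].
#' @return A `BestCutoffResult`: `scan` (data frame over candidates with
#'   `cutoff`, `n_low`, `n_high`, `chisq`, `p`, plus `selected_cutoff`,
#'   `selected_chisq`, `selected_p`), `cox` (univariate [cox_fit()] on the
#'   high indicator), `hr`/`ci_low`/`ci_high`, `logrank_p`, and per-group
#'   Kaplan-Meier curves `km_low`, `km_high`.
#' @export
best_cutoff_analysis <- function(values, surv) {
  stopifnot(inherits(surv, "SurvivalVector"))
  values <- as.numeric(values)
  if (length(values) != length(surv$time))
    stopf("expression and survival vectors differ in length",
          class = "survcutoff_validation_error")
  cands <- candidate_cutoffs(values)
  rows <- lapply(cands, function(cc) {
    low <- values <= cc
    if (!any(low) || all(low)) return(NULL)
    lr <- logrank_test(survival_vector(surv$time[!low], surv$event[!low]),
                       survival_vector(surv$time[low], surv$event[low]))
    data.frame(cutoff = cc, n_low = sum(low), n_high = sum(!low),
               chisq = lr$chisq, p = lr$p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    stopf("every candidate cutoff leaves an empty group",
          class = "survcutoff_no_candidates_error")
  scan <- do.call(rbind, rows)
  med <- median(values)
  ord <- order(scan$p, abs(scan$cutoff - med), scan$cutoff)
  sel <- ord[1]
  high <- values > scan$cutoff[sel]
  cox <- cox_fit(stats::setNames(data.frame(as.numeric(high)), "high"), surv)
  co <- cox$coefficients
  structure(list(
    scan = structure(scan, selected = sel,
                     class = c("CutoffScan", "data.frame")),
    selected_cutoff = scan$cutoff[sel],
    selected_chisq = scan$chisq[sel],
    selected_p = scan$p[sel],
    n_low = scan$n_low[sel], n_high = scan$n_high[sel],
    hr = co$hr[1], ci_low = co$ci_low[1], ci_high = co$ci_high[1],
    logrank_p = scan$p[sel],
    cox = cox,
    km_low = km_estimate(survival_vector(surv$time[!high], surv$event[!high])),
    km_high = km_estimate(survival_vector(surv$time[high], surv$event[high]))),
    class = "BestCutoffResult")
}

#' @export
print.BestCutoffResult <- function(x, ...) {
  cat(sprintf("Best cutoff %.4g (low n = %d, high n = %d): HR = %.2f (%.2f-%.2f), logrank p = %.2g\n",
              x$selected_cutoff, x$n_low, x$n_high, x$hr, x$ci_low,
              x$ci_high, x$logrank_p))
  invisible(x)
}

#' Define a gene-expression signature
#'
#' @param signature_id Identifier of the signature.
#' @param probe_ids Unique member probe IDs (>= 1).
#' @param provenance Free-text note on the signature's origin.
#' @return A `SignatureDefinition`.
#' @export
signature_definition <- function(signature_id, probe_ids, provenance = "") {
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) < 1) stopf("signature needs at least one probe")
  if (anyDuplicated(probe_ids))
    stopf("duplicate probes in signature '%s'", signature_id,
          class = "survcutoff_validation_error")
  structure(list(signature_id = as.character(signature_id)[1],
                 probe_ids = probe_ids, provenance = provenance),
            class = "SignatureDefinition")
}

#' Load signature definitions
#'
#' TSV with columns `signature_id` and `probe_id`; one row per member.
#'
#' @param path Path to the TSV file.
#' @return Named list of [signature_definition()]s.
#' @export
load_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("signature_id", "probe_id") %in% names(df)))
    stopf("signature file needs 'signature_id' and 'probe_id' columns",
          class = "survcutoff_format_error")
  lst <- split(df$probe_id, df$signature_id)
  setNames(lapply(names(lst), function(id)
    signature_definition(id, unique(lst[[id]]))), names(lst))
}

#' Score a signature per sample
#'
#' The metagene score is the unweighted mean of the member probes'
#' intensities in each sample. Member probes absent from the matrix are
#' dropped with a message reporting the count.
#'
#' @param dataset An `ExpressionDataset`, or a probe-by-sample matrix.
#' @param signature A [signature_definition()].
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(dataset, signature) {
  stopifnot(inherits(signature, "SignatureDefinition"))
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values else dataset
  present <- signature$probe_ids %in% rownames(expr)
  if (!any(present))
    stopf("no member probe of signature '%s' present in the data",
          signature$signature_id, class = "survcutoff_empty_signature_error")
  if (any(!present))
    message(sprintf("signature '%s': %d of %d member probe(s) absent, dropped",
                    signature$signature_id, sum(!present), length(present)))
  colMeans(expr[signature$probe_ids[present], , drop = FALSE])
}

# Encode clinical covariates for the multivariate Cox model: stage and grade
# as ordinal integers, histology one-hot with adenocarcinoma as reference,
# sex/smoking and the treatment flags as 0/1 indicators, age in years.
encode_covariates <- function(clinical, covariates) {
  known <- c("age", "sex", "smoking", "histology", "stage", "grade",
             "margins_negative", "chemo", "radio")
  bad <- setdiff(covariates, known)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(clinical)))
  for (f in covariates) {
    if (f == "histology") {
      h <- clinical$histology
      any_dummy <- FALSE
      for (lev in c("scc", "large", "other")) {
        v <- as.numeric(h == lev)
        v[is.na(h)] <- NA
        if (any(v == 1, na.rm = TRUE)) {
          out[[paste0("histology_", lev)]] <- v
          any_dummy <- TRUE
        }
      }
      if (!any_dummy)
        warnf("histology requested but only one level present; dropped from the model")
    } else {
      out[[f]] <- switch(f,
        age = clinical$age,
        sex = as.numeric(clinical$sex == "male"),
        smoking = as.numeric(clinical$smoking == "ever"),
        stage = as.numeric(clinical$stage),
        grade = as.numeric(factor(clinical$grade,
                                  levels = c("well", "moderate", "poor"))),
        margins_negative = as.numeric(clinical$margins_negative),
        chemo = as.numeric(clinical$chemo),
        radio = as.numeric(clinical$radio))
    }
  }
  out
}

# Resolve a probe / gene / signature target to an id and a per-sample value
# vector within a cohort.
resolve_target <- function(collection, target, cohort, annotation = NULL) {
  if (inherits(target, "SignatureDefinition")) {
    return(list(id = target$signature_id,
                type = "signature",
                values = signature_score(cohort$expr, target)))
  }
  target <- as.character(target)[1]
  if (target %in% collection$common_probes)
    return(list(id = target, type = "probe", values = cohort$expr[target, ]))
  if (is.null(annotation))
    stopf("target '%s' is not a probe in the collection and no annotation was supplied",
          target, class = "survcutoff_unknown_gene_error")
  probe <- select_probe_for_gene(collection, target, annotation, cohort)
  list(id = as.character(probe), type = "gene", gene = target,
       values = cohort$expr[as.character(probe), ])
}

#' Validate a biomarker candidate
#'
#' The full validation workflow: filter the cohort, resolve the target
#' (probe ID, gene symbol via annotation, or signature), run the best-cutoff
#' univariate analysis, and — only when the univariate logrank p passes the
#' significance gate (default p < 0.01) — fit a multivariate Cox model of
#' the dichotomized expression indicator together with the requested
#' clinical covariates on the subset of samples with complete covariate
#' data (so the multivariate model typically uses fewer patients). Cohorts
#' below 50 patients trigger a warning, mirroring the usual inclusion floor
#' for biomarker studies.
#'
#' @param collection A `DatasetCollection`.
#' @param target Probe ID, gene symbol, or [signature_definition()].
#' @param filter A [cohort_filter()].
#' @param covariates Character vector of clinical covariates for the
#'   multivariate model (any of `age`, `sex`, `smoking`, `histology`,
#'   `stage`, `grade`, `margins_negative`, `chemo`, `radio`).
#' @param gate Univariate significance gate for running the multivariate
#'   model.
#' @param annotation Optional probe annotation, required for gene targets.
#' @return A `BiomarkerResult`: cohort description, the resolved target,
#'   the [best_cutoff_analysis()] result, and `multivariate` (a
#'   [cox_fit()] result, or `NULL` when the gate is not passed).
#' @export
validate_biomarker <- function(collection, target, filter,
                               covariates = character(), gate = 0.01,
                               annotation = NULL) {
  cohort <- filter_cohort(collection, filter)
  n <- length(cohort$time)
  if (n < 50)
    warnf("small cohort: n = %d is below the usual inclusion floor of 50 patients", n)
  tgt <- resolve_target(collection, target, cohort, annotation)
  surv <- survival_vector(cohort$time, cohort$event)
  uni <- best_cutoff_analysis(tgt$values, surv)
  multivariate <- NULL
  if (length(covariates) && uni$selected_p < gate) {
    enc <- encode_covariates(cohort$clinical, covariates)
    complete <- complete.cases(enc)
    if (sum(cohort$event[complete]) >= ncol(enc) + 1 && sum(complete) >= 10) {
      high <- as.numeric(tgt$values > uni$selected_cutoff)
      design <- cbind(data.frame(high = high), enc)[complete, , drop = FALSE]
      multivariate <- cox_fit(design,
                              survival_vector(cohort$time[complete],
                                              cohort$event[complete]))
    } else {
      warnf("too few complete-covariate samples for the multivariate model; skipped")
    }
  }
  structure(list(target = tgt$id, target_type = tgt$type,
                 endpoint = cohort$endpoint,
                 n = n, n_events = sum(cohort$event),
                 summary = cohort_summary(cohort),
                 analysis = uni,
                 gate = gate,
                 covariates = covariates,
                 multivariate = multivariate),
            class = "BiomarkerResult")
}

#' @export
print.BiomarkerResult <- function(x, ...) {
  cat(sprintf("Biomarker %s (%s), endpoint %s: n = %d, events = %d\n",
              x$target, x$target_type, x$endpoint, x$n, x$n_events))
  print(x$analysis)
  if (!is.null(x$multivariate)) {
    cat(sprintf("Multivariate model (gate p < %g passed):\n", x$gate))
    print(x$multivariate)
  } else {
    cat(sprintf("No multivariate model (univariate p %.2g not below gate %g, or no covariates requested)\n",
                x$analysis$selected_p, x$gate))
  }
  invisible(x)
}

#' Per-dataset meta-analysis
#'
#' Runs the best-cutoff analysis independently within each dataset of the
#' collection, yielding one hazard-ratio record per cohort for a funnel
#' plot (HR and confidence interval against sample size). Datasets whose
#' cohorts are degenerate (empty after filtering, too small for a scan, or
#' without informative candidates) are skipped with a logged reason.
#'
#' @inheritParams validate_biomarker
#' @return Data frame of funnel records (`dataset_id`, `n`, `n_events`,
#'   `cutoff`, `hr`, `ci_low`, `ci_high`, `p`), sorted by decreasing `n`;
#'   skipped datasets are recorded in attribute `"skipped"`.
#' @export
per_dataset_analysis <- function(collection, target, filter,
                                 annotation = NULL) {
  records <- list()
  skipped <- data.frame(dataset_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (id in names(collection$datasets)) {
    f <- filter
    f$datasets <- id
    rec <- tryCatch({
      cohort <- filter_cohort(collection, f)
      tgt <- resolve_target(collection, target, cohort, annotation)
      res <- best_cutoff_analysis(tgt$values,
                                  survival_vector(cohort$time, cohort$event))
      data.frame(dataset_id = id, n = length(cohort$time),
                 n_events = sum(cohort$event),
                 cutoff = res$selected_cutoff, hr = res$hr,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 p = res$selected_p, stringsAsFactors = FALSE)
    }, survcutoff_error = function(e) {
      skipped <<- rbind(skipped, data.frame(dataset_id = id,
                                            reason = conditionMessage(e),
                                            stringsAsFactors = FALSE))
      NULL
    })
    if (!is.null(rec)) records[[id]] <- rec
  }
  if (length(records) == 0)
    stopf("no dataset yields an analyzable cohort (%s)",
          paste(skipped$reason, collapse = "; "),
          class = "survcutoff_degenerate_error")
  out <- do.call(rbind, records)
  out <- out[order(-out$n, out$dataset_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("FunnelRecords", "data.frame")
  out
}
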