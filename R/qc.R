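# Array-level quality control: six per-array checks, pass/outlier/excluded
# status, and collection filtering.

#' Default array QC thresholds
#'
#' The six checks and their default acceptance regions: background within
#' [19, 218], raw Q within [0.5, 14], percentage of present calls above 30,
#' bioB/C/D spike-in controls all detected, GAPDH 3'/5' ratio below 4.3 and
#' beta-actin 3'/5' ratio below 18. The defaults are the 95% range of a
#' large reference corpus of MAS5-normalized arrays and can be overridden
#' per run. "Between a and b" is treated as the closed interval, "over" and
#' "below" as strict inequalities.
#'
#' @param background Closed interval, length 2.
#' @param raw_q Closed interval, length 2.
#' @param percent_present Strict lower bound on percent present calls.
#' @param gapdh_ratio Strict upper bound.
#' @param actin_ratio Strict upper bound.
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(background = c(19, 218), raw_q = c(0.5, 14),
                          percent_present = 30, gapdh_ratio = 4.3,
                          actin_ratio = 18) {
  structure(list(background = background, raw_q = raw_q,
                 percent_present = percent_present,
                 gapdh_ratio = gapdh_ratio, actin_ratio = actin_ratio),
            class = "QCThresholds")
}

qc_metric_names <- function() {
  c("background", "raw_q", "percent_present", "spikes_present",
    "gapdh_ratio", "actin_ratio")
}

#' Evaluate the QC checks for one array
#'
#' Each available metric is compared with its threshold; metrics that could
#' not be measured are marked `unevaluated` and never count as failures.
#' Status follows the failure count: 0 failures is a `pass`, exactly 1
#' failure marks the array an `outlier` (droppable on request), and 2 or
#' more failures mark it `excluded` (always dropped from analyses).
#'
#' @param metrics Named list or one-row data frame with any of `background`,
#'   `raw_q`, `percent_present`, `spikes_present` (logical), `gapdh_ratio`,
#'   `actin_ratio`; `NA` means not evaluable.
#' @param thresholds A [qc_thresholds()] object.
#' @return A `QCReport`: per-metric verdicts (`pass`/`fail`/`unevaluated`),
#'   `n_failures` and `status`.
#' @export
evaluate_array_qc <- function(metrics, thresholds = qc_thresholds()) {
  metrics <- as.list(metrics)
  m <- setNames(vector("list", length(qc_metric_names())), qc_metric_names())
  for (f in qc_metric_names()) m[[f]] <- metrics[[f]] %||% NA
  if (all(vapply(m, function(x) is.na(x), TRUE)))
    stopf("all QC metrics missing: quality control not possible for this array",
          class = "survcutoff_qc_error")
  in_range <- function(x, lo, hi) x >= lo & x <= hi
  checks <- c(
    background = if (is.na(m$background)) NA else
      in_range(m$background, thresholds$background[1], thresholds$background[2]),
    raw_q = if (is.na(m$raw_q)) NA else
      in_range(m$raw_q, thresholds$raw_q[1], thresholds$raw_q[2]),
    percent_present = if (is.na(m$percent_present)) NA else
      m$percent_present > thresholds$percent_present,
    spikes_present = if (is.na(m$spikes_present)) NA else
      isTRUE(as.logical(m$spikes_present)),
    gapdh_ratio = if (is.na(m$gapdh_ratio)) NA else
      m$gapdh_ratio < thresholds$gapdh_ratio,
    actin_ratio = if (is.na(m$actin_ratio)) NA else
      m$actin_ratio < thresholds$actin_ratio)
  verdict <- ifelse(is.na(checks), "unevaluated", ifelse(checks, "pass", "fail"))
  n_failures <- sum(verdict == "fail")
  status <- if (n_failures >= 2) "excluded" else if (n_failures == 1) "outlier" else "pass"
  structure(list(verdict = verdict, n_failures = n_failures, status = status),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %s (%d failure(s))\n", x$status, x$n_failures))
  fails <- names(x$verdict)[x$verdict == "fail"]
  if (length(fails)) cat("  failed:", paste(fails, collapse = ", "), "\n")
  invisible(x)
}

#' Load a per-array QC metrics table
#'
#' TSV with columns `dataset_id`, `sample_id`, `background`, `raw_q`,
#' `percent_present`, `spikes_present` (TRUE/FALSE or 1/0), `gapdh_ratio`,
#' `actin_ratio`; empty cells mean the metric was not evaluable. The metrics
#' are consumed precomputed — deriving them needs raw probe-level files,
#' which this toolkit does not parse.
#'
#' @param path Path to the TSV file.
#' @return Data frame of QC metrics, one row per array.
#' @export
load_qc_metrics <- function(path) {
  qc <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("dataset_id", "sample_id")
  if (!all(need %in% names(qc)))
    stopf("QC table needs 'dataset_id' and 'sample_id' columns",
          class = "survcutoff_format_error")
  for (f in setdiff(qc_metric_names(), names(qc))) qc[[f]] <- NA
  qc$spikes_present <- as.logical(qc$spikes_present)
  for (f in setdiff(qc_metric_names(), "spikes_present"))
    qc[[f]] <- as.numeric(qc[[f]])
  bad <- !is.na(qc$percent_present) &
    (qc$percent_present < 0 | qc$percent_present > 100)
  if (any(bad)) stopf("percent_present outside [0, 100]",
                      class = "survcutoff_validation_error")
  qc
}

#' Evaluate QC for every array of a metrics table
#'
#' @param qc_metrics Data frame from [load_qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @return Data frame with `dataset_id`, `sample_id`, one verdict column per
#'   metric, `n_failures` and `status`.
#' @export
evaluate_qc_table <- function(qc_metrics, thresholds = qc_thresholds()) {
  reports <- lapply(seq_len(nrow(qc_metrics)), function(i)
    evaluate_array_qc(qc_metrics[i, ], thresholds))
  verdicts <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(as.list(r$verdict), stringsAsFactors = FALSE)))
  out <- data.frame(dataset_id = qc_metrics$dataset_id,
                    sample_id = qc_metrics$sample_id,
                    verdicts,
                    n_failures = vapply(reports, function(r) r$n_failures, 0L),
                    status = vapply(reports, function(r) r$status, ""),
                    stringsAsFactors = FALSE)
  out
}

# Status lookup for (dataset_id, sample_id) pairs; arrays absent from the
# reports are treated as unevaluated and retained ("pass").
qc_status_for <- function(reports, dataset_id, sample_id) {
  idx <- match(sample_key(dataset_id, sample_id),
               sample_key(reports$dataset_id, reports$sample_id))
  st <- reports$status[idx]
  st[is.na(st)] <- "pass"
  st
}

#' Filter a collection by array QC status
#'
#' Arrays with status `excluded` are always removed; `outlier` arrays are
#' removed only when requested. Arrays without a QC report are retained.
#'
#' @param collection A `DatasetCollection`.
#' @param reports QC report data frame from [evaluate_qc_table()] (defaults
#'   to the reports attached to the collection, if any).
#' @param exclude_outliers Also drop single-failure (`outlier`) arrays.
#' @return The filtered `DatasetCollection`; the removal log (data frame of
#'   dropped arrays and their status) is attached as attribute `"removed"`.
#' @export
apply_qc_filter <- function(collection, reports = collection$qc_reports,
                            exclude_outliers = FALSE) {
  stopifnot(inherits(collection, "DatasetCollection"))
  if (is.null(reports)) {
    attr(collection, "removed") <- data.frame(dataset_id = character(),
                                              sample_id = character(),
                                              status = character())
    return(collection)
  }
  removed <- data.frame(dataset_id = character(), sample_id = character(),
                        status = character(), stringsAsFactors = FALSE)
  for (id in names(collection$datasets)) {
    d <- collection$datasets[[id]]
    st <- qc_status_for(reports, d$dataset_id, dataset_sample_ids(d))
    drop <- st == "excluded" | (exclude_outliers & st == "outlier")
    if (any(drop)) {
      removed <- rbind(removed, data.frame(dataset_id = d$dataset_id,
                                           sample_id = dataset_sample_ids(d)[drop],
                                           status = st[drop],
                                           stringsAsFactors = FALSE))
      d$values <- d$values[, !drop, drop = FALSE]
      collection$datasets[[id]] <- d
    }
  }
  keep <- !sample_key(collection$clinical$dataset_id,
                      collection$clinical$sample_id) %in%
    sample_key(removed$dataset_id, removed$sample_id)
  collection$clinical <- collection$clinical[keep, , drop = FALSE]
  rownames(collection$clinical) <- NULL
  collection$usable <- collection$usable[keep]
  collection$n_samples <- vapply(collection$datasets,
                                 function(d) ncol(d$values), 0L)
  attr(collection, "removed") <- removed
  collection
}
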