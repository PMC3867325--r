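# Reading, validation and integration of expression datasets and clinical
# tables, plus probe-level selection rules.

#' Construct an expression dataset
#'
#' An `ExpressionDataset` holds one cohort's probe-by-sample intensity matrix
#' on a MAS5-like positive scale, together with its identifier and array
#' platform label.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   row and column names set. All values must be finite and non-negative.
#' @param dataset_id Single string naming the cohort.
#' @param platform Single string naming the array platform (e.g. `"GPL96"`).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, dataset_id, platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix", class = "survcutoff_validation_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must carry probe row names and sample column names",
          class = "survcutoff_validation_error")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate probe IDs in dataset '%s'", dataset_id,
          class = "survcutoff_validation_error")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample IDs in dataset '%s'", dataset_id,
          class = "survcutoff_validation_error")
  if (any(!is.finite(values)))
    stopf("non-finite intensities in dataset '%s'", dataset_id,
          class = "survcutoff_format_error")
  if (any(values < 0))
    stopf("negative intensities in dataset '%s'", dataset_id,
          class = "survcutoff_format_error")
  structure(list(dataset_id = as.character(dataset_id)[1],
                 platform = as.character(platform)[1],
                 values = values),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s): %d probes x %d samples\n",
              x$dataset_id, x$platform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
dataset_sample_ids <- function(x) colnames(x$values)

#' Load an expression matrix from a tab-delimited file
#'
#' Expects a header row of sample IDs, a first column of probe IDs and a
#' numeric intensity body. Column order is preserved.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
load_expression_dataset <- function(path, dataset_id, platform = "unknown") {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (ncol(raw) < 2) stopf("'%s': need a probe-ID column plus >= 1 sample column",
                           path, class = "survcutoff_format_error")
  probes <- raw[[1]]
  body <- raw[-1]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(body),
                 dimnames = list(probes, names(body)))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stopf("'%s': non-numeric value '%s' at probe '%s', sample '%s'",
            path, body[[j]][bad[1]], probes[bad[1]], names(body)[j],
            class = "survcutoff_format_error")
    vals[, j] <- v
  }
  expression_dataset(vals, dataset_id = dataset_id, platform = platform)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [load_expression_dataset()]; values are written at full
#' precision so a round-trip is exact.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output path.
#' @export
write_expression_dataset <- function(dataset, path) {
  df <- data.frame(probe_id = probe_ids(dataset),
                   format(dataset$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", dataset_sample_ids(dataset))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_fields <- function() {
  c("dataset_id", "sample_id", "os_time", "os_event", "fp_time", "fp_event",
    "age", "sex", "smoking", "histology", "stage", "grade",
    "margins_negative", "chemo", "radio")
}

vocab_fields <- function() {
  c("sex", "smoking", "histology", "stage", "grade",
    "margins_negative", "chemo", "radio")
}

load_vocab_map <- function() {
  path <- system.file("extdata", "clinical_vocab.tsv", package = "survcutoff")
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

map_vocab <- function(x, field, vocab) {
  out <- rep(NA_character_, length(x))
  present <- !is_missing_token(x)
  if (!any(present)) return(out)
  tab <- vocab[vocab$field == field, ]
  tok <- tolower(trimws(x[present]))
  idx <- match(tok, tab$token)
  out[present] <- tab$value[idx]
  unknown <- present
  unknown[present] <- is.na(idx)
  if (any(unknown))
    warnf("clinical field '%s': %d unmappable token(s) (e.g. '%s') set to missing",
          field, sum(unknown), x[which(unknown)[1]])
  out
}

#' Load a clinical follow-up table
#'
#' Reads a tab-delimited clinical table with fixed column names
#' (`dataset_id`, `sample_id`, `os_time`, `os_event`, `fp_time`, `fp_event`,
#' `age`, `sex`, `smoking`, `histology`, `stage`, `grade`,
#' `margins_negative`, `chemo`, `radio`); any subset of the covariate columns
#' may be absent and missing cells are preserved. Controlled-vocabulary
#' fields are normalized through a shipped mapping table (e.g. `"IIIa"` to
#' stage 3); unmappable tokens become missing with a warning. Survival times
#' are converted to months.
#'
#' @param path Path to the TSV file.
#' @param time_unit Unit of `os_time`/`fp_time` in the file; converted to
#'   months (`days` divided by 30.44, `years` multiplied by 12).
#' @return A `data.frame` of class `ClinicalTable`, one row per sample.
#' @export
load_clinical_table <- function(path, time_unit = c("months", "days", "years")) {
  time_unit <- match.arg(time_unit)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (!all(c("dataset_id", "sample_id") %in% names(raw)))
    stopf("'%s': clinical table needs 'dataset_id' and 'sample_id' columns",
          path, class = "survcutoff_format_error")
  clinical_table(raw, time_unit = time_unit)
}

#' Build a validated clinical table from a raw data frame
#'
#' @param raw Data frame with character (or already typed) columns using the
#'   header names documented in [load_clinical_table()].
#' @inheritParams load_clinical_table
#' @return A `ClinicalTable` data frame.
#' @export
clinical_table <- function(raw, time_unit = "months") {
  vocab <- load_vocab_map()
  n <- nrow(raw)
  out <- data.frame(dataset_id = as.character(raw$dataset_id),
                    sample_id = as.character(raw$sample_id),
                    stringsAsFactors = FALSE)
  num_col <- function(name) {
    if (!name %in% names(raw)) return(rep(NA_real_, n))
    x <- raw[[name]]
    if (is.numeric(x)) return(as.numeric(x))
    v <- rep(NA_real_, n)
    present <- !is_missing_token(x)
    v[present] <- suppressWarnings(as.numeric(x[present]))
    if (any(present & is.na(v)))
      stopf("clinical field '%s': non-numeric value '%s'", name,
            x[which(present & is.na(v))[1]], class = "survcutoff_format_error")
    v
  }
  div <- switch(time_unit, months = 1, days = 30.44, years = 1 / 12)
  out$os_time <- num_col("os_time") / div
  out$os_event <- num_col("os_event")
  out$fp_time <- num_col("fp_time") / div
  out$fp_event <- num_col("fp_event")
  out$age <- num_col("age")
  for (f in vocab_fields()) {
    x <- if (f %in% names(raw)) as.character(raw[[f]]) else rep(NA_character_, n)
    out[[f]] <- map_vocab(x, f, vocab)
  }
  for (f in c("stage", "margins_negative", "chemo", "radio"))
    out[[f]] <- as.integer(out[[f]])
  for (ep in c("os", "fp")) {
    tm <- out[[paste0(ep, "_time")]]
    ev <- out[[paste0(ep, "_event")]]
    if (any(is.na(tm) != is.na(ev)))
      stopf("endpoint '%s': time and event indicator must be present together (first offender: sample '%s')",
            toupper(ep), out$sample_id[which(is.na(tm) != is.na(ev))[1]],
            class = "survcutoff_validation_error")
    if (any(!is.na(ev) & !ev %in% c(0, 1)))
      stopf("endpoint '%s': event indicator must be 0/1", toupper(ep),
            class = "survcutoff_validation_error")
    if (any(!is.na(tm) & tm < 0))
      stopf("endpoint '%s': negative survival time", toupper(ep),
            class = "survcutoff_validation_error")
  }
  if (anyDuplicated(sample_key(out$dataset_id, out$sample_id)))
    stopf("duplicate (dataset_id, sample_id) pairs in clinical table",
          class = "survcutoff_validation_error")
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Write a clinical table as TSV
#' @param clinical A `ClinicalTable`.
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Load a probe-to-gene annotation table
#'
#' TSV with columns `probe_id` and `gene_symbol`; many probes may map to one
#' gene. A probe mapping to several genes is allowed but flagged with a
#' warning, since such probes are ambiguous for gene-level lookups.
#'
#' @param path Path to the TSV file.
#' @return Data frame with `probe_id`, `gene_symbol`.
#' @export
load_probe_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(ann)))
    stopf("annotation needs 'probe_id' and 'gene_symbol' columns",
          class = "survcutoff_format_error")
  if (anyDuplicated(ann[c("probe_id", "gene_symbol")]))
    stopf("duplicate annotation rows", class = "survcutoff_validation_error")
  multi <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(multi))
    warnf("%d probe(s) map to more than one gene (e.g. '%s')",
          length(multi), multi[1])
  ann
}

#' Integrate expression datasets with a clinical table
#'
#' Restricts all datasets to the intersection of their probe sets — only
#' probes measured on every platform are retained, so the same transcript is
#' measured with comparable scale and dynamic range across cohorts. Samples
#' without any survival endpoint are kept in the collection but flagged
#' unusable for survival analysis.
#'
#' @param datasets List of `ExpressionDataset` objects.
#' @param clinical A `ClinicalTable` covering (a subset of) the samples.
#' @param qc_reports Optional QC report data frame from [evaluate_qc_table()];
#'   carried on the collection so cohort construction can honour array status.
#' @return A `DatasetCollection`: the probe-intersected datasets, the clinical
#'   table, per-dataset sample counts and a per-sample usability flag.
#' @export
integrate_datasets <- function(datasets, clinical, qc_reports = NULL) {
  if (length(datasets) < 1) stopf("need at least one dataset")
  ids <- vapply(datasets, function(d) d$dataset_id, "")
  if (anyDuplicated(ids)) stopf("duplicate dataset_id among datasets",
                                class = "survcutoff_validation_error")
  names(datasets) <- ids
  common <- Reduce(intersect, lapply(datasets, probe_ids))
  if (length(common) == 0)
    stopf("empty probe intersection across datasets",
          class = "survcutoff_empty_intersection_error")
  datasets <- lapply(datasets, function(d) {
    d$values <- d$values[common, , drop = FALSE]
    d
  })
  key_expr <- unlist(lapply(datasets, function(d)
    sample_key(d$dataset_id, dataset_sample_ids(d))), use.names = FALSE)
  key_clin <- sample_key(clinical$dataset_id, clinical$sample_id)
  clin <- as.data.frame(clinical)[match(key_expr, key_clin), , drop = FALSE]
  clin$dataset_id <- sub("\r.*$", "", key_expr)
  clin$sample_id <- sub("^.*\r", "", key_expr)
  rownames(clin) <- NULL
  usable <- (!is.na(clin$os_time)) | (!is.na(clin$fp_time))
  structure(list(datasets = datasets,
                 common_probes = common,
                 clinical = clin,
                 usable = usable,
                 qc_reports = qc_reports,
                 n_samples = vapply(datasets, function(d) ncol(d$values), 0L)),
            class = "DatasetCollection")
}

#' @export
print.DatasetCollection <- function(x, ...) {
  cat(sprintf("DatasetCollection: %d dataset(s), %d common probes, %d samples (%d usable for survival)\n",
              length(x$datasets), length(x$common_probes),
              sum(x$n_samples), sum(x$usable)))
  for (d in x$datasets)
    cat(sprintf("  %-12s %-8s n = %d\n", d$dataset_id, d$platform,
                ncol(d$values)))
  invisible(x)
}

#' Define a cohort filter
#'
#' Constraints restrict the analysis to samples matching every active field;
#' an unset (`NULL`) constraint does not filter. Samples missing a value in an
#' actively filtered field are excluded.
#'
#' @param endpoint `"OS"` (overall survival) or `"FP"` (first progression).
#' @param datasets Optional character vector of dataset IDs to keep.
#' @param sex,smoking,histology,stage,grade,margins_negative,chemo,radio
#'   Optional vectors of allowed values for the corresponding clinical field.
#' @param exclude_outlier_arrays Drop arrays whose QC status is `outlier`
#'   (arrays with status `excluded` are always dropped when QC reports are
#'   attached to the collection).
#' @return A `CohortFilter` list.
#' @export
cohort_filter <- function(endpoint = c("OS", "FP"), datasets = NULL,
                          sex = NULL, smoking = NULL, histology = NULL,
                          stage = NULL, grade = NULL, margins_negative = NULL,
                          chemo = NULL, radio = NULL,
                          exclude_outlier_arrays = FALSE) {
  endpoint <- match.arg(endpoint)
  structure(list(endpoint = endpoint, datasets = datasets,
                 constraints = list(sex = sex, smoking = smoking,
                                    histology = histology, stage = stage,
                                    grade = grade,
                                    margins_negative = margins_negative,
                                    chemo = chemo, radio = radio),
                 exclude_outlier_arrays = isTRUE(exclude_outlier_arrays)),
            class = "CohortFilter")
}

#' Extract an analysis cohort from a collection
#'
#' Keeps samples with a complete (time, event) pair for the chosen endpoint
#' that satisfy every active constraint of the filter. When QC reports are
#' attached to the collection, arrays with status `excluded` are always
#' dropped and `outlier` arrays are dropped if the filter requests it.
#'
#' @param collection A `DatasetCollection`.
#' @param filter A [cohort_filter()].
#' @return A `Cohort`: combined expression matrix (common probes x samples),
#'   aligned clinical rows, and `time`/`event` vectors for the endpoint.
#' @export
filter_cohort <- function(collection, filter) {
  stopifnot(inherits(collection, "DatasetCollection"),
            inherits(filter, "CohortFilter"))
  clin <- collection$clinical
  ep <- tolower(filter$endpoint)
  keep <- !is.na(clin[[paste0(ep, "_time")]]) & !is.na(clin[[paste0(ep, "_event")]])
  if (!is.null(filter$datasets))
    keep <- keep & clin$dataset_id %in% filter$datasets
  for (f in names(filter$constraints)) {
    allowed <- filter$constraints[[f]]
    if (is.null(allowed)) next
    keep <- keep & !is.na(clin[[f]]) & clin[[f]] %in% allowed
  }
  if (!is.null(collection$qc_reports)) {
    st <- qc_status_for(collection$qc_reports, clin$dataset_id, clin$sample_id)
    keep <- keep & st != "excluded"
    if (filter$exclude_outlier_arrays) keep <- keep & st != "outlier"
  }
  if (!any(keep))
    stopf("cohort is empty after filtering (endpoint %s)", filter$endpoint,
          class = "survcutoff_empty_cohort_error")
  clin <- clin[keep, , drop = FALSE]
  rownames(clin) <- NULL
  expr <- do.call(cbind, lapply(collection$datasets, function(d) d$values))
  colnames(expr) <- unlist(lapply(collection$datasets, function(d)
    sample_key(d$dataset_id, dataset_sample_ids(d))), use.names = FALSE)
  expr <- expr[, sample_key(clin$dataset_id, clin$sample_id), drop = FALSE]
  structure(list(expr = expr, clinical = clin, endpoint = filter$endpoint,
                 time = clin[[paste0(ep, "_time")]],
                 event = clin[[paste0(ep, "_event")]]),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort (%s): %d samples, %d events, %d probes\n",
              x$endpoint, ncol(x$expr), sum(x$event), nrow(x$expr)))
  invisible(x)
}

#' Classify a probe's measurement quality
#'
#' Probes are graded by their intensity profile across the database:
#' high quality when average expression exceeds 500 or maximal expression
#' exceeds 1000; low quality when average expression is below 100; all other
#' probes are intermediate. The high rule is applied first, so a probe with
#' a low mean but a strong maximum still counts as high.
#'
#' @param values Numeric vector of intensities for one probe.
#' @return `"high"`, `"intermediate"` or `"low"`.
#' @export
classify_probe_quality <- function(values) {
  if (length(values) == 0) stopf("empty intensity vector")
  if (any(!is.finite(values))) stopf("non-finite intensities")
  if (mean(values) > 500 || max(values) > 1000) return("high")
  if (mean(values) < 100) return("low")
  "intermediate"
}

#' Select the probe representing a gene
#'
#' When several probe sets measure one gene, the probes of the highest
#' available quality tier (see [classify_probe_quality()], computed over all
#' samples in the collection) are preferred; if several share the top tier,
#' the best performing one — smallest logrank p from its best-cutoff analysis
#' in the given cohort — is used.
#'
#' @param collection A `DatasetCollection`.
#' @param gene Gene symbol.
#' @param annotation Probe annotation (see [load_probe_annotation()]).
#' @param cohort Cohort in which performance is compared (needed only when
#'   several probes share the top quality tier).
#' @return The selected probe ID (with the quality tier as attribute).
#' @export
select_probe_for_gene <- function(collection, gene, annotation, cohort = NULL) {
  probes <- annotation$probe_id[annotation$gene_symbol == gene]
  probes <- intersect(probes, collection$common_probes)
  if (length(probes) == 0)
    stopf("gene '%s' has no mapped probe in the collection; known genes include: %s",
          gene, paste(head(sort(unique(annotation$gene_symbol)), 20), collapse = ", "),
          class = "survcutoff_unknown_gene_error")
  if (length(probes) == 1) return(structure(probes, quality = NA_character_))
  expr <- do.call(cbind, lapply(collection$datasets,
                                function(d) d$values[probes, , drop = FALSE]))
  quality <- vapply(probes, function(p) classify_probe_quality(expr[p, ]), "")
  tiers <- c("high", "intermediate", "low")
  best_tier <- tiers[min(match(quality, tiers))]
  cand <- probes[quality == best_tier]
  if (length(cand) == 1) return(structure(cand, quality = best_tier))
  if (is.null(cohort))
    stopf("gene '%s': several %s-quality probes; a cohort is required to pick the best performer",
          gene, best_tier)
  p_vals <- vapply(cand, function(p) {
    res <- try(best_cutoff_analysis(cohort$expr[p, ],
                                    survival_vector(cohort$time, cohort$event)),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NA_real_)
    res$selected_p
  }, 0)
  if (all(is.na(p_vals)))
    stopf("gene '%s': no candidate probe admits a cutoff analysis", gene)
  sel <- cand[order(p_vals, cand)][1]
  structure(sel, quality = best_tier)
}
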