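# Second-stage scaling normalization and duplicate-array detection.

#' Scale-normalize each array to a common mean
#'
#' After restriction to the common probe set, a second scaling step centers
#' the mean intensity of every array to a common target (default 1000). This
#' per-array multiplicative rescaling brings cohorts processed in different
#' laboratories onto one scale and markedly reduces batch effects, while
#' leaving the within-array rank order of probes untouched.
#'
#' @param dataset An `ExpressionDataset`.
#' @param target_mean Target per-array mean intensity.
#' @return The rescaled `ExpressionDataset`; idempotent.
#' @export
scale_normalize <- function(dataset, target_mean = 1000) {
  stopifnot(inherits(dataset, "ExpressionDataset"), target_mean > 0)
  means <- colMeans(dataset$values)
  if (any(means <= 0))
    stopf("array '%s' has non-positive mean intensity; cannot scale",
          dataset_sample_ids(dataset)[which(means <= 0)[1]],
          class = "survcutoff_degenerate_array_error")
  dataset$values <- sweep(dataset$values, 2, target_mean / means, `*`)
  dataset
}

#' Detect duplicated arrays by expression rank correlation
#'
#' Samples re-published across studies are spotted by comparing the ranked
#' expression of all common probes between every pair of arrays, within and
#' across datasets. Ranks use midranks for ties, so the comparison is the
#' Spearman correlation; any monotone rescaling of an array (including
#' [scale_normalize()]) leaves it unchanged. Pairs at or above the threshold
#' are reported once each, sorted by decreasing correlation.
#'
#' @param datasets List of `ExpressionDataset` objects sharing a common
#'   probe set (probes are intersected internally if they differ).
#' @param threshold Rank correlation at or above which a pair is called a
#'   duplicate. The default 0.99 (rather than exactly 1) tolerates float
#'   round-trips through files.
#' @return Data frame of `DuplicatePair` rows: `dataset_id_a`, `sample_id_a`,
#'   `dataset_id_b`, `sample_id_b`, `rank_correlation`.
#' @export
detect_duplicates <- function(datasets, threshold = 0.99) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (inherits(datasets, "DatasetCollection")) datasets <- datasets$datasets
  common <- Reduce(intersect, lapply(datasets, probe_ids))
  if (length(common) < 3)
    stopf("fewer than 3 common probes: rank correlation degenerate",
          class = "survcutoff_degenerate_error")
  mats <- lapply(datasets, function(d) d$values[common, , drop = FALSE])
  expr <- do.call(cbind, mats)
  ds_of <- unlist(lapply(datasets, function(d)
    rep(d$dataset_id, ncol(d$values))), use.names = FALSE)
  sm_of <- unlist(lapply(datasets, dataset_sample_ids), use.names = FALSE)
  ranks <- apply(expr, 2, rank)  # midranks for ties
  rho <- stats::cor(ranks)
  n <- ncol(expr)
  out <- data.frame(dataset_id_a = character(), sample_id_a = character(),
                    dataset_id_b = character(), sample_id_b = character(),
                    rank_correlation = numeric(), stringsAsFactors = FALSE)
  if (n >= 2) {
    idx <- which(upper.tri(rho) & rho >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- data.frame(dataset_id_a = ds_of[idx[, 1]],
                        sample_id_a = sm_of[idx[, 1]],
                        dataset_id_b = ds_of[idx[, 2]],
                        sample_id_b = sm_of[idx[, 2]],
                        rank_correlation = rho[idx],
                        stringsAsFactors = FALSE)
      out <- out[order(-out$rank_correlation,
                       out$dataset_id_a, out$sample_id_a), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("DuplicatePairs", "data.frame")
  out
}
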