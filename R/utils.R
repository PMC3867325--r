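# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "survcutoff_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "survcutoff_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_missing_token <- function(x) {
  is.na(x) | trimws(x) == "" | tolower(trimws(x)) %in% c("na", "n/a", "null", "-", ".")
}

# Sample keys must be unique across datasets: identity is the exact
# (dataset_id, sample_id) string pair.
sample_key <- function(dataset_id, sample_id) paste(dataset_id, sample_id, sep = "\r")

#' @importFrom stats median pchisq pnorm qnorm quantile rbinom rexp rlnorm
#'   rnorm runif setNames complete.cases uniroot
#' @importFrom utils read.delim write.table head
#' @importFrom tools file_ext
#' @importFrom graphics lines points legend mtext plot.default
NULL
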