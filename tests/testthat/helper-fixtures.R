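# Small in-code fixtures shared across test files.

toy_matrix <- function(probes, samples, values) {
  matrix(values, nrow = length(probes), ncol = length(samples),
         dimnames = list(probes, samples), byrow = TRUE)
}

toy_dataset <- function(id = "D1", n_probes = 5, n_samples = 4, seed = 1,
                        platform = "GPL96") {
  set.seed(seed)
  m <- matrix(rlnorm(n_probes * n_samples, log(300), 0.6),
              nrow = n_probes,
              dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                              sprintf("%s_s%02d", id, seq_len(n_samples))))
  expression_dataset(m, id, platform)
}

toy_clinical <- function(dataset_id, sample_ids, os_time = NULL,
                         os_event = NULL, ...) {
  n <- length(sample_ids)
  raw <- data.frame(dataset_id = dataset_id, sample_id = sample_ids,
                    stringsAsFactors = FALSE)
  raw$os_time <- os_time %||% round(runif(n, 5, 80), 2)
  raw$os_event <- os_event %||% rbinom(n, 1, 0.6)
  extra <- list(...)
  for (f in names(extra)) raw[[f]] <- extra[[f]]
  clinical_table(raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small integrated collection with a clinical table covering everything.
toy_collection <- function(n_samples = 30, seed = 7) {
  set.seed(seed)
  d1 <- toy_dataset("D1", n_probes = 6, n_samples = n_samples, seed = seed)
  d2 <- toy_dataset("D2", n_probes = 6, n_samples = n_samples, seed = seed + 1)
  clin <- rbind(
    data.frame(dataset_id = "D1", sample_id = colnames(d1$values),
               stringsAsFactors = FALSE),
    data.frame(dataset_id = "D2", sample_id = colnames(d2$values),
               stringsAsFactors = FALSE))
  clin$os_time <- round(runif(nrow(clin), 2, 90), 2)
  clin$os_event <- rbinom(nrow(clin), 1, 0.7)
  clin$histology <- sample(c("adeno", "scc", "large"), nrow(clin), TRUE,
                           prob = c(.5, .45, .05))
  clin$sex <- sample(c("male", "female"), nrow(clin), TRUE)
  clin$stage <- sample(1:4, nrow(clin), TRUE)
  integrate_datasets(list(d1, d2), clinical_table(clin))
}
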