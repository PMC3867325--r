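# survcutoff

Cutoff-optimized survival biomarker validation across gene-expression
cohorts.

## The problem

Dozens of prognostic biomarkers have been proposed for non-small cell lung
cancer (NSCLC) from individual microarray studies, most of them too small to
settle the question on their own. Testing a candidate gene or metagene
signature properly requires pooling every published cohort that measured it
together with survival follow-up — which in turn requires consistent
quality control, cross-platform probe matching, normalization onto a common
scale, detection of arrays re-published across studies, and a survival
analysis that does not depend on an arbitrary expression threshold.

`survcutoff` is a desk-scale R toolkit for exactly this workflow:

1. **Integrate** probe-by-sample intensity matrices (MAS5-like positive
   scale) from several cohorts, keeping only the probes measured on every
   platform, and attach clinical follow-up (overall survival `OS` or time
   to first progression `FP`, plus histology, stage, grade, sex, smoking,
   surgery, chemo/radiotherapy).
2. **Quality-control** each array with six checks (background, raw Q,
   percent present calls, bioB/C/D spikes, GAPDH and beta-actin 3′/5′
   ratios). One failed check marks an array an *outlier* (droppable on
   request); two or more mark it *excluded* (always dropped).
3. **Normalize** by scaling every array to a mean intensity of 1000, and
   **de-duplicate** by flagging array pairs whose expression rank
   correlation is ≈ 1.
4. **Analyse** a probe, gene, or signature (mean of member probes): every
   integer expression percentile between the lower and upper quartiles is
   tried as a dichotomization threshold, each split is scored by the
   logrank test, and the best-performing threshold is the final cutoff for
   a univariate Cox proportional-hazards model:

   h(t | high) = h(t | low) · HR,  HR = exp(β̂),

   reported with Kaplan–Meier curves, the 95% Wald interval for the HR and
   the logrank p. Candidates that pass the significance gate (p < 0.01)
   are additionally adjusted in a multivariate Cox model with clinical
   covariates on the complete-case subset.
5. **Meta-analyse** per dataset, drawing a funnel plot of HR (with CI)
   against cohort size.

A built-in simulator generates multi-cohort corpora from an exponential
proportional-hazards model with a planted effect, calibrated censoring,
realistic NSCLC covariate frequencies, planted QC violations and planted
duplicate arrays — so the entire pipeline, including its known optimism
(the minimum-p cutoff scan inflates nominal significance under the null),
is testable end to end with known ground truth.

## Worked example

```r
library(survcutoff)

cfg  <- simulation_config(n_datasets = 3, samples_per_dataset = 200,
                          beta = log(2), censoring_target = 0.2,
                          n_qc_excluded = 2, n_qc_outlier = 5, seed = 42)
sim  <- simulate_collection(cfg)
coll <- integrate_datasets(sim$datasets, sim$clinical,
                           qc_reports = evaluate_qc_table(sim$qc_metrics))
coll$datasets <- lapply(coll$datasets, scale_normalize)

validate_biomarker(coll, sim$truth$planted_probe, cohort_filter("OS"),
                   covariates = c("sex", "stage", "histology"))
#> Biomarker probe_0001 (probe), endpoint OS: n = 598, events = 475
#> Best cutoff 1437 (low n = 270, high n = 328): HR = 1.88 (1.56-2.27), logrank p = 3e-11
#> Multivariate model (gate p < 0.01 passed):
#> Cox model: n = 598, events = 475, score chi-square = 55.656
#>   high             HR = 1.91 (1.58-2.31), p = 2.8e-11
#>   sex              HR = 1.14 (0.95-1.37), p = 0.17
#>   stage            HR = 0.99 (0.87-1.13), p = 0.86
#>   histology_scc    HR = 1.17 (0.97-1.42), p = 0.091
#>   histology_large  HR = 1.85 (1.24-2.77), p = 0.0027
```

The planted hazard ratio was 2.0 acting above the median of probe
`probe_0001`; the scan recovers a cutoff near that median and an HR of
1.88 (univariate) / 1.91 (adjusted), both with 95% intervals covering the
truth. Two arrays failed two QC checks and were excluded automatically
(n = 598, not 600); the covariates, drawn independently of survival, stay
near HR 1 (the `histology_large` excess is the kind of fluctuation a 5%
category produces at this size). Per-dataset records for the funnel plot
come from `per_dataset_analysis(coll, sim$truth$planted_probe,
cohort_filter("OS"))`.

The same workflow runs from a shell via the thin wrapper:

```sh
Rscript exec/survcutoff simulate --out corpus/ --seed 42 --n-datasets 3
Rscript exec/survcutoff analyze \
  --expression corpus/expression_SIM01.tsv,corpus/expression_SIM02.tsv,corpus/expression_SIM03.tsv \
  --clinical corpus/clinical.tsv --qc corpus/qc_metrics.tsv \
  --target probe_0001 --endpoint OS --covariates sex,stage \
  --out results/
```

which writes `result.json`, the cutoff scan `scan.tsv`, the annotated
Kaplan–Meier plot (`km_plot.svg`/`.png`) and a run log. Subcommands
`qc`, `dedup`, `integrate` and `meta` cover the remaining steps.

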