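---
title: "Methods: cutoff-optimized survival biomarker validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cutoff-optimized survival biomarker validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcutoff)
```

## Scope and model

`survcutoff` validates candidate prognostic biomarkers — single probes,
genes, or metagene signatures — in integrated multi-cohort expression data
with survival follow-up. The statistical core is the Cox proportional
hazards model applied to *dichotomized* expression: for a sample with
expression value $x$ and cutoff $c$,

$$ h(t \mid x) = h_0(t)\, \exp\{\beta \cdot \mathbf{1}[x > c]\}, $$

so $\mathrm{HR} = e^{\beta}$ compares the high- against the low-expression
group. The cutoff $c$ is not fixed in advance: every integer percentile of
the expression distribution from the 25th to the 75th is tried
(nearest-rank definition: the $p$-th percentile of $n$ sorted values is
the value at index $\lceil pn/100\rceil$), each candidate split is scored
by the two-group logrank test, and the candidate with the smallest p is
the final cutoff. Exact p ties are broken toward the candidate closest to
the median, then the smaller value, so reruns are bit-identical.
Restricting candidates to the interquartile range guarantees both groups
hold at least a quarter of the cohort.

Kaplan–Meier estimation, the logrank test and Cox fitting are delegated to
the `survival` package (product-limit estimator; hypergeometric-variance
logrank; Efron approximation for tied event times, Newton–Raphson with a
$10^{-9}$ log-likelihood tolerance). We report Wald per-covariate p-values
and the 95% Wald interval for the HR, and expose the global score
statistic because on a tie-free binary split it coincides with the logrank
chi-square — a coincidence the test suite checks numerically against
hand-rolled implementations of both.

### Why minimal p, and what it costs

The scan's selection criterion ("best performing cutoff") is interpreted
as minimal logrank p; maximizing the score statistic is numerically
equivalent on these splits, and minimizing p is the convention users of
cutoff-optimized KM tools expect. The price is multiplicity: the reported
p is the minimum of ~51 highly correlated tests and is therefore
optimistic under the null. We quantify rather than correct this —
`simulate_null_pvalue_study()` runs the scan on cohorts where expression
is independent of survival and reports the fraction of nominal p < 0.05;
with 200 simulations of 100 patients this fraction sits around 0.25–0.30,
versus the nominal 0.05 recovered by the pre-specified median-split
control arm. Users should treat scan p-values as screening statistics;
the 0.01 significance gate (below) is one pragmatic guard.

### The univariate → multivariate workflow

`validate_biomarker()` runs the scan and, only when the univariate
logrank p is below the gate (default $p < 0.01$), refits the dichotomized
indicator together with requested clinical covariates in a multivariate
Cox model. Covariate encodings: stage (1–4) and grade
(well < moderate < poor) as ordinal integers, histology one-hot with
adenocarcinoma as reference (dummies for levels absent from the cohort
are dropped), sex/smoking/treatment flags as 0/1. The multivariate model
uses only complete-case samples for the chosen covariates, so its n is
typically smaller than the univariate n; both are reported. Cohorts under
50 patients trigger a warning — the customary inclusion floor for
biomarker validation series. The dichotomized indicator (not continuous
expression) enters the multivariate model, reusing the univariate cutoff,
so the adjusted and unadjusted HRs share semantics.

### Gene-level lookup and signatures

When several probe sets measure one gene, probes are tiered by intensity
profile: *high* if mean > 500 or max > 1000, *low* if mean < 100,
*intermediate* otherwise, with the high rule taking precedence in the
ambiguous low-mean/high-max corner. The best available tier wins; among
equals the probe with the smallest best-cutoff p in the target cohort is
used. Signature scores are the unweighted per-sample mean of member-probe
intensities — the simplest rule consistent with a single scalar cutoff
per signature — with absent members dropped and counted. Weighted
combinations are out of scope.

## Data handling

**Integration.** Datasets are restricted to the intersection of their
probe sets, so every retained probe is measured on all platforms with
comparable scale and dynamic range; an empty intersection is an error,
never an imputation. Sample identity across expression and clinical
tables is the exact `(dataset_id, sample_id)` string pair. Samples
without any survival endpoint stay in the collection (they still matter
for probe quality and duplicate detection) but are flagged unusable.

**Clinical vocabulary.** Free-text clinical tokens are normalized through
a shipped mapping table (`"IIIa"` → stage 3, `"SCC"` → `scc`, `"M"` →
`male`, ...); unmappable tokens become missing with a warning rather than
an error, because in practice curation glitches should cost one sample,
not one cohort. Survival times are stored in months; loaders convert
days (÷ 30.44) and years (× 12). A time without its event indicator (or
vice versa) is a hard validation error. A sample is dropped only from
computations that need its missing field: an actively filtered covariate,
or a multivariate model including it.

**Quality control.** Six per-array checks with default acceptance
regions: background ∈ [19, 218], raw Q ∈ [0.5, 14], percent present
calls > 30, bioB/C/D spikes all detected (counted as one check), GAPDH
3′/5′ < 4.3, beta-actin 3′/5′ < 18. The defaults are the 95% range of a
large reference corpus of MAS5 arrays and are overridable; "between" is
read as a closed interval and "over"/"below" as strict, stated explicitly
because the verbal rules do not pin the endpoints. Metrics are consumed
from a precomputed table — computing them needs raw probe-level files,
which the toolkit deliberately does not parse; arrays whose metrics are
all missing raise an error (QC is simply not possible for such cohorts),
and individual missing metrics are `unevaluated`, never failures. Failure
counts map to status: 0 pass, 1 outlier (droppable via
`exclude_outlier_arrays`), ≥ 2 excluded (always dropped).

**Normalization and duplicates.** Each array is rescaled to mean 1000
(idempotent; columns means equal the target to ~1e−13 relative). Because
the rescaling is monotone within an array, it cannot change rank-based
duplicate detection: all pairs of arrays are compared by the Spearman
correlation of their common-probe expression ranks (midranks for ties),
and pairs at or above 0.99 are reported once each. The threshold is a
choice — exact rank identity would miss files that round-tripped through
different numeric formats — and is configurable; fewer than 3 common
probes makes the correlation degenerate and is refused. The O(n²) scan is
fine at desk scale (thousands of arrays).

**Pairwise rank randomness test.** To check that a clinical variable does
not drift along the database assembly order, each value is compared with
all later values; under randomness P(earlier > later) = 1/2. The
statistic S = #(earlier > later) − #(earlier < later) uses the
Mann–Kendall normal approximation, variance $n(n-1)(2n+5)/18$, with a
continuity correction; for fewer than 10 tie-free values the exact
permutation distribution of S (Mahonian counts, computed by dynamic
programming) replaces the approximation. Ties contribute ½ to the
concordant fraction and 0 to S.

## The synthetic-data generator

The simulator is first-class, tested code, not a fixture. It emulates the
statistical structure the analysis assumes:

* **Expression**: per-probe log-normal intensities, location
  $\mathcal{N}(\log 400, 0.7)$ and log-scale spread 0.8, giving positive
  MAS5-like values with realistic dynamic range.
* **Survival**: exponential proportional hazards. The baseline rate
  $\log 2 / 40$ per month corresponds to a median survival of 40 months,
  matching a surgically resected NSCLC series; the hazard is multiplied
  by $e^{\beta}$ above the planted probe's true cutoff (a quantile of its
  theoretical distribution), so the planted effect acts on the
  dichotomized indicator — exactly the analysis model, which makes
  recovery tests well-posed.
* **Censoring**: independent uniform on $[0, c_{\max}]$, with
  $c_{\max}$ solved numerically so the expected censoring fraction hits
  the configured target (default 0.5, typical of such series where about
  half the patients are alive at last follow-up); the empirical fraction
  lands within a few points at n = 1000.
* **Covariates**: drawn independently of survival at frequencies typical
  of a pooled NSCLC database — 58% male, 17.8% never smokers, histology
  adeno/SCC/large ≈ 50/45/5, stage 1–4 ≈ 63/27/10/1, grade
  poor/moderate/well ≈ 34/53/13, age $\mathcal{N}(64, 10)$, 95% negative
  margins, 29% chemotherapy, 21% radiotherapy. A first-progression
  endpoint (1.5× the OS hazard) is generated for the first half of the
  datasets only, emulating cohorts that never published progression.
* **Planted defects**: a configurable number of arrays get two failing QC
  metrics (excluded) or exactly one (outlier); duplicate arrays are
  literal re-publications of first-dataset columns inside the second.
  The truth (β, HR, cutoff, violations, duplicates, seed) is serialized
  next to every corpus.

What the simulator does **not** emulate: probe–probe correlation,
platform/batch effects beyond a per-array scale, non-proportional
hazards, informative censoring, or covariates correlated with outcome.
Passing recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not robustness to their
violation on real cohorts.

## Numerical choices and degenerate inputs

* Zero survival times are bumped to half the smallest positive time with
  a warning, so every sample contributes risk time.
* Constant covariates and perfect separation (monotone partial
  likelihood) raise typed errors rather than returning unstable
  estimates.
* Candidates leaving a group empty are skipped inside the scan; a scan
  with no valid candidate (constant expression, all-tied splits) is an
  explicit error.
* All-zero arrays cannot be scale-normalized and are refused.
* Simulation restores the caller's RNG state, so corpora are reproducible
  from their seed without side effects on the session.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while keeping each check
well-powered: oracle-equivalence over 100 random instances of n = 60;
parameter recovery on three cohorts of 200 (planted HR 2, ~20%
censoring) across 50 replicates; the null-calibration study with 200
simulations of n = 100; QC/duplicate recovery on 20 arrays of 150
probes. Coverage of the planted HR by the reported 95% interval runs at
roughly 94% in this regime; the slight shortfall from nominal is the
expected cost of reusing the data-chosen cutoff in the interval's own
model.

## Known limitations

* The reported p at the selected cutoff is nominal; see the multiplicity
  discussion above.
* Only two-group dichotomization is supported — no tertiles, no
  continuous-expression models, no stratified or time-varying Cox, no
  competing risks.
* Probes mapping to several genes are flagged but not resolved; gene
  lookup uses the annotation as given.
* The toolkit consumes already-normalized intensity matrices plus a
  precomputed QC table; it neither parses raw array files nor re-derives
  the QC reference ranges.
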