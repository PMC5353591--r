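# funlung

Functional lung dosimetry and toxicity association analysis for thoracic
radiotherapy.

Anatomical dose–volume predictors of radiation-induced lung toxicity
(RILT) — V20, the percentage of lung receiving ≥ 20 Gy, and MLD, the mean
lung dose — treat all lung tissue as equal. V/Q SPECT shows it is not:
perfusion (Q) and ventilation (V) tracer maps reveal which lung actually
works. `funlung` restricts the classical metrics to *functional* lung,
defined as the lung voxels with SPECT activity at or above 30% of the
within-lung maximum:

- segmentation: `FL = { v ∈ lung : A(v) ≥ 0.30 · max_lung A }`,
  identically for Q and V;
- dosimetry: cumulative DVH `S(d) = 100 · #{v : D(v) ≥ d} / #mask`,
  `Vx = S(x)`, `MLD = mean(D)` over the mask, giving the six per-patient
  metrics V20, MLD, Q-V20, Q-MLD, V-V20, V-MLD;
- cohort statistics: tie-corrected Spearman correlation of each metric
  with the binary RILT event (grade ≥ 2), overall and stratified by COPD,
  PFT class, tumor location and stage, with per-stratum dominance labels
  ("Q ≈ V > CT") and baseline-characteristic tests (chi-square / Fisher
  by the expected-count-5 rule).

Digital thorax phantoms, a worked-example fixture pair and a
Gaussian-copula cohort simulator generate every input the pipeline needs,
so the whole analysis is testable without patient data. Volumes are read
and written as NIfTI; results are tibbles with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Two phantoms with identical anatomical V20 but different functional
burdens — the classic case for functional dosimetry:

```r
library(funlung)

fx <- figure1_fixture()
analyze_bundle(fx$rilt_case)$metrics
#> # A tibble: 1 x 7
#>   patient_id   V20   MLD Q_V20 Q_MLD V_V20 V_MLD
#>   <chr>      <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 case          25    15    35    17    33  16.6
analyze_bundle(fx$non_rilt_case)$metrics
#> 1 case          25    15    20    14    22  14.4
```

Both phantoms have V20 = 25%, yet the first concentrates far more dose in
functional lung (Q-V20 35% vs 20%, V-V20 33% vs 22%) — exactly the
pattern that separates the toxicity case from the control.

Cohort-level analysis on a simulated 57-patient cohort with a planted
strong functional / weak anatomical association:

```r
co <- simulate_cohort(cohort_spec(), seed = 42)
glance(subgroup_correlations(co))
#> # A tibble: 9 x 4
#>   subgroup         n dominance  best_metric
#> 1 All patients    57 Q ≈ V > CT Q_V20
#> ...
```

A thin CLI over the same functions lives at `inst/cli/funlung.R`
(subcommands `segment`, `dvh`, `metrics`, `cohort-stats`, `simulate`,
`fixtures`, `run`).

## Package layout

- `R/grid.R`, `R/nifti-io.R` — volumetric data model, alignment,
  resampling, NIfTI I/O
- `R/segment.R` — functional lung segmentation and V/Q mismatch reports
- `R/dosimetry.R` — DVH curves, Vx, MLD, activity-weighted variants
- `R/cohort-stats.R` — Spearman statistics, subgroup tables, dominance
  labels, characteristic comparisons
- `R/phantom.R`, `R/figure1.R`, `R/cohort-sim.R` — synthetic data
- `R/config.R`, `R/pipeline.R` — configuration and the end-to-end runner
- `vignettes/functional-lung-dosimetry.Rmd` — models, parameters and
  design choices in full
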