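# immunoscoreTx

Transcriptomics-based T-cell immunoscore: immune deconvolution of bulk
RNA-seq, cross-validated percentile scoring of CD3+/CD8+ T-cell density,
and survival stratification.

## The problem

The immunoscore summarizes the density of CD3+ (pan-T) and CD8+
(cytotoxic) tumor-infiltrating T cells; higher infiltration is associated
with better prognosis, particularly under immune checkpoint inhibitor
(ICI) therapy. Direct immunohistochemical measurement is often unavailable
in real-world cohorts that do carry bulk tumor RNA-seq. This package
implements the computational route around that gap, for analysts working
with bulk expression plus survival follow-up:

1. **Deconvolution.** A bulk TPM profile *m* is regressed on an LM22-style
   leukocyte signature matrix *S* (547 genes x 22 cell types by default)
   with linear-kernel nu-support-vector regression over the grid
   nu ∈ {0.25, 0.5, 0.75}; the best-RMSE fit is kept, negative
   coefficients are truncated and the rest renormalized, giving cell-type
   fractions *f* ≥ 0, Σf = 1 (the published CIBERSORT core; the
   proprietary CIBERSORTx batch-correction modes are out of scope).
2. **T-cell densities.** CD3 = Σ fractions over the signature's seven
   declared T subsets; CD8 = the "T cells CD8" fraction, so
   0 ≤ CD8 ≤ CD3 ≤ 1.
3. **Immunoscore.** With mid-rank empirical percentiles
   P(x | training) = 100·(#{t < x} + ½#{t = x})/n, each patient's score in
   one cross-validation iteration is
   ½·[P(CD3ᵢ | train) + P(CD8ᵢ | train)] evaluated out-of-fold; 20
   iterations of 5-fold CV are averaged into the final score in [0, 100].
4. **Dichotomization.** Category "low" (0) vs "intermediate-high" (1) at a
   fixed 25th-percentile cut-off, or at a Youden-optimized cut-off:
   per iteration, the threshold c maximizing
   J(c) = sensitivity + specificity − 1 (death as the positive class,
   score < c as test-positive) is expressed as a percentile of that
   iteration's scores and averaged.
5. **Survival.** Kaplan-Meier curves with Greenwood log(−log) 95% bands,
   two-group log-rank test, univariate Cox hazard ratio (Breslow ties) and
   Harrell's C-index per CV iteration, aggregated as mean ± 1.96·sd/√k.

A synthetic-cohort generator (Dirichlet cell fractions, multiplicative
log-normal expression noise, exponential survival whose hazard falls with
CD3 abundance, independent right-censoring) provides ground truth for
every stage.

## Worked example

```r
library(immunoscoreTx)

cohort <- simulateCohort(SyntheticConfig(nPatients = 200, nGenes = 100,
                                         nCellTypes = 6, nTCellTypes = 3,
                                         seed = 42))
report <- analyzeCohort(cohort@expression, signatureMatrix(cohort),
                        survivalRecords(cohort), scheme = CVScheme(seed = 42))
report
#> CohortReport [whole cohort]: 200 patients
#>   fixed_25         pct  25.0 | low  50 (25.0%) | C 0.6081 (0.6051, 0.6111) | log-rank p 7.92e-07
#>   youden           pct  80.2 | low 160 (80.0%) | C 0.6223 (0.6208, 0.6237) | log-rank p 8.05e-06

report@densities
#> TCellDensities: 200 samples | mean CD3 0.487, mean CD8 0.150
```

Reading the output: under the fixed cut-off, the 50 patients (25%) with
the lowest cross-validated immunoscore form the "low" category; their
survival differs from the rest at log-rank p ≈ 8e-07, and the
category's CV-averaged Harrell C-index of 0.61 (95% CI 0.605-0.611) means
the dichotomized score correctly orders about 61% of comparable patient
pairs — the simulated protective CD3 effect is recovered. The Youden row
repeats the analysis at the cut-off percentile optimized per CV iteration
(80.2 here: with this cohort's strong effect, J keeps climbing along the
score distribution).

Per-histology analysis (`stratifiedReport()`) and a file-driven run
(`runPipeline()` with a YAML/JSON config) produce the same report shape
per stratum, including stratum-specific Youden optima. A thin CLI covering
`simulate`, `deconvolve`, `score`, `report` and `run-all` lives at
`inst/scripts/immunoscore-cli.R`:

```sh
Rscript inst/scripts/immunoscore-cli.R simulate --out cohort --n 522 --seed 1
Rscript inst/scripts/immunoscore-cli.R run-all --config cohort/config.json --out report
```

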