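---
title: "Methods: the transcriptomics-based T-cell immunoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the transcriptomics-based T-cell immunoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `immunoscoreTx`, the parameters
that matter, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## 1. Signature-regression deconvolution

### Model

A bulk tumor expression profile is modeled as a non-negative mixture of
reference cell-type profiles: for sample $i$ with per-gene abundance
vector $m_i$ (linear TPM) and signature matrix $S$ (genes $\times$ cell
types),

$$ m_i \approx S f_i, \qquad f_i \ge 0, \quad \textstyle\sum_k f_{ik} = 1. $$

`deconvolveSample()` implements the support-vector flavor of this
regression: after intersecting genes (at least 50% of the signature genes
must be present), the signature matrix is standardized *globally*
(subtract its overall mean, divide by its overall standard deviation) and
the mixture by its own mean and standard deviation; a linear-kernel
$\nu$-SVR is fitted for each $\nu \in \{0.25, 0.5, 0.75\}$; the fit whose
truncated-and-renormalized coefficients reconstruct the standardized
mixture with the lowest RMSE wins. Negative coefficients are set to zero
and the remainder renormalized to proportions.

**Why global, not per-column, standardization.** Write
$y = \sum_k f_k S_k$. Under a single affine transform applied to all of
$S$ (global standardization), the regression weights of the standardized
problem remain proportional to $f$, with the offset absorbed by the SVR
intercept, so renormalized weights recover the proportions exactly on
noiseless mixtures. Standardizing each column by its *own* standard
deviation $s_k$ instead would scale weight $k$ by $s_k$, and the
renormalized weights would become $f_k s_k / \sum_j f_j s_j$ — a bias of
several percent whenever column scales differ. The global convention is
therefore the package's contract, and the unit tests verify noiseless
recovery to well under 0.02 absolute error per component against both the
ground truth and a non-negative least-squares oracle solved on the same
standardized system (with a free intercept, since global standardization
does not zero column means).

### Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `nuGrid` | 0.25, 0.50, 0.75 | $\nu$ bounds the fraction of support vectors; the small grid with best-RMSE selection is the established practice for this regression and is cheap. |
| gene overlap | $\ge$ 50% | below this, the signature no longer identifies the cell types; hard error rather than silent degradation. |
| `nPermutations` | 0 (off); 100 when used | gene-label shuffling null for the selected-fit correlation; the add-one estimator $(1 + \#\{r_{null} \ge r_{obs}\})/(n+1)$ avoids $p = 0$. Minimum 10 permutations. |

Degenerate inputs are explicit errors: an empty gene intersection, a
zero-variance mixture (standardization undefined), or a mixture whose
coefficients are all truncated to zero for every $\nu$. Inside the
permutation test only, a degenerate *shuffled* fit is recorded as
correlation $-\infty$ so the null statistic is total; a degenerate
observed mixture then lands near $p = 1$.

Quantile normalization is **not** applied to mixtures: the input contract
is RNA-seq TPM, for which the reference implementations of this
deconvolution disable it. Batch-correction modes that require the
proprietary service are out of scope.

### Expression input scale

The deconvolution contract is linear TPM. Matrices encoded as
$\log_2(\mathrm{TPM}+1)$ (a common storage convention) carry a scale tag
and are inverted cell-wise by `toLinearTPM()` ($2^x - 1$, tiny negatives
from rounding clamped to 0). Duplicate gene rows collapse by arithmetic
mean — deterministic and order-independent. CD3 density is the summed
fraction of the signature's declared pan-T subsets (the seven T-cell
columns of an LM22-style matrix); CD8 is the declared "T cells CD8"
column. These are *relative* leukocyte fractions standing in for the
histological densities of the original immunoscore — an imputation, not a
measurement.

## 2. The cross-validated percentile immunoscore

Percentiles use the mid-rank convention,
$P(x \mid T) = 100\,(\#\{t < x\} + \tfrac12 \#\{t = x\})/|T|$: ties are
split symmetrically, and a cohort of identical densities scores exactly
50. A patient's score in one CV iteration is the mean of the CD3 and CD8
percentiles evaluated against the *other* folds; the final score averages
the `nIterations` (default 20) iteration scores from `nFolds`-fold
(default 5) partitions. Fold assignment is a balanced shuffle from the
scheme's seed, stratified by the event indicator by default so every
training split contains both outcome classes. Scoring is monotone: a
patient dominating another in both densities never scores lower.

### Cut-offs

* **Fixed percentile** (default 25): the classical lower-quartile rule.
* **Youden**: per CV iteration, candidate thresholds are the midpoints
  between consecutive distinct scores plus one sentinel below the minimum
  and one above the maximum (so the all-positive and all-negative
  dichotomizations are representable and $J_{max} \ge 0$); death
  (event = 1) is the positive class and "score < c" test-positive; ties
  in $J$ break toward the smallest threshold, with a $10^{-9}$ tolerance
  absorbing float noise between mathematically equal $J$ values (true
  $J$ differences are bounded below by $1/n^2$). The winning threshold is
  re-expressed as a mid-rank percentile of that iteration's scores, and
  the per-iteration percentiles are averaged into the resolved cut-off.

The binary label for Youden's J is the raw event indicator; follow-up
time is ignored at this step (the log-rank test and C-index downstream do
use it). This is the one binary outcome available without choosing an
arbitrary time horizon; it is a known simplification.

Categorization takes the resolved percentile of the cohort's own final
scores (quantile type 7) as the threshold; scores strictly below are
"low" (0), ties and above are "intermediate-high" (1) — "low" is the
strict lower tail. The threshold is taken over the whole cohort's scores
rather than per training fold: the final score is already CV-averaged,
and a single threshold makes the category reproducible from the published
score vector alone.

## 3. Survival statistics

Estimation stands on the `survival` package: product-limit curves with
Greenwood variance and log(−log) 95% bands (clamped to $[0,1]$; where the
transform is undefined at survival 1 or 0 the band collapses onto the
estimate), the standard two-group log-rank chi-square, and a univariate
Cox fit with Breslow tie handling (convergence tolerance $10^{-9}$, at
most 100 iterations; the partial-likelihood gradient at the estimate is
verified below $10^{-8}$ in the tests). Zero survival times are shifted
to $10^{-6}$ with a warning; negative times are errors. A group without
events makes the Cox likelihood monotone; the estimate is returned with a
`flagged` marker and a warning.

Harrell's C is computed in-package with an explicit pair definition: a
pair is comparable when the earlier time is an observed death, or the
times are tied with exactly one death (the censored patient counts as the
longer survivor); the pair is concordant when the longer survivor has the
*higher* score (values above 0.5 mean a protective score), and tied
scores contribute ½. `survival::concordance` serves as an independent
cross-check in the tests, never as the implementation.

The reported C-index follows the cross-validation structure: each
iteration's scores are dichotomized at the cut-off percentile of that
iteration's own distribution (the binary category is what the analysis
stratifies on; a flag switches to the continuous score), the C-index is
computed per iteration, and the $k$ values are aggregated as
mean $\pm\, 1.96\,\mathrm{sd}/\sqrt{k}$ — a normal approximation across
iterations, matching the "average C-index (95% CI)" reporting convention.
These iteration values share patients and are not independent, so the
interval describes CV stability, not sampling error of the cohort.

## 4. The synthetic-data generator

`simulateCohort()` draws, per patient: cell fractions from a symmetric
Dirichlet; bulk expression as signature $\times$ fractions with
multiplicative log-normal noise, columns rescaled to TPM totals
($10^6$); an exponential survival time with hazard
$h_0 \exp\{\beta\,(\mathrm{cd3}_i - \overline{\mathrm{cd3}})\}$; and an
independent censoring coin that, when it lands, truncates the record at a
uniform fraction of its event time (administrative, non-informative —
what KM and Cox assume). Histology labels are assigned round-robin. The
signature generator gives every cell type a disjoint block of ~12-fold
marker genes, which keeps the globally standardized matrix well
conditioned (condition number below 100 at the default geometry).

Default study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| signature | 547 genes, 22 types, 7 T subsets | the LM22 geometry the pipeline targets. |
| `dirichletConcentration` | 2 per type | mean CD3 content $7/22 \approx 0.32$ of leukocytes with realistic spread. |
| `noiseSd` | 0.3 | log-normal multiplicative noise giving true-vs-estimated CD8 correlation ~0.95 — noisy but informative, in line with bulk deconvolution practice. |
| `baselineHazard` | $\ln 2 / 10.5$ per month | 10.5-month median time-to-event at the mean CD3 density, the scale of ICI-treated advanced-malignancy cohorts. |
| `logHrPerUnitCd3` | −8 | protective; with the Dirichlet spread above this yields a low-vs-high category hazard ratio near 2, the magnitude reported for immunoscore stratification in the literature. |
| `censoringRate` | 0.47 | roughly half the cohort censored, matching real-world ICI follow-up. |
| `nCancerTypes` | 4 | four histology strata of near-equal size. |

What the generator does **not** emulate: count-level RNA-seq noise
(negative binomial per read), batch effects, tumor purity confounding,
correlated marker programs across cell types, non-proportional hazards,
informative censoring. Passing tests therefore demonstrate that the
pipeline recovers known structure under its own model assumptions — not
that it is robust to everything real cohorts do.

## 5. Pipeline and problem sizes

`analyzeCohort()` inner-joins patient ids across inputs (dropped ids are
warned about explicitly), and all randomness flows from one root seed via
deterministic child seeds, so a rerun is byte-identical.
`stratifiedReport()` re-runs scoring, cut-off resolution and survival
independently per stratum; cell fractions are deconvolved once for the
joined cohort, because the deconvolution of a sample depends only on that
sample's mixture and the signature — re-running it inside a stratum would
reproduce the same numbers at pure cost.

Validation problem sizes (the package's own choices): deconvolution
accuracy is checked at the full 547 × 22 geometry (50 noiseless samples,
MAE; 200 noisy samples, CD8 correlation); the percentile/Youden machinery
against exhaustive oracles on 1000 random instances; coverage at
$n = 1000$ over 20 seeds; threshold recovery at $n = 300$ over 20 seeds;
Cox recovery at 500 per group over 20 seeds; the KM median on
$n = 5000$ exponential cohorts. End-to-end runs use 522 patients in four
strata with a 200-gene, 22-type signature — the SVR stage scales roughly
quadratically in genes, and 200 genes (9 markers per type) preserves the
recovery behavior while keeping repeated whole-cohort runs fast.

## 6. Known limitations

* Fractions are relative to total leukocyte content; an "absolute mode"
  score is not implemented, so CD3/CD8 are comparable across samples only
  under similar overall immune content.
* One tumor compartment: bulk RNA mixes core and margin; the original
  core-vs-invasive-margin distinction of the histological immunoscore
  cannot be expressed.
* The Youden label ignores censoring time (see §2).
* The C-index CI reflects CV stability, not cohort-level sampling error.
* No multivariable adjustment (age, performance status, line of therapy),
  competing risks, or time-varying effects in the Cox stage.
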