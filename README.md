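# ldsem

Multivariate LD score regression and genomic structural equation models for
GWAS summary statistics, in R.

## What this package is for

Many questions about the shared genetics of behavioral traits must be
answered from published GWAS summary statistics alone — per-variant effect
sizes, standard errors, and sample sizes, with no individual-level data. The
motivating analysis asks how much of the genetic liability shared by alcohol
consumption, alcohol problems, and suicide attempt overlaps with five
impulsivity facets (negative urgency, positive urgency, lack of
premeditation, sensation-seeking, lack of perseverance). `ldsem` implements
the whole analysis chain as tested, reusable functions:

1. **Harmonization / QC** (`read_sumstats()`, `munge()`): allele matching
   against an LD-score reference with strand-flip and allele-swap
   resolution, INFO ≥ 0.90 and MAF ≥ 0.01 filters, removal of
   strand-ambiguous variants; effective sample sizes
   `Neff = 4v(1−v)n` for case-control cohorts (`effective_sample_size()`).
2. **Conditioning** (`select_instruments()`, `estimate_bxy()`,
   `condition_sumstats()`): removes the component of one trait's effects
   mediated by an exposure trait, via inverse-variance-weighted Wald ratios
   over genome-wide-significant instruments (p < 5×10⁻⁷).
3. **LD score regression** (`estimate_h2()`, `estimate_gcov()`,
   `build_S_V()`): SNP heritabilities from the regression
   `E[χ²_j] = 1 + Na + (N h²/M) ℓ_j`, genetic covariances from
   `E[z₁ⱼz₂ⱼ] = ρ₀ + (√(N₁N₂) ρ_g/M) ℓ_j`, liability-scale conversion for
   binary traits, and the block-jackknife sampling covariance **V** of the
   whole genetic covariance matrix **S**.
4. **Genomic SEM** (`model_spec()`, `fit_dwls()`): declarative structural
   models fitted to (S, V) by diagonally weighted least squares,
   `F(θ) = (s−σ(θ))' diag(V)⁻¹ (s−σ(θ))`, with sandwich standard errors,
   a residual-based χ² model test, AIC/CFI/SRMR, and a fully standardized
   solution.
5. **Model battery** (`run_battery()`): the six model families of the
   motivating analysis — common factor, five-factor impulsivity CFA,
   combined correlational model, two alternative factorizations, and seven
   multivariable genetic regressions.
6. **Synthetic data** (`canonical_truth()`, `simulate_sumstats()`, ...):
   a summary-level simulator with known latent-factor ground truth, used by
   the test suite and the acceptance script.
7. **Pipeline** (`run_pipeline()`): the full chain from a single YAML/JSON
   config, with persisted intermediates and a run manifest
   (`inst/scripts/ldsem-pipeline.R` is a thin command-line wrapper).

## Worked example

Simulate the canonical 12-trait scenario (heritabilities and sample sizes
mirroring the real GWAS inputs), estimate the genetic covariance structures,
and fit the common factor model:

```r
library(ldsem)
truth <- canonical_truth(seed = 1)
ref <- simulate_ld_reference(truth$M, truth$n_blocks, seed = 1)
ss <- simulate_sumstats(truth, ref)
munged <- lapply(ss, munge, ref = ref)
gs <- build_S_V(munged, ref, M = truth$M, n_blocks = truth$n_blocks)
fit <- fit_dwls(spec_common_factor(), gs, n_restarts = 1)
fit
```

```
<fit_result> 'common_factor': chi2(5) = 7.17, p = 0.208, AIC = 27.17, CFI = 0.999, SRMR = 0.010
      param op  free     est       se est_std  se_std         p   sig
1   Cg=~ALC =~  TRUE 0.25448 0.005284   0.944 0.01607  0.00e+00  TRUE
2   Cg=~DPW =~  TRUE 0.20810 0.003394   0.961 0.00932  0.00e+00  TRUE
3   Cg=~ALP =~  TRUE 0.15863 0.003324   0.835 0.01201  0.00e+00  TRUE
4   Cg=~DEP =~  TRUE 0.22768 0.006727   0.660 0.01802 4.06e-251  TRUE
5    Cg=~SA =~  TRUE 0.05468 0.003661   0.273 0.01859  1.87e-50  TRUE
...
```

The standardized loadings (0.944, 0.961, 0.835, 0.660, 0.273) recover the
generating values (0.93, 0.97, 0.84, 0.65, 0.27) within sampling error, and
the model χ² is consistent with correct specification. The combined
correlational model then gives the factor correlations of interest:

```r
bat <- run_battery(gs, models = "combined", n_restarts = 1)
bat$correlations
```

```
      param        rg         se             p  sig
1 Cg~~F_NEG 0.2401746 0.01726113  1.119692e-48 TRUE
2 Cg~~F_POS 0.3780597 0.01914219  2.238892e-72 TRUE
3 Cg~~F_PRE 0.5472612 0.02537156 3.446354e-103 TRUE
4 Cg~~F_SEN 0.2499496 0.02138164  1.435213e-31 TRUE
5 Cg~~F_PER 0.2653074 0.01770451  2.313942e-53 TRUE
```

— correlations of the common alcohol/suicide factor with the five
impulsivity factors (generating values 0.24, 0.39, 0.53, 0.26, 0.30; lack
of premeditation highest, as in the motivating analysis).

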