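---
title: "Methods: multivariate LD score regression and genomic SEM in ldsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate LD score regression and genomic SEM in ldsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldsem)
```

## The problem

GWAS of behavioral phenotypes are usually published as summary statistics:
per-variant effect sizes, standard errors, and sample sizes, without
individual-level data. `ldsem` implements the full chain of analyses needed
to ask a multivariate question of such data — here, how much of the genetic
liability shared by alcohol consumption, alcohol problems, and suicide
attempt overlaps with five impulsivity facets (negative and positive
urgency, lack of premeditation, sensation-seeking, lack of perseverance) —
and a synthetic-data generator with known ground truth so that every stage
can be validated.

The chain is: harmonization and quality control of per-trait summary
statistics; optional conditioning of one trait on another (suicide attempt
on major depression in the motivating analysis); LD score regression (LDSC)
estimates of SNP heritability and genetic covariance; a block-jackknife
sampling covariance of all those estimates; and structural equation models
fitted to the genetic covariance matrix by diagonally weighted least squares
(genomic SEM).

## Models and estimators

### LD score regression

For variant $j$ with LD score $\ell_j$ (the sum of squared correlations with
neighboring variants), sample size $N$, and $M$ polymorphic variants, the
polygenic model implies
$$E[\chi^2_j] = 1 + Na + \frac{N h^2}{M}\,\ell_j,$$
so the slope of a weighted regression of $\chi^2_j = z_j^2$ on $N\ell_j/M$
estimates the observed-scale SNP heritability $h^2$, and the free intercept
$1+Na$ absorbs uncontrolled confounding. For two traits,
$$E[z_{1j} z_{2j}] = \rho_0 + \frac{\sqrt{N_1 N_2}\,\rho_g}{M}\,\ell_j,$$
with the genetic covariance $\rho_g$ as slope and the intercept $\rho_0$
absorbing sample overlap. Heritability is implemented as the self-pair of
the covariance regression under one shared weighting scheme,
$w_j = 1/\!\left(\ell_j\,(a_{1j}a_{2j} + c_j^2)\right)$ with
$a_{ij} = 1 + N_i \hat h^2_i \ell_j / M$ and $c_j$ the first-pass fitted
mean of $z_{1j}z_{2j}$ — a two-pass approximation to the inverse variance of
the products. This choice makes the self-covariance identity
(`estimate_gcov(ss, ss)` equals `estimate_h2(ss)`) exact.

Standard errors come from a delete-one-block jackknife over contiguous
blocks of variants (default 200 blocks), with the second-pass weights held
fixed across jackknife replicates. `build_S_V()` runs all $k$ heritability
and $k(k-1)/2$ covariance regressions on the intersection variant set and
assembles the genetic covariance matrix $S$ together with the jackknife
sampling covariance $V$ of its half-vectorization
($V = \frac{B-1}{B}\sum_b (\theta_{(b)}-\bar\theta)(\theta_{(b)}-\bar\theta)'$).
The half-vectorization order is the lower triangle in column-major order
throughout, and is stamped into serialized files.

Binary traits analysed with effective sample sizes
($N_\mathrm{eff} = 4\upsilon(1-\upsilon)n$ summed over cohorts) are
converted to the liability scale with
$h^2_\mathrm{liab} = h^2_\mathrm{obs}\,K^2(1-K)^2 / \!\left(P(1-P)\,\varphi(t)^2\right)$,
$t$ the upper-$K$ standard-normal quantile; with effective sample sizes the
standard convention $P = 0.5$ applies, and the population prevalence $K$ is
user configuration. The trait's rows and columns of $S$ scale by the square
root of the conversion factor (so its heritability scales by the factor) and
$V$ by the matching products.

### Conditioning

Conditioning one trait on another uses genome-wide-significant exposure
variants ($p < 5\times10^{-7}$) as instruments. Effects are first put on the
standardized per-allele scale ($b = z/\sqrt{N}$, $se = 1/\sqrt{N}$), which
makes binary/continuous mixing well-defined. The exposure-on-outcome effect
is the inverse-variance-weighted mean of per-instrument Wald ratios
$b_{zy}/b_{zx}$ with first-order delta-method variances; instrument
heterogeneity is summarized by Cochran's $Q$ (the LD-aware HEIDI outlier
step of the full mtCOJO method is out of scope — the artifact carries no
genotype panel, so greedy best-$p$-first pruning within a 100-position
window substitutes for LD clumping). Conditioning then removes
$b_{xy} b_{zx}$ from each outcome effect and inflates its variance by
$b_{xy}^2 se_{zx}^2 + b_{zx}^2 se_{xy}^2$, so conditional standard errors
never shrink.

### Genomic SEM

Structural models are declared as parameter records over observed traits
and latent factors — loadings (`=~`), regressions (`~`), and (co)variances
(`~~`) with status `free`, `fixed:<value>`, or `equal:<label>` — and held
internally in RAM form ($v = Av + u$, $\Sigma = F(I-A)^{-1}S_u(I-A)^{-T}F'$),
which treats measurement and structural paths uniformly. Identification
conventions: multi-indicator factors have unit variance with free loadings
(equated for two-indicator factors); single-indicator factors have the
loading fixed to 1, the indicator residual fixed to 0, and a free factor
variance. These conventions are the ones consistent with every reported
(df, AIC) pair of the real-data models.

Estimation minimizes the DWLS discrepancy
$F(\theta) = (s-\sigma(\theta))' D^{-1} (s-\sigma(\theta))$, $s$ the
half-vectorized $S$ and $D = \mathrm{diag}(V)$, using `nlminb` with analytic
gradients, box constraints keeping variances non-negative, deterministic
start values (loadings $0.5\sqrt{\overline{\mathrm{diag}\,S}}$, variances
half the matching diagonal, covariances zero) plus jittered restarts with a
fixed seed per restart index. The Jacobian
$\Delta = \partial\sigma/\partial\theta$ is computed analytically from the
RAM matrices; the test suite verifies it against central finite differences.
Convergence is declared when the optimizer reports success and the gradient
is small on a scale-free criterion,
$\max_i |g_i| / \max(1, |F|, \max_j [\Delta'W\Delta]_{jj}) < 10^{-6}$: the
absolute gradient itself is not meaningful because the weights
$W = D^{-1}$ can exceed $10^6$ for precisely-estimated covariance elements.

Inference uses the full $V$: sandwich covariance
$(\Delta'W\Delta)^{-1}\Delta'W V W\Delta(\Delta'W\Delta)^{-1}$; the model
test is the residual-based statistic $T = e'\,\Omega^{+}\,e$ with
$e = s - \sigma(\hat\theta)$ and $\Omega^{+}$ the rank-$(p^*-q)$
Moore–Penrose pseudoinverse of
$(I - \Delta(\Delta'W\Delta)^{-1}\Delta'W)\,V\,(\cdot)'$, referred to
$\chi^2_{p^*-q}$. Fit indices: $\mathrm{AIC} = \chi^2 + 2q$; CFI against an
independence baseline (free variances, zero covariances) estimated with the
same DWLS machinery; SRMR as the root mean square of standardized residuals
over the unique moments. The standardized solution rescales all variables to
unit variance with delta-method standard errors propagated from the
sandwich covariance.

$S$ and $V$ need not be positive definite after jackknifing; both are
eigenvalue-smoothed (eigenvalues floored at $10^{-8}$) before fitting, and
the maximum element-wise change is reported in `smoothing_report`.

## The model battery

`run_battery()` constructs and fits the analysis suite on one shared
covariance structure:

* a common factor (`Cg`) over ALC, DPW, ALP, DEP, SA (q = 10, df = 5);
* the five-factor impulsivity CFA — single-indicator factors for negative
  urgency, positive urgency, and lack of perseverance; equated two-indicator
  factors for premeditation (MED, BIS) and sensation-seeking (SEN, EXT)
  (q = 19, df = 9);
* the combined correlational model: `Cg` plus the five impulsivity factors,
  all 15 factor covariances free (q = 34, df = 44);
* a two-factor alternative with an alcohol-specific factor (ACPg) and a
  single-indicator suicide factor (SUICg) (q = 39, df = 39);
* a problems-only variant with the common factor restricted to ALP, DEP, SA
  (q = 30, df = 25);
* seven multivariable regressions of each impulsivity measure on a latent
  consumption factor (ALC + DPW), ALP, DEP, and SA simultaneously, with
  free predictor covariances. The consumption factor uses unit variance and
  free loadings; parameter counts for these models were not reported with
  the real-data analyses, so the unconstrained choice is the default.

## The synthetic-data generator

Real inputs of this kind are controlled-access consortium data, so the
package ships a summary-level simulator instead. For each variant the
$k$-vector of z-statistics is drawn from
$\mathcal{N}\!\left(0,\; \tfrac{\ell_j}{M} D_N \Sigma_g D_N + I_0\right)$,
with $\Sigma_g = \Lambda\Phi\Lambda' + \Theta$ the true genetic covariance,
$D_N = \mathrm{diag}(\sqrt{N})$, and $I_0$ the intercept matrix (confounding
on the diagonal, sample overlap off it). This simulates directly at the
summary level — no individual genotypes, no LD matrix — and therefore
matches *exactly* the second-moment model the estimators assume. That is the
key idealization: passing tests demonstrate correct estimation under the
assumed model, not robustness to LD misspecification, annotation-dependent
architectures, or stratification in real data.

The canonical configuration (`canonical_truth()`) mirrors the motivating
study: 12 traits whose heritabilities (0.0729, 0.0372, 0.1175, 0.0492,
0.0399, 0.0799, 0.0682, 0.0402, 0.0617, 0.0836, 0.0508, 0.0774) and sample
sizes (effective sizes 26,853 and 74,887 for the two case-control traits)
match the real GWAS inputs; common-factor standardized loadings (0.93,
0.97, 0.84, 0.65, 0.27) and its correlations with the impulsivity factors
(0.24, 0.39, 0.53, 0.26, 0.30) match the reported estimates. The
two-indicator factors are given equal loadings on the *covariance* scale
(so the equated-pair convention is exactly true under the generator), which
fixes the standardized pairs at (0.85, 0.69) and (0.55, 0.71). The
impulsivity inter-factor correlations are not available from the motivating
analyses; they were chosen once as moderate values inside the reported range
(0.0–0.6) and verified to give a positive-definite correlation structure.
Desk-scale dimensions are $M = 20{,}000$ variants in 50 jackknife blocks;
LD scores are shifted-gamma with mean 40.

## Numerical and experimental design choices

* **Smoothing floor** $10^{-8}$ for eigenvalues of $S$ and $V$; jackknife
  variances additionally floored at $10^{-10}$ when inverted for weights.
* **Optimizer tolerances**: objective absolute tolerance $10^{-10}$,
  relative $10^{-12}$; 5 restarts by default (1 suffices for the
  well-conditioned synthetic runs and is used inside the large replicate
  loops).
* **Problem sizes for the validation experiments** (all run by
  `scripts/acceptance.R` and the acceptance tests): LDSC null calibration
  uses $M = 20{,}000$, $N = 10{,}000$, 200 blocks, 200 replicates; coverage
  and loading recovery use the canonical configuration with 100 replicates;
  the chi-square size experiment refits the common factor model 500 times at
  $M = 20{,}000$ with **500** jackknife blocks. The block count matters for
  the last experiment: the residual-based statistic is exactly calibrated
  when $V$ is known (a unit test draws moment vectors from
  $\mathcal{N}(\sigma(\theta_0), V_0)$ and observes mean $\chi^2 \approx$ df
  and nominal size), but estimation noise in a jackknife $V$ built from few
  blocks biases the pseudoinverse statistic upward — at 50 blocks the
  empirical size roughly doubles. The size experiment therefore uses enough
  blocks for the asymptotic regime it is designed to measure, and the
  known-$V$ test separately pins down the statistic itself.
* **Instrument scenario** for conditioning validation: 50 instruments with
  standardized effects 0.1 at $N = 10^5$ (far beyond the selection
  threshold), causal effect 0.3; the noiseless variant plants direct
  effects only at non-instrument positions so the Wald ratios are exact.
* **Strand-ambiguous variants** (A/T, C/G) are always removed during
  harmonization; duplicated variant ids are removed entirely (they cannot
  be disambiguated); variants with per-variant $N$ below $0.67\times$ the
  90th percentile are dropped, mirroring conventional munging.

## Known limitations

* The simulator's independence across variants means jackknife blocks are
  exchangeable; real LD makes blocks locally correlated, and block counts
  below $p^*$ leave $V$ rank-deficient — fits still run (only
  $\mathrm{diag}(V)$ enters the weights) but chi-square calibration
  degrades, as quantified above.
* Single-step intercept estimation (no two-step $\chi^2 < 30$ filtering) and
  fixed second-pass weights across jackknife replicates are simplifications
  relative to the reference LDSC software.
* The conditioning estimator is a simplified mtCOJO: no HEIDI outlier
  removal, position-window pruning instead of LD clumping. It is validated
  by parameter recovery on synthetic data, not by reproducing any real
  conditioned statistics.
* Maximum-likelihood estimation, ordinal/threshold inputs,
  annotation-stratified heritability, and SNP-level factor GWAS are out of
  scope.

## A minimal worked run

```{r, eval = FALSE}
truth <- canonical_truth(seed = 1)
ref <- simulate_ld_reference(truth$M, truth$n_blocks, seed = 1)
ss <- simulate_sumstats(truth, ref)
munged <- lapply(ss, munge, ref = ref)
gs <- build_S_V(munged, ref, M = truth$M, n_blocks = truth$n_blocks)
bat <- run_battery(gs)
bat$fits$combined_primary
bat$correlations
```
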