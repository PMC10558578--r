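---
title: "Methods: two-sample MR mediation with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The question and the model

`mrmediate` decomposes the causal effect of an exposure (e.g. standardised
body-mass index or waist-hip ratio) on an outcome (e.g. grip strength in kg)
into the part transmitted through a mediator (e.g. log C-reactive protein, a
chronic-inflammation marker) and the part that bypasses it. Two parallel
arms estimate the same three quantities:

* **MR arm** (summary statistics only). Genetic variants are instruments.
  The *total* effect comes from univariable two-sample MR on the exposure's
  instruments; the *direct* effect conditional on the mediator comes from
  multivariable MR (MVMR) on the union of exposure and mediator
  instruments; the *indirect* effect is their difference
  (`indirect = total - direct`), with a propagation-of-errors SE
  `sqrt(se_total^2 + se_direct^2)` that assumes the two estimates are
  uncorrelated.
* **Observational arm** (individual-level data). Two least-squares
  regressions — mediator on exposure plus covariates, and outcome on
  exposure, mediator and covariates — plus the total-effect model. With
  identical covariate sets the difference `total - direct` equals the
  product `a1 * b2` of the exposure-to-mediator and mediator-to-outcome
  coefficients exactly (an OLS identity the code asserts at run time); the
  indirect SE uses the delta method on the product form
  (`sqrt(b2^2 se_a1^2 + a1^2 se_b2^2)`), which unlike zero-covariance
  propagation reflects that both coefficients are estimated.

Everything downstream assumes linear, homogeneous effects without
exposure-mediator interaction; "direct" and "indirect" are the usual
difference/product-method quantities of linear mediation, not
counterfactual natural effects.

## Instrument assembly

`assemble_mvmr_instruments()` reproduces the standard MVMR selection rule:

1. keep SNPs reaching genome-wide significance (`p < 5e-8`, strict) for
   *either* trait;
2. greedy LD clumping of the union: visit SNPs by ascending p (ties broken
   by rsid), accept a SNP iff its r² with every accepted SNP within 250 kb
   is below 0.001; cross-chromosome pairs never clump, and when positions
   are unavailable the r² test is applied to all pairs (conservative);
3. look every survivor up in all three summary sets; a SNP missing from one
   set may be replaced by a proxy with r² strictly above 0.8 that is present
   in *all* sets (highest r², then smaller p, then lexicographic rsid);
   SNPs without proxies are dropped and counted;
4. harmonize alleles to the exposure's effect-increasing allele.

Harmonization flips swapped alleles (negating beta, complementing the
frequency), matches strand complements by complementing, and resolves
palindromic (A/T, C/G) SNPs by allele-frequency concordance only when both
frequencies fall outside [0.42, 0.58]; otherwise the SNP is dropped. The
source GWAS do not disclose how palindromic SNPs were handled, so this
conservative frequency rule is the package's own choice and is flagged in
the per-SNP `palindromic` column and the drop report. Proxy effect sizes
are used as-is after alignment (no r²-attenuation correction). Coordinates
are taken to be 1-based on a single shared build; joins are by rsid, never
by position.

The accounting identity
`n_panel = n_union - n_clumped - n_unavailable - n_dropped_harmonize`
is checked exactly in the tests.

## Estimators

**Wald ratios and IVW.** Per SNP, `r_j = beta_out_j / beta_exp_j` with
first-order SE `se_out_j / |beta_exp_j|` (no second-order term), weights
`w_j = beta_exp_j^2 / se_out_j^2`. The IVW estimate is the weighted mean;
its fixed-effect SE `1/sqrt(sum w)` is inflated by
`max(1, sqrt(Q/(k-1)))` — multiplicative random effects, with the floor at
1 so under-dispersion never shrinks the SE. The ratio form and the
weighted through-origin regression form are algebraically identical with
these weights; the tests verify both routes against each other.

**Heterogeneity.** Cochran's `Q = sum w_j (r_j - ivw)^2` on `k-1` df and
`I² = max(0, (Q - df)/Q) * 100`.

**MR-Egger.** Weighted regression with intercept after orienting exposure
betas non-negative (joint per-SNP sign flips, so results are invariant to
allele coding); the intercept tests directional pleiotropy, the slope is
the causal estimate under InSIDE. Degrees of freedom `k-2`.

**Weighted median.** The inverse-variance-weighted empirical quantile
function of the ratios interpolated at 0.5; consistent while SNPs carrying
at least half the weight are valid. The SE comes from a parametric
bootstrap (default 2,000 iterations) that redraws each beta from a normal
with its reported SE; a seed is mandatory and recorded in the output. The
bootstrap count and SE method are not dictated by any convention, so they
are explicit metadata.

**MVMR.** Weighted regression of outcome betas on (exposure, mediator)
betas without intercept, weights `1/se_out^2`, RE scaling on `k-2` df;
MVMR-Egger adds the intercept after exposure orientation (df `k-3`).
Identically-zero beta columns are dropped (with a message) before the rank
check, so the nested univariable model is recovered exactly; genuine
collinearity is a hard error naming the aliased column.

**Conditional F.** Two-sample Q-based formulation with cross-trait
sampling covariance fixed at zero (non-overlapping estimation samples):
`F = min_delta sum (b1 - delta b2)^2 / (se1^2 + delta^2 se2^2) / (k-1)`,
minimised by golden-section search with a 2,001-point grid guard and
automatic interval widening. When the conditioning betas are identically
zero the profile carries no regression information and the minimisation
degenerates (the denominator can grow without bound), so `delta = 0` is
used by construction, recovering the univariable mean F. The rule-of-thumb
adequacy threshold is 10.

**Q_A and Q-het.** The generalised heterogeneity statistic
`Q_A(tx, tm) = sum (by - tx bx - tm bm)^2 /
(sey^2 + tx^2 sex^2 + tm^2 sem^2 + 2 tx tm rho sex sem)` with `rho` the
within-sample phenotype correlation (zero for non-overlapping samples; a
stratum-specific `phenotype_correlation()` matrix otherwise — the exact
functional form of the cross-term is stated here because published
descriptions leave it implicit). Values above ~k suggest pleiotropy or
weak instruments. `qhet_estimate()` minimises Q_A by Nelder-Mead from the
MVMR-IVW solution (reltol 1e-8) with an 11x11 grid fallback spanning ±5
starts, and builds percentile CIs from a parametric bootstrap (default
2,000 replicates, seed mandatory, >1% replicate non-convergence is an
error). In the pipeline, Q-het is always computed; it is *labelled*
primary when the conditional F falls below 10 or Q_A exceeds the SNP
count.

**Diagnostics.** Single-SNP forest/funnel tables (data are the
deliverable; `plot_forest()`/`plot_funnel()` are conveniences), leave-one-
out IVW, Cook's distances from the weighted IVW regression flagged at
`4/k` (no cut-off is canonical; `4/k` is the common default and is
configurable), and Benjamini-Hochberg confounder screening at FDR 0.05
applied over the pooled SNP-by-confounder family (more conservative per
SNP than per-confounder adjustment, which remains available).

## The synthetic cohort generator

Because the motivating individual-level resource is access-restricted, the
package ships a generator whose defaults emulate a sex-stratified
adiposity / CRP / grip-strength analysis, so that every estimator is
testable by parameter recovery:

* 76 exposure SNPs explaining 2.1% of exposure variance and 88 mediator
  SNPs explaining 1.6% of mediator variance (minor-allele frequencies
  uniform on (0.05, 0.45), Hardy-Weinberg, LD-free — LD enters only
  through `simulate_ld()` fixtures, because the estimators assume
  independent instruments);
* exposure on the SD scale, mediator on the natural-log scale, outcome in
  kg with SD 8.8;
* GWAS sample sizes 322,000 (exposure), 204,000 (mediator) and 170,000
  (outcome stratum), giving per-SNP standard errors
  `sd_trait / sqrt(2 maf (1-maf) n)`;
* causal structure `theta_xm = 0.4` ln-units/SD, `theta_my = -0.5`
  kg/ln-unit, `theta_dir = 0.5` kg/SD, hence total 0.30 and indirect
  -0.20 kg/SD. The truth record stores
  `theta_total = theta_dir + theta_xm * theta_my` and the identity is
  asserted exactly.

Horizontal pleiotropy is off by default and can be balanced or directional
(`alpha_mean`, `alpha_sd`); confounding is induced by shared covariates
loading on several phenotypes (used to show the observational arm's
omitted-variable bias has the constructed sign). `cohort_to_sumstats()`
estimates per-SNP regressions within disjoint subsamples, reproducing the
two-sample design in which cross-trait sampling covariance is zero;
`simulate_sumstats()` is the fast path that composes the implied per-SNP
truths (`by = theta_dir * gamma + theta_my * (theta_xm * gamma + kappa) +
alpha`) and adds normal noise directly. Zero SE overrides give exact
noiseless limits; negative SEs are an error.

What the generator does *not* emulate: realistic LD, population
stratification, selection into the cohort, assortative mating, non-linear
or interaction effects, and genotyping error. Passing recovery tests
therefore demonstrate estimator correctness under the stated model, not
robustness to those features of real data.

## Numerical choices and degenerate inputs

* CIs are `beta ± 1.96 se` throughout; p-values are two-sided normal
  (consistent with the CI convention, rather than t-based).
* `k = 1` IVW degenerates to the single Wald ratio; `k < 2` heterogeneity
  is a defined null (`NA`), not an error; Egger/WME require `k >= 3`,
  MVMR-Egger `k >= 4`; sensitivity re-runs report "not estimable" instead
  of failing when exclusions push a panel below these minima.
* Zero exposure betas are dropped from ratio-based estimators with a
  warning (the ratio is undefined).
* Per-SNP regression SEs are floored at the smallest positive double so
  noiseless fits remain representable.
* All stochastic routines (WME and Q-het bootstraps, simulators) take
  explicit integer seeds, restore the caller's RNG state, and record the
  seed in their output; the pipeline fans a master seed out with
  `stage_seed(seed, stage) = (1009 seed + 97 stage) mod (2^31 - 1)` so any
  stage is independently reproducible.

## Test problem sizes

The recovery and calibration suites run at sizes chosen to make
Monte-Carlo error small while keeping the default test run quick: 300-500
replicates for unbiasedness checks, 5,000 replicates for the Cochran's Q
null calibration, 200 panels with 500 bootstrap replicates each for Q-het
coverage, and 100-150 replicates for the weak-instrument contrast (at
conditional F ≈ 6, emulating a weak sex-stratified central-adiposity
instrument). The MVMR recovery unit test raises the instrument-arm GWAS
sizes to 5 million so that it isolates estimator correctness in the
consistency limit; see the next section for why.

## Known limitations

* **Finite-sample MVMR attenuation.** At realistic GWAS precision the
  MVMR-IVW direct effect is attenuated by a few percent: the mediator
  block's exposure betas are structural zeros observed with noise, which
  acts as classical measurement error in the weighted regression. The
  total effect is unbiased, so the same attenuation appears in the
  difference-method indirect effect — and because total and direct share
  each panel, the indirect estimate's Monte-Carlo SE is small enough to
  resolve it. Q-het, whose weights carry the exposure-side variances, is
  materially less biased in this regime and its percentile intervals hold
  ~95% coverage; this is precisely why the robust layer exists. Users
  should read small indirect effects (relative to the exposure-arm SEs)
  with this in mind.
* The weighted median's resistance to invalid instruments is asymptotic:
  with a fixed per-ratio SE and 40% of weight carrying a directional
  offset, its residual bias is proportional to that SE (it estimates a
  slightly off-centre quantile of the valid cluster), while IVW absorbs
  the full weight-fraction of the offset. The tests encode exactly this
  contrast.
* The observational indirect CI uses estimated coefficient variances but
  assumes the two fits' sampling errors are uncorrelated; it is validated
  on synthetic cohorts only.
* Proxy substitution does not correct for r² < 1 between proxy and target.
* Only two simultaneous exposures (exposure + mediator) are supported, and
  LD is consumed, never computed.

## A worked synthetic run

```{r, eval = FALSE}
cfg <- sim_config()                       # study-scale defaults
sim <- simulate_sumstats(cfg, seed = 42)

total <- ivw(panel_subset_role(sim$panel, "exposure"))
mv <- mvmr_ivw(sim$panel)
direct <- dplyr::select(mv[mv$term == "exposure", ],
                        -term, -cond_F, -Q_A)
direct$exposure <- total$exposure
difference_method(total, direct)

qhet_estimate(sim$panel, n_boot = 2000, seed = 43)   # robust layer
```
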