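---
title: "Variance control for polygenicity-driven inflation in TWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance control for polygenicity-driven inflation in TWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasvc)
```

## The problem

A TWAS (or any xWAS) regresses a complex target trait $Y$ on a genetically
predicted mediator $\tilde T = \sum_k \tilde\gamma_k X_k$, where $X_k$ are
genotype dosages and $\tilde\gamma_k$ are prediction weights trained in an
external cohort. The test statistic is the Z-score of the regression slope.
Under the textbook null — $Y$ independent of the mediator and of the
genotypes — the Z-score is standard normal and p-values are uniform.

Most complex traits, however, are highly polygenic: essentially every
common variant carries a small effect. Writing the null target trait as

$$Y = \sum_k X_k \delta_k + \epsilon,$$

with i.i.d. small effects $\delta_k$, every variant used to predict the
mediator also contributes to $Y$, even when the mediator itself is
biologically unrelated to the trait. The resulting Z-score is inflated:

$$\mathrm{var}(Z) \approx 1 + N\,h^2\,\Phi,$$

where $N$ is the GWAS sample size, $h^2$ the polygenic heritability of the
target trait, and $\Phi$ a per-mediator *inflation slope*

$$\Phi = \frac{1}{M}\,
  \frac{\tilde\gamma' \Sigma^2 \tilde\gamma}
       {\tilde\gamma' \Sigma \tilde\gamma},$$

with $\Sigma$ the variant correlation (LD) matrix and $M$ the effective
number of causal variants for the target trait. Because inflation scales
with $N h^2$, modern GWAS sample sizes make it material even for tiny
$\Phi$ (order $10^{-5}$): at $N = 10^5$, $h^2 = 0.5$, $\Phi = 2\times
10^{-5}$ the Z-variance is 2, and a Z of 4 shrinks to 2.83 after
correction — often the difference between passing and failing a
transcriptome-wide Bonferroni threshold.

The correction is *variance control*: divide each Z by the square root of
its modeled variance,

$$Z_{\text{corrected}} = \frac{Z}{\sqrt{1 + N h^2 \Phi}},$$

and recompute the two-sided normal p-value. Unlike genomic control, the
factor is mediator-specific; unlike empirical-null Bayesian approaches, it
needs only three inputs: $N$, $h^2$ (estimable from summary statistics by
LD score regression) and the per-mediator $\Phi$ shipped alongside the
prediction weights.

Under the alternative ($\beta \neq 0$, with prediction precision
$\tau^2 = \mathrm{var}(T)/\mathrm{var}(\tilde T)$),

$$E[Z^2] \approx 1
  + \frac{N h_\delta^2 \sigma_Y^2}
         {\sigma_Y^2 - \tau^2\beta^2\sigma_T^2}\,\Phi
  + \frac{N \tau^2 \beta^2 \sigma_T^2}
         {\sigma_Y^2 - \tau^2\beta^2\sigma_T^2}.$$

At $\beta = 0$ this collapses to $1 + N h_\delta^2 \Phi$: prediction error
costs power but never calibration, which is why the correction targets
polygenicity rather than prediction noise.

## What the package provides

* `simulate_genotypes()`, `simulate_mediator_weights()`,
  `simulate_null_trait()`, `simulate_polygenic_trait()`,
  `simulate_alternative_trait()` — fully seeded generators for the three
  generative regimes above.
* `theoretical_phi()` — the closed-form quadratic-form ratio.
* `estimate_phi_empirical()` — the production route: simulate many
  polygenic null traits over a grid of $(N, h^2)$ cells on a reference
  panel, average $Z^2$ per cell, and regress the cell means on $N h^2$.
* `correction_factor()`, `apply_correction()`, `bonferroni_summary()` —
  the end-user correction applied to any result table.
* `z_sample_variance()`, `null_variance_interval()`, `uniformity_test()`,
  `qq_points()`, `calibration_report()` — calibration diagnostics.
* TSV/JSON readers and writers for weights, dosages, results and
  inflation slopes, a single-file JSON model store with a `build_id`
  guard, and a CLI (`inst/cli/twasvc.R`) with subcommands
  `simulate-genotypes`, `simulate-traits`, `run-twas`, `estimate-phi`,
  `correct`, `report`.

## A worked example

```{r example, eval = FALSE}
G <- simulate_genotypes(2000, identity_ld(999), seed = 1)
W <- lapply(1:500, function(k)
  simulate_mediator_weights(999, seed = 1000 + k,
                            mediator_id = paste0("gene_", k)))
y <- simulate_polygenic_trait(G, h2 = 0.5, seed = 2)

res <- run_twas(G, W, y)
z_sample_variance(res$z)            # about 2, not 1
uniformity_test(res$p)$ks_p         # rejects uniformity

out <- apply_correction(res, N = 2000, h2 = 0.5,
                        phis = data.frame(mediator_id = res$mediator_id,
                                          phi = 1 / 999))
z_sample_variance(out$z_corrected)  # about 1
uniformity_test(out$p_corrected)$ks_p  # calibrated
```

## Design of the synthetic-data generators

**Genotypes.** Independent variants are Binomial$(2, f)$ dosages with MAF
drawn uniformly from `maf_range` (default $(0.05, 0.5)$ — a realistic
common-variant spectrum). Correlated blocks use a Gaussian-copula
construction: each of the two allele copies is a thresholded latent
Gaussian with exchangeable within-block correlation. Plain thresholding
attenuates correlation (a latent 0.9 yields dosage correlation about 0.71
at MAF 0.5), so the latent correlation is calibrated by numerically
inverting the tetrachoric relation at the block's mean MAF; the realized
dosage correlation then matches the requested one to within sampling
noise. Explicit per-block matrices are used as latent correlations without
calibration and are validated for symmetry, unit diagonal and positive
semi-definiteness (the offending block is named on failure). The generator
deliberately omits population structure, relatedness and imputation noise;
passing tests therefore demonstrate calibration of the statistical
machinery under the stated model, not robustness to those real-data
features.

**Traits.** The polygenic generator rescales the genetic component so its
in-sample variance equals $h^2$ *exactly* (noise variance $1-h^2$ in
expectation). This removes one Monte Carlo noise source from
inflation-slope estimation; expectation-only scaling is available via
`exact_h2 = FALSE`. Effects and traits can be drawn from a unit-variance
Student-t (default `df = 5`: finite variance, visibly heavy tails) to
check robustness to non-normality; draws are rescaled so the variance
budget is preserved. Effects are redrawn for every replicate (fixing
$\delta$ and redrawing only $\epsilon$ would estimate a conditional rather
than marginal inflation).

**Alternative model.** `perturb_weights()` constructs noisy prediction
weights at exact in-sample precision $\tau^2$ by adding a weight-noise
direction orthogonalized against the true mediator, so $\tau^2 = 1$
returns the true weights unchanged. `simulate_alternative_trait()` uses
the same draw order as the polygenic generator, so $\beta = 0$ with
$\sigma_Y^2 = 1$ reproduces the polygenic null bit-for-bit under the same
seed — the null reduction is exact, not merely distributional.

## Numerical choices in the inflation-slope estimator

* **Grid regression.** Cell means of $Z^2$ are regressed on $N h^2$ with
  a *free* intercept; an intercept near 1 is a diagnostic that the null
  machinery is calibrated (forcing it to 1 is available via
  `fix_intercept` and changes the raw slope slightly). Cells are weighted
  equally by default, matching the way the cell averages are usually
  displayed; inverse-variance weighting is available via `weighted`.
* **Standard errors.** Cell means are strongly heteroskedastic (the MC
  variance of a mean of squared Z-scores grows with the inflation), so
  the residual-based `lm` standard error over a dozen cells is both noisy
  and anti-conservative. The reported SE instead propagates each cell's
  known Monte Carlo SE through the linear-estimator weights, then
  rescales by the residual over-dispersion when that exceeds its MC
  prediction (floored at 1, quasi-likelihood style). The floor absorbs
  the systematic per-cell offsets contributed by finite-reference-panel
  LD and per-cell subsampling, which trait redraws cannot average out.
* **Clamping.** A raw slope can go negative by Monte Carlo noise when the
  true $\Phi$ is near zero; estimates are clamped at 0 (the lowest
  admissible value) with `clamped = TRUE` and the SE still reported.
* **Degenerate inputs.** Grids with fewer than two distinct $N h^2$
  values are rejected as unidentifiable; weights annihilated by a
  rank-deficient LD matrix are an error rather than $\Phi = 0$; constant
  predicted mediators and perfect fits abort the association test.

## Fixture sizes and what the checks show

The package's own acceptance experiments use: a single-mediator toy
design (1000 individuals, 999 independent SNPs, dense normal weights,
1000 trait replicates), where the average $Z^2$ sits inside the central
99% band of a mean of 1000 $\chi^2_1$ draws for non-polygenic traits and
at $1 + N h^2/M$ for polygenic ones; a grid estimation design (reference
panel of 10,000 individuals at 500 independent SNPs, $N \in \{1000, 2000,
5000\}$, $h^2 \in \{0, 0.2, 0.5, 0.8\}$, 300 replicates per cell), where
the estimator recovers $\Phi = 1/500$ within 2 SE with intercept within
2 SE of 1 and $R^2 > 0.95$; and a 500-mediator panel (2000 individuals,
999 SNPs, $h^2 = 0.5$) where uncorrected p-values fail the KS uniformity
test and variance-controlled ones pass. The 10,000-row panel was chosen
because it halves the shared panel-LD component of the slope's sampling
error relative to a minimal panel and lets every grid cell draw a fresh
subsample; 300 replicates per cell keeps a full estimate in the
tens-of-seconds range on one CPU, with 1000 per cell the natural
production setting.

## Known limitations

* $M$, the LD matrix and $h^2$ are inputs, not estimands: the package
  never estimates them from real data.
* The correction accepts a point estimate of $h^2$; uncertainty in $h^2$
  is not propagated into corrected p-values.
* Binary traits are accepted with a warning; the linear-regression
  approximation is reasonable only for balanced case-control designs, and
  no effective-sample-size adjustment is applied.
* Horizontal pleiotropy with large, localized effects (a different
  causal gene in cis, LD contamination) is a different failure mode and
  is not addressed by variance control.
* The KS threshold used to declare p-values "calibrated" is an
  operational proxy for the visual QQ-alignment judgement; it is a test
  of global uniformity, not of tail behavior specifically.
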