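---
title: "Methods: two-sample MR of pulmonary function at synthetic scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of pulmonary function at synthetic scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmomr)
```

`pulmomr` implements the statistical pipeline of a two-sample Mendelian
randomization (MR) study of continuous pulmonary phenotypes (FEV1, FVC,
FEV1/FVC) on a binary disease outcome, together with the synthetic data
needed to exercise it with known ground truth. This vignette is the
package's own account of the models, the defaults, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The causal model and its assumptions

For variant $j$ the two GWAS supply $\hat\beta_{Xj} \sim N(\beta_{Xj},
\sigma_{Xj}^2)$ on the exposure and $\hat\beta_{Yj} \sim N(\theta
\beta_{Xj} + \alpha_j, \sigma_{Yj}^2)$ on the outcome log-odds, estimated
in disjoint samples. $\theta$ is the causal log-odds effect per exposure
unit and $\alpha_j$ a direct (horizontally pleiotropic) effect. The
estimators differ in what they assume about $\alpha_j$:

* **IVW / maximum likelihood** assume $\alpha_j = 0$ for all instruments.
  IVW combines Wald ratios with first-order weights
  $w_j = \beta_{Xj}^2/\sigma_{Yj}^2$; under the multiplicative
  random-effects model its SE is inflated by $\max(1, \sqrt{Q_1/(J-1)})$,
  never deflated. The ML estimator maximizes the joint normal likelihood
  with the per-variant true effects profiled out analytically; it accounts
  for $\sigma_{Xj}$, which first-order IVW ignores.
* **Weighted median** is consistent when at least half the total weight
  comes from valid instruments; its SE is a parametric bootstrap SD
  (default 1000 draws, seeded, restoring the caller's RNG state).
* **MR-Egger** frees an intercept: under InSIDE (instrument strength
  independent of direct effects) the slope remains consistent and the
  intercept estimates the mean direct effect; a nonzero intercept is the
  directional-pleiotropy test. The slope p-value uses $t_{J-2}$, the
  intercept a normal test.
* **MR-RAPS** models $\alpha_j$ as additive zero-mean noise (systematic
  pleiotropy, overdispersion parameter $\tau^2$) with a Huber
  $\psi$-function ($k = 1.345$) guarding against idiosyncratic outliers.
  We solve the profile-score equations by alternating a robust-loss
  minimization in $\theta$ with a moment equation in $\tau^2$ (the mean of
  $\psi(r)r$ matched to its standard-normal expectation $2\Phi(k)-1$),
  and report a sandwich SE. A dispersion equation that would drive
  $\tau^2$ negative is clamped to zero with a warning.

First-order weights are used for IVW and the weighted median; the
uncertainty of the exposure effects enters through the diagnostics
(modified-weight Q, I²GX, ML, RAPS) instead. This mirrors common practice
and keeps the primary estimator simple; the modified-weight machinery is
available wherever heterogeneity is quantified.

## Heterogeneity, outliers, and directionality

Cochran's Q with **modified second-order weights**,
$w_j(\theta)^{-1} = \sigma_{Yj}^2/\beta_{Xj}^2 +
\theta^2\sigma_{Xj}^2/\beta_{Xj}^2$, is evaluated at the $\theta$ that
*minimizes* $Q(\theta)$. Because the weights depend on $\theta$, the
fixed-point iteration "weighted mean, re-weight" does not reach the
minimum; we therefore minimize $Q(\theta)$ directly by Brent search,
re-bracketing from the first-order IVW start until the optimum is interior
and stationary to $10^{-8}$ (the unit tests verify agreement with a dense
grid to $10^{-5}$). When all $\sigma_X = 0$ the statistic reduces exactly
to first-order Q.

**Outlier filtering** iteratively removes the variant with the largest
contribution $Q_j$ while it exceeds the $\chi^2_1$ upper-$\alpha$ quantile
at the Bonferroni level $\alpha = 0.05/J$, recomputing Q each round and
stopping before J drops below 3. No published rule fixes this threshold or
the iteration; we chose the conservative systematic default (per-variant
Bonferroni, iterate to convergence) and expose `q_alpha`. On clean
simulated data this removes well under one variant per 30 instruments
(false-removal control in the test suite).

The **Steiger** test compares instrument variance explained on the two
sides, $r^2 = z^2/(z^2 + N - 2)$ per variant; for the binary outcome this
is an observed-scale approximation from the log-odds z-statistic, and the
report says so — a liability-scale conversion is deliberately out of
scope. The aggregate z-test Fisher-transforms the aggregate correlations
with the harmonic-mean sample size; $p > 0.05$ flags the direction
indeterminate.

**Power** uses the standard noncentrality approximation
$\Phi(\sqrt{N R^2 K(1-K)}\,|\log OR| - z_{1-\alpha/2})$, with the minimum
detectable OR solved by bisection. It is exercised at the motivating
study's printed inputs (85,716 samples with 34.1% cases and $R^2$ of
3.13% / 5.83%; 9,859 never-smoker samples with 23.9% cases and 4.21% /
2.06%).

## Instrument development

Spirometry QC follows the reproducibility convention: individuals with a
single blow are excluded outright; the best measure is the maximum blow;
other blows more than 0.15 L below the best are non-reproducible; a
participant passes if at least one non-best blow survives. FEV1 and FVC
are z-standardized; FEV1/FVC stays in natural 0–1 units, with obstruction
(COPD) flagged below 0.70.

Variant QC hard-calls dosages within 0.1 of an integer, then filters on
call rate (< 95%), MAF (< 0.005), and an exact Hardy–Weinberg test
(p < 10⁻⁵), computed on disease-free individuals when an outcome label
exists. The exact test enumerates the full conditional distribution of
the heterozygote count via the stable adjacent-class recurrence; tests
verify it against an independent log-factorial enumeration oracle.

Two-stage selection takes discovery hits at $P < 5\times10^{-8}$,
LD-clumps them greedily ($r^2 < 0.05$ within a ±10,000 kb window; ties in
p broken by position then id, making the output order-invariant), and
keeps index variants replicating at $P < 0.05$ with a consistent effect
direction. The replication threshold is nominal by default (a
Bonferroni-within-trait option is a matter of passing a smaller
`p_replication`). **Instrument weights default to the discovery-stage
effects**, with replication used only for filtering: the two-stage design
already protects against winner's curse at the selection step, and
discovery effects are the more precise of the two; `weights =
"replication"` switches to the unbiased-but-noisier alternative. The
70/30 split is by seeded random assignment without stratification.
Instrument strength is summarized from the independent replication sample
as $r_j^2 = z_j^2/(z_j^2+n-2)$, $R^2 = \sum_j r_j^2$, and
$F = R^2(n-1-J)/((1-R^2)J)$.

## Harmonization conventions

Outcome effects are aligned to the exposure's effect allele, resolving
label swaps by sign flips and strand flips by complementing; allele sets
that cannot be reconciled raise an error rather than passing silently.
Palindromic (A/T, C/G) variants are retained only when the minor allele
frequency is at most 0.42 in *both* studies (the strictest reading, since
the convention does not name a study) and the minor-allele side agrees
after orientation; discordant inferable palindromes are excluded rather
than re-flipped (conservative). Every exclusion carries a
machine-readable reason, and `exclusion_counts()` reports them. Proxies
(r² > 0.90 within the window, argmax with a position tie-break) inherit
the index variant's exposure effect and contribute their own outcome
effect — standard proxy semantics.

Three reporting scales are supported: per-SD (identity for z-scored
traits), per-10%-of-ratio (exposure effects multiplied by 10 so that
$\theta$ is one tenth of the per-unit effect), and the impairment
convention, which orients every variant to its exposure-*decreasing*
allele so that odds ratios read as risk per unit of impairment. The
impairment orientation is idempotent: a set already in that convention is
returned unchanged.

## The synthetic generators: what they emulate, and what not

The generators reproduce the statistical structure the pipeline needs,
not human genetics:

* **Genotypes** come from a latent Gaussian copula: two independent
  haplotypes per individual, thresholded at the allele-frequency quantile,
  with an autoregressive latent correlation inside fixed-size blocks. The
  latent correlation of each adjacent pair is calibrated (tetrachoric
  inversion by 1-D integration and root-finding) so that the *dosage*
  correlation matches the configured `rho`; because the attainable
  correlation between binary margins is Fréchet-bounded, the latent value
  is capped at 0.9999 when frequencies differ strongly. Hardy–Weinberg
  holds by construction. There is no mutation/recombination realism, no
  MAF–LD coupling, no population structure, and positions are uniform.
* **Cohorts**: the exposure is a standardized polygenic score plus a
  shared confounder plus noise, with effect sizes rescaled so the genetic
  variance fraction equals `h2x` exactly in expectation and the exposure
  has unit variance (so $\theta$ is per SD). The binary outcome is
  **logistic**, not liability-threshold: the log-odds are
  $\alpha_0 + \theta x + \gamma c$ (+ direct effects for invalid
  instruments), with $\alpha_0$ solved by bisection to ±0.001 so the
  expected case fraction hits `K` (default 0.34, a case-enriched
  case-control mix). The logistic choice makes `exp(theta)` the exact
  ground-truth odds ratio; the price is mild non-collapsibility
  attenuation of marginal per-variant log-odds effects, visible as a few
  percent shrinkage at realistic effect sizes, which is a property of real
  marginal GWAS too.
* **Summary-level MR data** skip individuals entirely and draw effect
  pairs from the model above; this is the workhorse for estimator
  calibration (type-I error, coverage, robustness) because thousands of
  replicates run in seconds. Defaults: true exposure effects
  $N(0.1, 0.03^2)$, $\sigma_X = 0.02$, $\sigma_Y = 0.05$. For
  parameter-recovery reporting we use the strong-instrument regime
  ($\beta_X \sim N(0.1, 0.06^2)$, $\sigma_X = 0.01$), which gives
  F-statistics comfortably above 40 and I²GX above 0.97 — the regime in
  which all five estimators are consistent and MR-Egger is not diluted.
* **Polygenic z-score pairs** implement the LD-score regression generative
  model directly: per-variant standardized effects are bivariate normal
  with correlation `rg`, z-scores are inflated by the *analytic* LD score
  of an AR block (default block 50, rho 0.9, giving scores ranging from
  about 5 to 10) and carry sampling noise, correlated across traits in
  proportion to sample overlap. Adjacent z-scores are independent given
  the LD score — the model's mean structure is faithful, its correlation
  structure is not, which jackknife SEs over contiguous blocks absorb at
  this scale.

Ground-truth labels travel alongside every dataset and are never read by
inference code. Passing tests therefore demonstrate internal consistency
of the machinery under its own assumptions — they cannot certify behavior
under real LD, assortative mating, selection bias, or population
stratification.

## LD-score regression at desk scale

LD scores use the small-sample-adjusted $r^2_{adj} = r^2 - (1-r^2)/(n-2)$,
floored at zero, summed within a window (self-correlation contributes the
leading 1). Heritability regresses $\chi^2$ on the LD score with the
two-step heteroskedasticity weights $1/(\ell_j (1 + N h_0^2 \ell_j/M)^2)$
and a free intercept (a constrained-intercept mode exists); the slope
times $M/N$ is $h^2$. Cross-trait regression of $z_1 z_2$ identifies the
genetic covariance, with the free intercept absorbing sample overlap;
$r_g$ is clamped to $[-1.25, 1.25]$ with a warning outside $[-1, 1]$, and
an impairment flag negates it (exactly a sign flip of one trait's
z-scores). Partitioned heritability fits
$E[\chi^2] = N\sum_c \tau_c \ell(j,c) + 1$ and reports, per binary
annotation, the proportion of heritability, enrichment, and a jackknife
test of enrichment ≠ 1, flagged at the Bonferroni level 8.5×10⁻⁴ by
default. All standard errors are delete-one-block jackknives over
contiguous variant blocks; **20 blocks** is the desk-scale default
(against 200 in genome-scale practice) and is configurable. MHC-style
region masking is a coordinate exclusion the caller applies before
invoking the regressions; synthetic panels have no MHC, so no default
mask is applied.

## Numerical choices

* ML: Brent optimization of the profile log-likelihood over the Wald-ratio
  range ±5 spreads, with bracket doubling on boundary hits; SE from the
  numerical curvature at the optimum.
* RAPS: alternation converges in a handful of iterations; tolerances are
  $10^{-8}$ in $\theta$ and $10^{-10}$ in $\tau^2$, capped at 100 rounds.
* Weighted median: cumulative-midpoint interpolation at probability 0.5;
  degenerate weight mass reduces to the dominant instrument's ratio.
* Logistic intercept for the case fraction: bisection on $[-30, 30]$ to
  ±0.001.
* Tie-breaks: clumping and proxy search break p/r² ties by position, then
  id, so every output is order-invariant and reproducible.
* Degenerate inputs error loudly: constant phenotypes in z-scoring, zero
  `beta_x` in Wald ratios, equal exposure effects in Egger, rank-deficient
  covariates or exposure matrices, nonpositive heritability in $r_g$.

## Problem sizes used by the tests and the acceptance script

Simulated scales were chosen so the whole suite runs in about a minute:
type-I error uses 500 summary-level replicates at J = 150; coverage 300
replicates at J = 100; robustness and directionality 200 replicates;
LDSC recovery 100 replicates at m = 5,000 and N = 20,000; the
individual-level pipeline demo uses 12,000 + 12,000 individuals, 150
variants, and 35 causal variants. These sizes make Monte-Carlo bands
(e.g. type-I error in [2%, 10%] at nominal 5%) informative without being
brittle.

## Known limitations

* The LD generator calibrates adjacent-pair dosage correlation; longer-
  range decay within a block is faster than $\rho^{|j-k|}$ on the dosage
  scale.
* Binary-outcome Steiger $r^2$ and heritability are on the observed
  scale; liability-scale conversions are out of scope ( $r_g$ is
  scale-invariant, so cross-trait conclusions are unaffected).
* MR-PRESSO-style global/distortion tests, mode-based estimators, and
  contamination-mixture models are not implemented.
* `run_gwas` is OLS for continuous phenotypes; binary outcomes go through
  `run_gwas_binary` (per-variant logistic), which is the pipeline default
  for the outcome scan so that estimates live on the log-odds scale of the
  generator's ground truth.
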