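---
title: "Methods: two-sample Mendelian randomization with mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X (here, a continuous trait analysed per standard deviation, such
as long-term PM2.5 exposure) on a binary outcome Y (such as gestational
diabetes) from two independent GWAS summary datasets. For each instrument
SNP j we observe the exposure association $\hat\gamma_j$ with standard
error $\sigma_{X j}$ and the outcome association $\hat\Gamma_j$ (log-odds)
with standard error $\sigma_{Y j}$. Under the instrumental-variable
assumptions (relevance, independence from confounders, exclusion
restriction), each SNP provides a Wald ratio estimate
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ of the causal log-odds ratio
per SD of exposure, with first-order standard error
$s_j = \sigma_{Y j} / |\hat\gamma_j|$.

`mrpipe` implements the five standard pooled estimators:

* **IVW** (`ivw()`): weighted least squares of $\hat\Gamma_j$ on
  $\hat\gamma_j$ through the origin with weights $\sigma_{Y j}^{-2}$,
  identical to the inverse-variance weighted mean of the Wald ratios. The
  default flavour is multiplicative random effects: the SE is scaled by
  $\max(1, \hat\sigma)$ where $\hat\sigma^2$ is the weighted residual mean
  square on $J-1$ degrees of freedom, so heterogeneity widens the interval
  but can never shrink it below the fixed-effect SE. A `flavor = "fixed"`
  switch disables the scaling. Inference is normal.
* **MR-Egger** (`egger()`): the same regression with a free intercept,
  after orienting every SNP so $\hat\gamma_j \ge 0$. The slope is
  consistent under InSIDE (instrument strength independent of direct
  effects); the intercept estimates the mean directional pleiotropic
  effect and doubles as the standard pleiotropy test. Inference uses the t
  distribution on $J-2$ df, with the same $\max(1,\hat\sigma)$ scaling.
* **Weighted median** (`weighted_median()`): the weighted 50th percentile
  of the Wald ratios (weights $s_j^{-2}$), linearly interpolated with the
  mid-cumulative convention $p_j = (\sum_{k \le j} w_k - w_j/2)/\sum_k w_k$.
  Consistent while valid instruments carry more than half the weight.
* **Weighted and simple mode** (`mode_estimate()`): the argmax of a
  Gaussian-kernel density over the Wald ratios, weighted by $s_j^{-2}$ or
  uniformly. Consistent when the largest cluster of instruments is valid.

Estimates are reported on the log-odds scale and as odds ratios with
95% confidence intervals, $\mathrm{OR} = e^{\hat\beta}$,
$\mathrm{CI} = e^{\hat\beta \mp z_{0.975}\,\mathrm{SE}}$.

## Instrument selection and harmonization

Selection follows the conventional funnel, each stage a separate function
so counts can be reported at every step:

1. **p-value screen** (`select_by_pvalue()`): default threshold
   $10^{-5}$, the usual relaxation when genome-wide significance
   ($5\times10^{-8}$) leaves too few instruments for a diffuse exposure.
2. **LD clumping** (`clump()`): greedy, in ascending p-value; a SNP is
   dropped if it lies within 10,000 kb of an already-kept SNP on the same
   chromosome with pairwise $r^2 > 0.001$. Pairs absent from the LD table
   count as $r^2 = 0$; pairs beyond the window are independent regardless
   of the table. Ties in p are broken by position, then identifier, so the
   output is a deterministic function of the data.
3. **Confounder exclusion** (`exclude_snps()`): an offline rsid list
   replaces live variant-annotation lookups (those services are
   version-dependent and unreproducible); variants known to act through
   other risk-factor pathways are removed.
4. **Proxy search** (`find_proxy()`): an instrument missing from the
   outcome GWAS may be replaced by the outcome-present SNP with maximal
   $r^2 \ge 0.8$; ties break by distance, then identifier. Off unless an
   LD table is supplied.

Harmonization (`harmonize_datasets()`) expresses both studies' effects on
the exposure's effect allele; the exposure orientation is never changed, so
the causal estimate stays anchored to the exposure GWAS's allele coding.
Outcome effects are negated (and frequencies mirrored) when the outcome
coded the opposite allele; non-palindromic mismatches are retried after
strand complementing. Palindromic SNPs (A/T, C/G) cannot be resolved from
allele labels: they are aligned by effect-allele frequency, and dropped as
ambiguous when the minor-allele frequency is 0.3 or higher in either study
(frequencies that close to 0.5 cannot distinguish strands reliably) or when
a frequency is missing. Every input SNP is logged exactly once as kept or
dropped.

Instrument strength is summarised per SNP by
$r^2_j = \hat\gamma_j^2 / (\hat\gamma_j^2 + n\,\sigma_{Xj}^2)$ and
$F_j = r^2_j (n-2)/(1-r^2_j)$, with the $(\hat\gamma_j/\sigma_{Xj})^2$
approximation (flagged) when the sample size is unknown; $F > 10$ is the
conventional weak-instrument screen, and the summed $r^2$ feeds the power
calculation.

## Sensitivity diagnostics

`cochran_q()` computes $Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2$
over Wald ratios with $w_j = s_j^{-2}$, referred to $\chi^2_{J-1}$, plus
$I^2 = \max(0, (Q - df)/Q)$. `egger_intercept_test()` re-exposes the Egger
intercept block. `leave_one_out()` re-runs IVW omitting each SNP in turn.
`single_snp_forest()` and `funnel_data()` produce the tables behind the
standard forest and funnel displays (the package deliberately emits tables,
not figures; any plotting layer can consume them).

## Multivariable MR

`mvmr_ivw()` regresses $\hat\Gamma_j$ on the $J \times K$ matrix of
exposure effects without intercept, weights $\sigma_{Yj}^{-2}$, giving each
exposure's direct effect conditional on the others; SEs carry the same
$\max(1, \hat\sigma)$ scaling on $J-K$ df. With $K=1$ the fit reproduces
univariable IVW exactly (tested to machine precision). Two choices here
were genuinely open, because the source design describes no assembly
procedure:

* instruments for the joint model are the union of each exposure's
  p-screened instruments, clumped jointly by the minimum p-value across
  exposures — a symmetric rule that keeps the strongest signal per locus
  regardless of which exposure contributed it;
* the first exposure's allele orientation is the reference to which all
  other datasets are harmonized.

Weights use outcome SEs only (standard MVMR-IVW); conditional-F weak
instrument corrections are out of scope.

## Statistical power

`mr_power_binary()` implements the binary-outcome non-centrality
approximation popularised by the mRnd calculator:
$\mathrm{power} = \Phi\!\big(|\ln \mathrm{OR}|
\sqrt{n\, r^2_{XZ}\, \phi(1-\phi)} - z_{1-\alpha/2}\big)$
with $n$ the total outcome sample, $\phi$ the case fraction and $r^2_{XZ}$
the instrument variance explained. The combined sample (cases + controls)
is the default $n$; with 6,033 cases, 123,000 controls, $r^2 = 5.85\%$ and
OR 1.736 the power rounds to 100% under either reading of the sample size.
`minimum_detectable_or()` inverts the formula by bisection to relative
tolerance $10^{-6}$.

## The synthetic-data generator

`simulate_two_sample()` generates both GWAS directly at the summary level —
two-sample MR consumes nothing else, and this keeps a full pipeline
replicate in tens of milliseconds. Defaults emulate the study conditions
the package targets: 85 instruments, an exposure GWAS of 423,796, an
outcome GWAS of 6,033 cases and 123,000 controls, causal effect 0.551
log-odds per SD, and instruments jointly explaining 5.85% of exposure
variance. Per SNP: MAF uniform on (0.05, 0.5); true effects
$\gamma_j \propto$ standard normal draws rescaled so
$\sum_j 2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\gamma_j^2$ equals the target
$R^2$ exactly; observed effects add noise with the analytic SEs
$\sigma_{Xj} = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,n_X)^{-1/2}$ and
$\sigma_{Yj} = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,n_{eff})^{-1/2}$,
where $n_{eff} = 4/(1/\mathrm{cases} + 1/\mathrm{controls})$ is the
standard effective size of a case-control GWAS. Pleiotropic direct effects
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ hit a configurable fraction of
SNPs and are planted **relative to the exposure-increasing allele**, so a
nonzero $\mu_\alpha$ is directional in the orientation the estimators
analyse while InSIDE holds by construction. Allele structure is realistic
enough to exercise harmonization: a configurable fraction of palindromic
SNPs (default 5%, of which those with intermediate frequency are correctly
lost in harmonization), of outcome files with swapped allele coding
(default 10%), and optional LD blocks whose members share an allele pair so
proxy lookups can be allele-aligned.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: genome-wide LD beyond the declared blocks;
winner's curse from discovering instruments in the same exposure sample
(true effects are drawn independently of the screen); sample overlap
between the two GWAS (the samples are independent by construction, matching
the two-sample design); population stratification; and effect heterogeneity
across strata. Proxies inherit their block's allele pair but their effects
are drawn independently, so proxy tests are structural, not statistical.

One documented tension in the emulated conditions: 85 instruments summing
to $R^2 = 5.85\%$ at $n = 423{,}796$ imply a mean per-SNP F near 290,
whereas published per-SNP F statistics for this design are reported in the
tens; those two figures are mutually inconsistent, and the generator
follows the stated $R^2$. A small weak-instrument dilution bias of roughly
$-(J/n_X)/R^2 \cdot \beta \approx -0.002$ is therefore expected (and
observed) in IVW recovery simulations; it sits within the three-SE
Monte-Carlo equivalence band used by the acceptance checks.

## Numerical choices

* **Mode bandwidth**: $h = \phi \cdot 0.9 \min(\mathrm{sd}(b),
  \mathrm{mad}(b))\, J^{-1/5}$ with $\phi = 1$ by default (the
  Silverman-type rule standard for this estimator). If exactly one of the
  two scale measures is zero (a strict majority of identical ratios) the
  positive one is used; if all ratios are identical the common ratio is
  returned with SE 0.
* **Mode argmax**: the density is maximised over 10,000 evenly spaced
  points on $[\min(b) - 2h, \max(b) + 2h]$; ties resolve to the lowest
  grid value. For speed the exact kernel sum is evaluated only at
  fine-grid points surviving a binned FFT pre-screen (bin width $\le h/3$,
  keep-threshold 95% of the maximum, kept runs expanded by two bins — the
  binning error is an order of magnitude below the screening margin); a
  refinement test checks the result against an exhaustive scan.
* **Bootstrap SEs**: the weighted median and the modes resample each ratio
  from $N(\hat\beta_j, s_j)$ with weights held fixed, 1,000 draws by
  default, seeded (the seed is mandatory in the pipeline). The median
  summarises draws by the SD; the modes use the MAD, because mode
  estimates hop between density peaks in a minority of draws, which
  inflates an SD far beyond the scale of the central sampling
  distribution. Even so the simple mode remains conservative (type-I error
  well below nominal under the default conditions) — a known property of
  mode-based estimators, worth remembering when reading its wide
  intervals.
* **Weighted median interpolation**: cumulative weights within $10^{-12}$
  of 0.5 count as exact hits; otherwise floating-point rounding could leak
  a vanishing interpolation weight onto an arbitrarily distant neighbour.
* **Degenerate inputs**: a zero exposure effect is a hard error naming the
  SNP (its Wald ratio is undefined); rank-deficient multivariable exposure
  matrices are a hard error naming the collinear columns; fewer than 2/3
  SNPs for IVW/other estimators are hard errors.
* **I/O precision**: summary tables are written with `%.17g` so a
  write/read round trip is bit-exact.

## Validation design and problem sizes

The test suite validates the statistical claims by simulation at sizes
chosen to finish in minutes on one core: IVW recovery and CI coverage over
500 replicates of the default conditions; type-I error of IVW, weighted
median and weighted mode over 400 null replicates (bootstrap SEs at 100
draws there). The weighted median's prescribed bootstrap convolves each
ratio with its own SE before re-taking the median, which intrinsically
over-disperses the draws (up to a factor $\sqrt 2$ in the homogeneous
limit; ~20% measured); its type-I error therefore sits around 2%, below
the nominal band — a conservatism shared by the standard implementations
of this estimator, reported here rather than patched; uniformity of Cochran's Q
p-values over 500 null replicates (under a null effect the first-order
ratio SEs are exact, making Q pivotal); Egger intercept recovery over 200
replicates of the orientation-stable design described above; and exhaustive
small-instance oracles for clumping, proxy search, harmonization and the
median breakdown property. Monte-Carlo equivalence uses a three-SE band
throughout. With grossly unequal weights a single heavy SNP adjacent to
the median bracket can make the interpolated weighted median exceed the
valid ratios' range even when corrupted weight is below 50% — the 50%
breakdown guarantee is exact for the equal-weight construction and
asymptotic otherwise.

## Limitations

No MR-PRESSO/contamination-mixture/robust variants; no Steiger direction
filtering; no conditional-F MVMR diagnostics; LD must be supplied as a
table (the package never computes it from genotypes); live GWAS-repository
and variant-annotation services are deliberately out of scope, replaced by
file inputs, for reproducibility.
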