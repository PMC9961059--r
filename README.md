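# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, end
to end: instrument selection, allele harmonization, the five standard
causal estimators, sensitivity diagnostics, multivariable MR, and
statistical power — plus a synthetic summary-data generator with known
ground truth so the whole pipeline can be validated without external
downloads.

The package is written for epidemiologists asking causal questions about
environmental or lifestyle exposures — the motivating application is the
effect of long-term fine particulate matter (PM2.5) exposure, per standard
deviation, on the odds of gestational diabetes mellitus — but every stage
is generic over any continuous exposure and binary outcome with tabular
GWAS summary data (one row per SNP: identifier, position, alleles,
effect-allele frequency, beta, SE, p, n).

## The statistics

Each instrument SNP j gives a Wald ratio estimate of the causal log-odds
per SD of exposure, with first-order SE:

    beta_j = Gamma_j / gamma_j ,   s_j = se(Gamma_j) / |gamma_j|

where gamma/Gamma are the SNP's exposure/outcome associations. The pooled
estimators:

* **IVW** — inverse-variance weighted regression of Gamma on gamma through
  the origin (multiplicative random effects by default: SE scaled by
  max(1, sigma_hat) on J−1 df);
* **MR-Egger** — the same regression with a free intercept after orienting
  gamma ≥ 0; the intercept is the directional-pleiotropy test;
* **weighted median** — weighted 50th percentile of the ratios, robust to
  up to 50% invalid weight;
* **weighted / simple mode** — argmax of a kernel density over the ratios,
  robust when the largest cluster of instruments is valid.

Diagnostics: Cochran's Q (+ I²), the Egger intercept test, leave-one-out
IVW, and the tables behind forest and funnel plots. Multivariable MR
(`mvmr_ivw`) estimates direct effects of K exposures jointly.
`mr_power_binary` implements the mRnd-style binary-outcome power
approximation. See the methods vignette
(`vignettes/two-sample-mr-methods.Rmd`) for formulas, assumptions, and
design choices.

## Worked example

Simulate a two-sample study under the default conditions (85 instruments,
exposure GWAS n = 423,796, outcome 6,033 cases / 123,000 controls, true
effect 0.551 log-odds per SD, instruments explaining 5.85% of exposure
variance), then run the full pipeline:

```r
library(mrpipe)
sim <- simulate_two_sample(simulation_config(seed = 42))
cfg <- pipeline_config(exposure = sim$exposure, outcome = sim$outcome,
                       n_boot = 1000, seed = 7)
bundle <- run_mr_pipeline(cfg)
cat(mr_report(bundle))
```

which prints:

```
# Two-sample MR report

Instruments: 85 input, 66 past p-screen, 66 after clumping, 66 after exclusions, 66 harmonized (0 dropped).

| Method | N SNPs | Beta | SE | OR (95% CI) | p |
|---|---|---|---|---|---|
| IVW | 66 | 0.567 | 0.032 | 1.762 (1.656-1.876) | 1.45e-70 |
| MR-Egger | 66 | 0.654 | 0.058 | 1.924 (1.717-2.156) | 8.15e-17 |
| Weighted median | 66 | 0.555 | 0.046 | 1.742 (1.590-1.908) | 7.17e-33 |
| Weighted mode | 66 | 0.595 | 0.046 | 1.813 (1.655-1.985) | 9.21e-38 |
| Simple mode | 66 | 0.611 | 0.083 | 1.843 (1.565-2.170) | 2.27e-13 |

Cochran's Q = 88.566 (df 65), p = 0.028; I2 = 26.6%.
MR-Egger intercept = -0.0051 (SE 0.0028), p = 0.078.
Per-SNP F statistics span 23.99-4636.50; instruments explain 5.80% of exposure variance.
Power to detect OR = 1.762 at the observed sample size and R2: 100%.
```

Reading it: 85 simulated SNPs enter; 66 survive the p < 1e-5 screen (the
weakest draws fall below the threshold); none are lost to clumping (the
default simulation spaces SNPs beyond the LD window) or harmonization at
this seed. All five estimators land near the generating effect of 0.551 —
the IVW odds ratio 1.762 means each SD of exposure multiplies the odds of
the outcome by about 1.76 in this replicate. Q finds mild heterogeneity
(p = 0.028), the Egger intercept is consistent with no directional
pleiotropy (p = 0.078), every instrument clears F > 10, and the recovered
variance explained (5.80%) matches the generating 5.85% up to sampling
noise. `run_mr_pipeline` also writes every table (instruments, harmonized
pairs, estimates, heterogeneity, leave-one-out, forest, funnel, strength)
plus a JSON manifest when given `out_dir`; a rerun with the same seed is
byte-identical.

Real data enter through `read_summary_table(path, column_map = ...)`, an
LD table through `read_ld_table` (3-column TSV), and confounder-associated
instruments through `read_exclusion_list` (one rsid per line).

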