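---
title: "Methods: stratified SNP association, trans-ethnic meta-analysis, mediation, and gene-treatment survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified SNP association, trans-ethnic meta-analysis, mediation, and gene-treatment survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmeta)
library(dplyr)
```

# The analysis problem

transmeta implements the analysis chain used in candidate-SNP cardiovascular
epidemiology across ancestrally diverse cohorts, organised around the SCARB1
intronic variant rs10846744 (effect allele C vs reference G) and the
candidate mediator Lp-PLA~2~ (lipoprotein-associated phospholipase A~2~):

1. **Per-stratum association** — within each self-reported race/ethnic
   stratum, regress each candidate trait on the effect-allele dosage
   (additive model) with covariate adjustment.
2. **Evidence synthesis** — combine per-stratum estimates by inverse-variance
   fixed-effects meta-analysis with Cochran heterogeneity, by
   DerSimonian-Laird random effects for the trial analyses, and by a
   MANTRA-style trans-ethnic Bayes factor that tolerates ancestry-structured
   effect heterogeneity.
3. **Screening** — carry a trait forward when its meta p-value passes the
   Bonferroni threshold for the 27-trait panel (0.05/27 <= 0.0019) or its
   log10 Bayes factor exceeds 1.5.
4. **Mediation** — difference-in-coefficients mediation of the SNP-cIMT
   association through each carried-forward biomarker, with bias-corrected
   bootstrap intervals, meta-analysed across strata.
5. **Trial analyses** — baseline-biomarker association, proportional-hazards
   survival models for major coronary events, and the treatment-by-genotype
   interaction test in darapladib-trial-style data.

Individual-level cohort data are not distributable, so the package pairs
every stage with (a) the published per-stratum summary statistics
(`mesa_published_assoc()`, `trial_published_biomarker()`), from which the
meta-analytic stages are exactly reproducible, and (b) a seeded synthetic
cohort generator with known ground truth, from which the individual-level
stages are validated by recovery and calibration simulations.

# Synthetic multi-ethnic cohorts

`gen_multiethnic()` simulates per-subject tables from `population_spec()`
objects. Genotype dosages are Binomial(2, *q*) draws — Hardy-Weinberg
sampling, since only allele frequencies (0.18/0.62/0.35/0.57 in the four
strata) are published, not genotype counts. The mediator and outcome obey
the linear structural model

$$M = \alpha_M + aG + \gamma^\top X + \varepsilon,\qquad
  Y = \alpha_Y + c'G + bM + \delta^\top X + \eta,$$

so the indirect effect is $a\cdot b$ and the total dosage effect on $Y$ is
$c' + ab$ — the identities every downstream validation leans on. Defaults in
`mesa_cohort_specs()` are chosen to resemble the published cohort scale:
sample sizes 2470/2507/2071/758; mediator intercepts near the published
Lp-PLA~2~ activity medians (around 135-155 nmol/min/ml) with residual SD 36
(matching the published interquartile ranges under normality); a per-allele
mediator effect of 3.5 nmol/min/ml (the order of the published per-stratum
estimates); a cIMT-like outcome around 0.85 mm with residual SD 0.17; binary
events with marginal prevalences 12.7/11.0/12.1/8.4%. Noise is Gaussian by
default with a lognormal hook (`mediator_model(noise = "lognormal")`) for
skewed biomarkers; distributional forms are modelling choices, since only
medians and IQRs are published.

Binary events use a logistic model whose intercept is `qlogis(prevalence)`
and whose covariate coefficients default to zero, so the configured
prevalence is an exact marginal target rather than an approximation; the
coefficient hook is available when event-covariate structure is wanted.
Trial-style strata (`trial_cohort_specs()`) add exponential
proportional-hazards event times (baseline hazard 0.035/year), a 1:1
randomized arm, and uniform administrative censoring on (0, *h*] with *h*
the trial's median follow-up (3.7 y / 2.5 y) — a simple stand-in for
staggered enrolment.

Reproducibility: every stratum draws from a sub-seed derived from the master
seed and the stratum *label* (`stratum_seed()`), never its list position, so
re-ordering strata cannot change any subject's data. Generators save and
restore the caller's RNG state. An optional MCAR missingness injector
(`missing_rate`) exercises complete-case handling; the default is 0.

# Association models

`snp_assoc()` fits trait ~ dosage + covariates per stratum: OLS with
t-reference Wald tests for quantitative traits, IRLS logistic regression
with normal-reference Wald tests for binary ones (the published analyses
report p-values without stating the test construction; two-sided Wald is the
GWAS convention). Complete-case filtering is applied per model and the
per-model n is reported, mirroring the published tables whose n varies by
trait. Categorical covariates (study site, education) expand to indicators
against a first-level reference. A square-root transform is available for
right-skewed fatty-acid ratios. Ancestry PCs are ordinary numeric columns
supplied with the cohort; the package does not compute them. Degenerate
inputs fail loudly: rank-deficient designs name the collinear columns,
monomorphic genotypes, zero-variance responses, separation, and
non-convergence are errors, never silent results. No family-relatedness
correction is applied — a known limitation for family-augmented cohorts.

# Meta-analysis

`meta_fixed()` uses weights $w_i = 1/se_i^2$, combined SE
$(\sum w_i)^{-1/2}$, and two-sided normal p-values. Heterogeneity is
Cochran's $Q = \sum w_i(\beta_i - \hat\beta_{FE})^2$ on $k-1$ df with
$I^2 = \max(0, (Q - df)/Q)\cdot 100$, floored at zero exactly as printed
summaries floor it. `meta_random()` is DerSimonian-Laird:
$\tau^2 = \max(0,(Q-df)/C)$, $C = \sum w_i - \sum w_i^2/\sum w_i$; when
$Q \le df$ it truncates to the fixed-effects answer exactly. Estimates are
consumed at whatever precision the caller supplies; when fed published
values rounded to three decimals the combined estimates agree with the
published combined rows to about one unit in the last printed digit (the
original computations used unrounded inputs).

# Trans-ethnic Bayes factor

`transethnic_bf()` computes a Bayes factor for association in which the
populations are partitioned into effect-sharing clusters: within a cluster
the studies share one effect $\mu \sim N(0, \sigma^2)$; across clusters
effects are independent. Each cluster's marginal likelihood has the closed
form of a Gaussian integral (`cluster_log_marginal()`), a one-dimensional
conjugate computation that reduces to Wakefield's approximate Bayes factor
for a single study. The model marginal likelihood averages over all set
partitions of the populations (exact enumeration up to K = 10; Bell(4) = 15
partitions for a four-stratum cohort), and the Bayes factor compares it to
the null of no effect anywhere. All arithmetic is log-space with
log-sum-exp; with enumeration there is no Monte Carlo error and results are
bit-reproducible.

Two genuinely open design points are resolved as follows. The partition
prior is uniform over partitions by default: the relatedness-weighted prior
used by MANTRA-class software needs a genome-wide allele-frequency distance
matrix that a single-SNP analysis does not carry; a hook accepts a
user-supplied pairwise distance matrix with weights proportional to
`exp(-concentration x within-cluster distance)`. The effect-prior scale
$\sigma$ defaults to 0.2 on a standardized per-allele scale — about 0.2
trait SDs per allele, a "moderate effect" prior; `run_pipeline()` rescales
it per trait as 0.2 x the observed trait SD. Because published Bayes factors
depend on unstated prior settings, they are treated as qualitative
references (the decision threshold 1.5 is reproduced exactly; individual
BF values are not numeric targets), and the package's own BF is validated
against closed forms and adaptive quadrature instead.

# Mediation with the bias-corrected bootstrap

`mediation_diff()` fits Model 1 (outcome ~ dosage + covariates) and Model 2
(Model 1 + mediator) on the identical complete-case subset and reports the
change in the dosage coefficient; in the linear structural model this
difference converges to $-(a \cdot b)$, minus the indirect effect.
`mediation_boot()` wraps it in a nonparametric pairs bootstrap: whole
subject rows are resampled with replacement within stratum, preserving the
joint (G, M, X, Y) distribution. The interval is bias-corrected (BC), not
BCa — no acceleration constant — matching the named published procedure; an
acceleration extension would slot into `bc_interval()` if wanted. The
bias-correction constant uses the half-count tie convention
$z_0 = \Phi^{-1}\!\big((\#\{\theta^* < \hat\theta\} + \tfrac12\#\{\theta^* =
\hat\theta\})/B\big)$, so a degenerate bootstrap distribution yields
$z_0 = 0$ and a point interval rather than an infinity. The two-sided
p-value is the smallest $\alpha$ at which the BC interval excludes zero,
found by bisection to tolerance $1/B$ (both endpoints are monotone in
$\alpha$, so bisection is exact up to that resolution). Resamples with
singular designs are redrawn and counted, capped at 10% of B. B defaults to
1000 (the published analysis does not state B) and a seed is mandatory.

Across strata, the per-stratum differences are combined by fixed-effects
meta-analysis using each stratum's bootstrap SD as its SE — the only
self-consistent weighting available, since no analytic SE of a coefficient
difference between nested OLS fits is reported or assumed.

# Survival analyses

`fit_cox()` delegates the partial-likelihood maximization to the survival
package with Breslow tie handling by default (the trials' tie method is
unreported; Efron is a flag) and converts its soft failure modes into hard
errors: monotone likelihood, collinear or constant columns, no events,
non-convergence. `cox_interaction()` pools all subjects with dosage,
treatment, their product, optional covariates and stratum indicator columns
(the analog of the trials' "region" adjustment), testing the product term by
Wald. `baseline_biomarker_assoc()` reproduces the trials' baseline table
shape: per-stratum linear association plus DerSimonian-Laird pooling, the
random-effects choice the trial analyses state. Endpoint choice (MCE vs
MACE) is a column-selection concern: the event column is an argument.

# Screening and pipeline

`carry_forward()` implements the selection rule literally: meta p at or
below `alpha/m` OR log10 BF above 1.5. Applied to the shipped published
meta table it selects Lp-PLA~2~ activity and the DPA/EPA ratio; narrative
accounts of the same analyses name DHA/EPA (p = 0.008, BF = 1.09), which
the stated rule does not select — the package follows the rule and the
discrepancy is documented with the data rather than silently resolved.
`run_pipeline()` chains simulation/ingest, association, meta + BF,
selection, mediation, and (when trial columns exist) the survival stage,
writing TSV tables plus a `run.log` carrying the seed, package version and
a configuration hash; outputs are byte-identical for identical
configuration and seed, and the log carries no timestamps for that reason.

# Numerical choices and validation sizes

OLS uses QR with explicit rank checks; logistic IRLS converges on a 1e-10
relative log-likelihood criterion with separation detected by diverging
coefficients alongside fitted probabilities at the boundary. Bootstrap
quantiles use the default interpolation (type 7); the BC-equals-percentile
identity when $z_0 = 0$ holds for any quantile type. The test suite
validates each stage against an independent oracle: normal equations by
explicit inversion for OLS, a brute-force ML optimiser for logistic, the
metafor package for both meta-analysis flavours, adaptive quadrature for the
Bayes factor kernel, hand-enumerated risk sets for the Cox partial
likelihood, and Bell-number recurrences for the partition count.

Calibration simulations use sizes chosen to make sampling noise small
relative to the tolerance while keeping the suite quick to run: indirect
effect recovery at n = 5000; BC interval coverage over 500 replicates at
n = 1000 with B = 1000 (the 95% interval is required to cover in 93-97% of
replicates); bootstrap-p type-I error over 400-500 null replicates at
B = 250; interaction-test size over 300-500 replicated null trials of
n = 10^4. The same measurements are recomputed from scratch by
`scripts/acceptance.R`.

# What the synthetic validation does and does not show

The generator reproduces the statistical *structure* the methods assume —
HWE genotypes, linear mediation paths, logistic events, proportional
hazards, independent censoring, MCAR missingness — at the published sample
sizes, frequencies and prevalences. Passing tests therefore demonstrate
correctness of the estimators and calibration of the intervals under those
assumptions. They do not demonstrate robustness to what real cohorts add:
linkage disequilibrium and imputation uncertainty (dosage arrives as an
exact 0/1/2 count), family relatedness, non-proportional hazards,
informative censoring or missingness, skewed biomarker errors beyond the
lognormal hook, or ancestry confounding beyond supplied PC columns. The
published per-stratum individual-level estimates (per-stratum betas,
per-stratum mediation intervals, trial event analyses) are consequently not
reproducible without the cohort microdata; the package reproduces every
quantity that is a deterministic function of printed inputs and validates
everything else by simulation.
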