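---
title: "Optimizing and calibrating polygenic scores for a target population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing and calibrating polygenic scores for a target population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prstailor)
```

## The problem

Polygenic scores (PRS) are weighted sums of allele dosages,
$s_i = \sum_j w_j d_{ij}$, with weights from published GWAS-derived scoring
files. Most published weights were trained in European-ancestry cohorts, and
both the location and the spread of the raw score distribution shift with
genetic ancestry, so a raw score is not directly interpretable in a target
sub-population. `prstailor` implements a pragmatic four-step framework for
tailoring scores to a target population using only public-style resources:

1. **Prepare**: genotype QC, application of candidate scoring files, and
   principal-component (PC) ancestry adjustment of the raw scores.
2. **Select**: a train/validation split of the target case-control cohort;
   the best candidate score per trait is the one maximizing AUC (binary
   outcomes) or adjusted $R^2$ (continuous) in training, reported on
   validation.
3. **Calibrate**: percentiles, deciles and quintiles of genomic risk are
   anchored in a fixed population *reference cohort* of the same ancestry.
4. **Extend**: ancestry-matched individuals are found in an external biobank
   by genetic distance, so the tailored scores can be validated elsewhere.

Every user-facing function takes a data frame first and returns a tibble, so
steps chain with the pipe; `run_pgs_pipeline()` orchestrates all stages from
one seeded `pipeline_config()` and writes re-loadable TSV/JSON artifacts
plus a hash-stamped manifest. The package is function-first: an analysis in
R is the intended interface, and the pipeline runner plays the role a shell
entry point would in a command-line tool.

## Models and procedures

### Ancestry adjustment and reference percentiles

A PCA model is fit on a multi-population panel: pruned-variant dosages are
standardized by panel allele frequency (center $2p$, scale
$\sqrt{2p(1-p)}$) and the loadings are the top-$k$ right singular vectors
($k = 10$ throughout, configurable). All cohorts are *projected* into this
fixed panel-anchored space, never re-fit, so coordinates are comparable
across cohorts.

Raw scores are adjusted by regressing on PC1..PC10 and keeping the
residual: `adjust_scores()` fits on a stated fit cohort and applies the
fitted coefficients to everyone. `calibrate_reference()` performs the same
regression on the reference cohort only and stores the coefficients, the
residual mean and SD, and the sorted residuals. `percentile_rank()` then
maps any sample to a z-score and a percentile against that frozen
distribution.

Two percentile conventions exist in practice and the source procedure is
ambiguous between them, so both are implemented: the default **empirical**
mode interpolates mid-rank plotting positions $100(i - 0.5)/n$ through the
sorted reference residuals; the **normal** mode reports $100\,\Phi(z)$.
They agree within about 3 percentile points on Gaussian residuals at
$n_{\mathrm{ref}} = 1000$ (tested). Outside the observed reference range
the empirical percentile clamps to $100/(2n)$ and $100 - 100/(2n)$, which
keeps percentiles inside $(0, 100)$ at the cost of strict monotonicity
beyond the observed extremes; deciles and quintiles use right-open bins
$[0, 10), \ldots, [90, 100]$.

### Quality control

The filter cascade mirrors standard array QC, with strict inequalities
exactly as conventionally printed: sample missingness $> 0.05$, then
heterozygosity rate more than 5 SD above the mean of the
missingness-survivors; variant call rate $< 0.98$, MAF $< 0.01$, exact
Hardy-Weinberg $P < 10^{-6}$ (Wigginton-style enumeration on rounded hard
calls, chi-squared approximation above $n = 5000$); and a post-imputation
filter removing INFO $< 0.3$ or MAF $< 0.01$. Variants lacking an INFO
value are retained and counted, since a missing quality score is not
evidence of a bad variant. The source narrative does not state whether
variant call rates are computed before or after sample removal; sample QC
runs first here, and a regression test pins a crafted dataset where the
order changes the result.

### Allele harmonization and scoring

Scoring-file records are matched to dataset variants on (chromosome,
position); orientation is `direct` when the effect allele is the counted
allele and `swapped` otherwise, with swapped dosages counted as
$2 - d$. Strand-ambiguous (A/T, C/G) records are always dropped and
counted — the conservative choice, since strand errors at palindromic sites
are silent. Missing dosages are mean-imputed per variant (the PLINK
`--score` convention). Normalization is a z-score against an explicitly
named cohort, because "normalized" without a cohort is ambiguous: the
reference cohort for percentile work, the fit cohort for association models.

### Evaluation

`fit_score_model()` standardizes the score to SD 1 over the complete-case
fit rows, so logistic effects are odds ratios per SD and linear effects are
units per SD, with Wald 95% CIs ($\pm 1.96\,\mathrm{SE}$, matching the
symmetric intervals the framework reports). AUC is computed in-package as
rank-based concordance (equivalently the Mann-Whitney statistic) and is
tested against an $O(n^2)$ all-pairs oracle and against pROC. Apparent
separation or non-convergence is an error, never a silently huge OR.
Decile tables report per-decile prevalence (binary) or median/IQR
(continuous) with a Woolf-CI top-vs-bottom odds ratio.
`interaction_test()` adds a score-by-factor product term (two-sided Wald p)
and fits per-stratum models with the stratifying variable removed from the
covariates. Extreme-quintile comparisons use Welch's t-test by default
(Student's optional) and chi-squared for binary characteristics. No
multiple-testing correction is applied, matching the framework's reporting;
this is flagged rather than hidden.

### Ancestry matching

`mahalanobis_match()` computes squared Mahalanobis distances
$D^2(x) = (x-\mu)^\top \Sigma^{-1} (x-\mu)$ of candidates from the target
cohort's PC centroid, with $\mu$ and $\Sigma$ the target sample mean and
covariance, and matches candidates with $D^2 \le \chi^2_{k,1-\alpha}$
(defaults $\alpha = 0.05$, $k = 10$). For $k$-variate normal coordinates
this boundary excludes $\alpha$ of the target's own distribution — the
calibration the acceptance script recomputes. The covariance is the target
*sample* covariance (the source is silent on pooled alternatives); a ridge
of $10^{-6}\,\mathrm{tr}(\Sigma)/k$ is added only when the condition number
exceeds $10^8$, which small target cohorts can hit.

`nearest_neighbor_match()` builds 1:1 comparator cohorts: greedy sequential
nearest-neighbor matching without replacement in a seed-shuffled case
order, Euclidean distance on standardized continuous covariates with exact
matching enforced on binary covariates first. This deviates deliberately
from propensity-logit matching defaults: the propensity model behind the
original tool is unspecified, whereas standardized-Euclidean matching with
exact binary constraints is fully reproducible from the stated inputs.

## The synthetic-data generator

No raw data accompanies the framework (the motivating cohorts are
IRB-restricted), so `sim_config()` / `simulate_genotypes()` /
`simulate_scoring_files()` / `simulate_phenotypes()` generate cohorts with
the statistical structure the analysis assumes:

* **Population structure** is Balding-Nichols: ancestral frequencies
  $p \sim U(0.05, 0.95)$, population frequencies
  $p_k \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F$ the Fst
  parameter (copied exactly at $F = 0$), genotypes
  $\mathrm{Binomial}(2, p_k)$. A Hudson-estimator test confirms the
  realized differentiation tracks $F$.
* **Cohort roles** mirror the study design: a multi-population `panel`
  (default 2481), a target-ancestry `reference` (default 1017), a target
  `case_control` cohort (default 5399, split 2700/2699 downstream), and a
  mixed `biobank` with a planted target-ancestry fraction.
* **Disease** follows the liability-threshold model: liability
  $\sqrt{h^2} g + \sqrt{1-h^2}\,\varepsilon$ with $g$ the standardized true
  weighted dosage sum; a sample is a case when liability exceeds
  $\Phi^{-1}(1 - \mathrm{prevalence})$. Default prevalences follow the
  motivating cardiology-referral setting: CAD 0.65, type 2 diabetes 0.556,
  cardiomyopathy 0.093.
* **Continuous traits** use the same $g$ with trait-specific independent
  noise and the referral-cohort means/SDs (e.g. LDL 135.8 (53.4) mg/dL,
  BMI 29.3 (6.05) kg/m²), truncated below at a small positive value so
  measured quantities stay nonnegative. Using one shared $g$ across traits
  is a deliberate simplification — it is sufficient for every downstream
  contract while keeping fixtures cheap.
* **Medication** flags are logistic in the standardized *untreated* trait
  (coefficients live in `sim_config`), and the measured values then carry
  the forward treatment effect (statin LDL ×0.70 and TG ×0.85, ezetimibe
  LDL ×0.80, fibrate LDL ×0.90, antihypertensive SBP −15 / DBP −10 mmHg),
  so `adjust_lipids()` / `adjust_bp()` recover the untreated truth exactly
  for the implemented adjustments — a round-trip the tests assert at
  1e-10.
* **Candidate scoring files** are one true causal weight vector plus
  independent Gaussian noise scaled per candidate, emulating a panel of
  derivation methods of varying quality for `select_best()`.
* **Corruption knobs** (uniform missingness, a partial Uniform(0,1) INFO
  column, exact-duplicate variants at adjacent positions) exist solely to
  exercise QC and LD pruning.

What the generator does *not* emulate: linkage disequilibrium beyond the
optional exact duplicates (variants are independent), sex chromosomes,
imputation error structure, relatedness, or trait-specific genetic
architectures. Passing tests therefore demonstrate that the *procedures*
are implemented correctly under the assumed generative structure, not that
any particular real-data performance number would be reproduced.

## Numerical choices and degenerate inputs

* Seeds are mandatory everywhere randomness occurs (`sim_config`,
  `split_cohort`, `replicate_subsets`, `nearest_neighbor_match`,
  `pipeline_config`); identical config + seed gives byte-identical pipeline
  artifacts, which the pipeline test checks via file hashes.
* LD pruning is greedy within windows of `window` variants sliding by
  `step` (defaults 1000/50 at threshold $r^2 \ge 0.2$): the lower-MAF
  member of an offending pair is removed, ties broken toward the later
  position. This is an artifact convention; PLINK's exact tie-breaking
  differs in unspecified ways. The postcondition (no surviving
  within-window pair at $r^2 \ge 0.2$) is brute-force checked in tests.
* Monomorphic variants are excluded from PCA (their scale would be zero);
  `k` exceeding the numerical rank of the panel is an error.
* Constant PC columns drop out of score-adjustment regressions (they carry
  no ancestry signal, so the fit degrades gracefully to the intercept);
  genuinely collinear PCs are an error naming the rank.
* A constant reference cohort cannot be calibrated (zero residual
  variance, detected with a float-noise tolerance).
* Fibrate effects on TG and HDL have no established magnitudes in the
  framework's methods, only a footnote that adjustment occurred; they are
  optional rule entries with no default, and affected samples are flagged
  (`tg_needs_fibrate_adjustment`) rather than silently adjusted.
  "Hypercholesterolemia" is likewise never defined and is not derived.
* Left-main obstructive disease is excluded from the 1-3 vessel severity
  count (the three countable arteries are LAD, LCx, RCA) and carried as its
  own flag.

## Problem sizes

The test suite and the acceptance script run on deliberately desk-scale
instances: cohorts of a few hundred to a few thousand samples and 150-500
variants, 10 PCs, 10,000 Mahalanobis candidates per replicate, 100-200
Monte-Carlo seeds for the parameter-recovery and type-I-error suites. These
sizes were chosen so every statistical check retains its intended power
while the whole suite completes in about a minute; the defaults in
`sim_config()` remain the full study-shaped cohort sizes.

## Known limitations

Projection of new samples onto panel PCs is plain projection without
shrinkage correction; robust or probabilistic PCA, admixture modeling,
genome-build liftover, multi-allelic variants, dominance encodings, and
survival modeling are out of scope. The framework is cross-sectional by
design: nothing here estimates longitudinal risk.
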