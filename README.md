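# prstailor

Polygenic scores (PRS) — weighted sums of allele dosages with weights from
published GWAS scoring files — lose calibration and performance when carried
into populations distant from the ones they were trained in. `prstailor` is
an R package for analysts who need to *tailor* PRS to a target
sub-population using only publicly accessible resources: candidate scoring
files in PGS Catalog format, a multi-population reference panel for
principal components of ancestry, and a fixed population reference cohort of
the target ancestry.

The pipeline implements a pragmatic four-step framework:

1. **Prepare** — genotype/sample QC (missingness, heterozygosity, call rate,
   MAF, exact Hardy-Weinberg, post-imputation INFO filter), allele
   harmonization of scoring files, raw score computation
   `s_i = Σ_j w_j d_ij`, and ancestry adjustment by taking the residual of
   the raw score on the first 10 principal components.
2. **Select** — a seeded train/validation split; the best candidate score
   maximizes AUC (binary traits) or adjusted R² (continuous) in training and
   is reported on validation as an odds ratio or effect per SD of score with
   a Wald 95% CI.
3. **Calibrate** — percentiles, deciles and quintiles of genomic risk
   anchored in the reference cohort's PC-residual distribution, feeding
   decile prevalence tables, interaction tests with conventional risk
   factors, and extreme-quintile comparisons.
4. **Extend** — ancestry matching in an external biobank by squared
   Mahalanobis distance from the target centroid in PC space,
   `D²(x) = (x − μ)ᵀ Σ⁻¹ (x − μ)`, with the chi-squared critical value at
   α = 0.05 and 10 df as the match boundary.

Because the motivating cohorts of such analyses are typically
IRB-restricted, the package ships a first-class synthetic-cohort generator
(Balding-Nichols population structure, additive polygenic
liability-threshold disease, clinical covariates, medication use with known
forward effects) so every stage is testable end to end.

## Worked example

Simulate a two-population study, tailor a score, and stratify risk:

```r
library(prstailor)

cfg <- sim_config(
  seed = 2026, n_populations = 2, fst = 0.1,
  n_variants = 400, n_causal = 60, h2 = 0.5, prevalence = 0.5,
  cohort_sizes = c(panel = 300, reference = 300,
                   case_control = 800, biobank = 300)
)
dataset <- simulate_genotypes(cfg)
scoring <- simulate_scoring_files(dataset, cfg, 3, c(0, 0.5, 2))
pheno   <- simulate_phenotypes(dataset, attr(scoring, "truth"), cfg)

panel <- subset_cohort(dataset, "panel")
model <- fit_pca(panel, ld_prune(panel, window = 200, step = 50), k = 10)
pcs   <- project_pcs(model, dataset)

scores  <- compute_raw_scores(harmonize_weights(scoring$cand1, dataset),
                              dataset, normalization_cohort = "reference")
ref_ids <- dataset$samples$sample_id[dataset$samples$cohort == "reference"]
refdist <- calibrate_reference(scores[scores$sample_id %in% ref_ids, ], pcs)

cc_ids <- dataset$samples$sample_id[dataset$samples$cohort == "case_control"]
pct <- percentile_rank(refdist, scores[scores$sample_id %in% cc_ids, ], pcs)
dat <- dplyr::inner_join(dplyr::left_join(pct, scores, by = "sample_id"),
                         pheno, by = "sample_id")

fit_score_model(dat, "normalized", "cad",
                c("age", "sex", "array_version"), "logistic")
#> <score_eval> cad ~ normalized (logistic), n = 800
#>   OR per SD = 4.515 (95% CI 3.601-5.662), p = 6.1e-39; auc = 0.8187

decile_stratify(dat, "cad", "binary")
#>    decile     n cases prevalence
#>  1      1    87     5     0.0575
#>  ...
#> 10     10    82    75     0.915
```

The per-SD odds ratio says how much the odds of coronary artery disease
multiply per standard deviation of the ancestry-adjusted score; the decile
table shows prevalence rising from 5.8% in the bottom reference-anchored
decile to 91.5% in the top (a strong simulated signal: h² = 0.5 with a
noise-free scoring file). Ancestry matching of the mixed biobank against the
target reference recovers roughly the planted target-ancestry fraction:

```r
glance(mahalanobis_match(pcs[dataset$samples$cohort == "biobank", ],
                         pcs[dataset$samples$cohort == "reference", ]))
#>   n_candidates n_matched matched_fraction cutoff alpha    df n_target
#> 1          300        68            0.227   18.3  0.05    10      300
```

`run_pgs_pipeline(pipeline_config(...))` chains all stages — QC → scoring →
ancestry → calibration → selection → stratification → matching → evaluation
— writing re-loadable TSV/JSON artifacts and a hash-stamped manifest;
identical config and seed give byte-identical outputs. `autoplot()` methods
cover decile tables and Mahalanobis match objects; `tidy()`/`glance()`
return broom-style tibbles for fitted objects.

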