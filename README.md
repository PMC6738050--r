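# kinmr

Mendelian randomisation (MR) for time-to-event outcomes in ascertained
mutation-carrier cohorts.

`kinmr` is aimed at statistical geneticists and cancer epidemiologists
analysing quantitative traits (height, BMI) as modifiers of cancer risk in
clinic-recruited *BRCA1/2* carrier cohorts — settings where two problems
dominate: affected families are oversampled, and carriers cluster within
families. The package provides the complete analysis chain:

- **Genetic scores**: `GS = Σᵢ β_XGi · SNPᵢ`, the weighted sum of
  effect-allele dosages under an additive model, rescaled to trait units
  by regressing the observed trait on the raw score among non-case
  carriers (`load_snp_weights()`, `build_raw_scores()`, `fit_scaling()`).
- **Kin-cohort ascertainment weights**: within each gene × exit-age-band
  stratum, cases weigh `p_exp/p_obs` and non-cases
  `(1−p_exp)/(1−p_obs)` against external age-specific incidence, so the
  weighted case fraction matches the population's (`build_weights()`).
- **Weighted Cox models** on the age timescale with counting-process
  episodes, time-varying menopausal status (missing menopause age imputed
  at 50), and family-clustered robust sandwich variance
  (`split_episodes()`, `fit_weighted_cox()`, `interaction_test()`,
  `subtype_analysis()`).
- **Per-variant MR**: a per-SNP weighted Cox scan, the
  inverse-variance-weighted causal estimate
  `β_YX = Σ β_XGi β_YGi SE(β_YGi)⁻² / Σ β_XGi² SE(β_YGi)⁻²` with
  `SE_YX = (Σ β_XGi² SE(β_YGi)⁻²)^{-1/2}`, Cochran Q / I² heterogeneity on
  the per-variant Wald ratios, and MR-Egger's intercept test for
  directional pleiotropy (`scan_snps()`, `ivw_estimate()`,
  `heterogeneity()`, `egger_test()`).
- **Two-stage residual inclusion (TSRI)**: stage-one OLS of the trait on
  its score and covariates; stage-two weighted Cox on the trait plus the
  stage-one residual; family-level percentile bootstrap for uncertainty
  (`tsri_fit()`, `bootstrap_ci()`).
- **A synthetic-cohort generator** (`sim_config()`, `simulate_cohort()`,
  `ascertain()`) with family-structured genotypes, calibrated score-trait
  R², configurable confounding, Weibull baseline hazards per gene,
  competing censoring, and case-oversampled recruitment — every stage of
  the pipeline is testable without access to consortium data.
- **Orchestration**: `run_pipeline()` drives
  simulate/load → score → weight → fit → MR → TSRI and writes a
  reproducible report bundle (adjustment-ladder and subgroup tables,
  per-variant table, IVW and TSRI JSON, manifest); a thin command-line
  wrapper lives at `inst/cli/kinmr.R`.

The methods vignette (`vignettes/kinmr-methods.Rmd`) documents the models,
assumptions, numerical choices, and limitations.

## Worked example

A consortium-scale synthetic study — ~21,000 carriers from ~8,400
families, 13% ovarian-cancer cases after four-fold family oversampling, a
50-variant height-like panel explaining ~13% of trait variance, and a
generating hazard ratio of 1.07 per 10 cm:

```r
library(kinmr)

cfg <- sim_config(n_families = 26000, n_snps = 50,
                  causal_log_hr_per_unit = 0.007, seed = 42)
cohort <- ascertain(simulate_cohort(cfg), factor = 4, seed = 43)
cohort
#> synthetic carrier cohort: 20905 women, 8396 families, 50 variants
#>   cases: 2559 (12.2%); trait 'height_cm' observed for 7151

scores  <- build_raw_scores(cohort$genotypes, cohort$snp_weights)
pheno   <- cohort$phenotypes
scaling <- fit_scaling(scores, setNames(pheno$height_cm, pheno$person),
                       non_case = !pheno$case)
scaling
#> scaling model: trait = 144.406 + 0.971 * raw (R^2 = 0.123, n = 6303 non-cases)
scores <- scale_scores(scores, scaling)
pheno$gs_scaled <- scores$scaled[match(pheno$person, scores$person)]

w  <- build_weights(pheno, cohort$incidence)
ep <- split_episodes(pheno, menopause_imputation_age = 50, weights = w)
fit <- fit_weighted_cox(ep, c("gs_scaled", paste0("pc", 1:8), "country",
                              "birth_decade", "gene", "postmeno"))
hr_per_k(fit, "gs_scaled", k = 10)[c("hr", "ci_lo", "ci_hi", "p")]
#> $hr      0.985
#> $ci_lo   0.788
#> $ci_hi   1.230
#> $p       0.893

assocs <- scan_snps(ep, cohort$genotypes, cohort$snp_weights,
                    c(paste0("pc", 1:8), "country", "birth_decade",
                      "gene", "postmeno"))
ivw_estimate(assocs)
#> IVW causal estimate: beta = -0.0018 (SE 0.0110, p = 0.87) from 50 variants
#>   heterogeneity: Q = 59.26 on 49 df, I^2 = 17.3%
```

Reading the output: the score-based hazard ratio per 10 cm of genetically
predicted height is 0.98 (95% CI 0.79–1.23) and the IVW estimate is
−0.002 per trait unit (SE 0.011) — both consistent with the generating
log hazard ratio of 0.007/cm at this sample size, and an honest picture
of the precision such a cohort buys: genetic instruments explaining 13%
of trait variance cost roughly a 1/√0.13 ≈ 2.8-fold wider standard error
than the observational fit.

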