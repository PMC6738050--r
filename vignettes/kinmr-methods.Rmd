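---
title: "Mendelian randomisation for survival outcomes in ascertained carrier cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinmr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Women carrying pathogenic *BRCA1* or *BRCA2* variants face lifetime ovarian
cancer risks far above the population's, and anthropometric traits —
height and body-mass index — are candidate modifiers of that risk.
Observational associations between such traits and cancer are easily
distorted by confounding and reverse causation. Mendelian randomisation
(MR) sidesteps part of that problem: genetic variants that shift the trait
are fixed at conception, so a trait-increasing allele acts as a randomised
nudge to the exposure. `kinmr` implements the full analysis chain for an
MR study of a quantitative trait against a time-to-event cancer outcome in
a clinic-ascertained carrier cohort, together with a synthetic-cohort
generator that reproduces the statistical structure such a study assumes.

Two features make carrier cohorts statistically awkward, and both shape
the package:

1. **Ascertainment.** Families are recruited through genetics clinics, so
   affected women (and their relatives) are strongly over-represented. An
   unweighted Cox fit on such a sample is attenuated because risk sets are
   enriched with future cases.
2. **Family clustering.** Several carriers per family share genotype and
   environment, so observations are not independent.

## Models and estimators

### Genetic scores and scaling

The raw score is the additive weighted sum over the variant panel,
`GS = sum_i beta_i * dosage_i`, with `beta_i` the external per-allele trait
effect and dosages oriented to count the trait-increasing allele
(`build_raw_scores()`). Dosage columns are aligned to effect alleles,
allowing allele swaps (dosage becomes `2 - d`) and strand complements;
palindromic A/T and C/G variants are rejected only when the effect-allele
frequency lies in [0.4, 0.6], where strand orientation is genuinely
ambiguous. Missing person-variant dosages are mean-imputed as `2 * EAF`,
the standard polygenic-score convention. Variants with imputation quality
below 0.5 are excluded at load time (quality exactly 0.5 is retained).

Raw scores are converted to trait units by ordinary least squares of the
observed trait on the raw score among *non-case* carriers
(`fit_scaling()`); the fitted intercept and slope define
`scaled = beta0 + beta1 * raw`. Regressing the trait on the score (rather
than the reverse) is forced by the convention that the fitted intercept is
reported in trait units (an intercept near the population mean height only
arises in that direction). Non-cases of both genes are pooled, and
BMI-like scores are scaled to the questionnaire-time measurement, never
the early-adulthood recall.

### Ascertainment weights

`build_weights()` implements kin-cohort style weighting: within each
stratum of gene and exit-age band (5-year bands by default), cases receive
weight `p_exp / p_obs` and non-cases `(1 - p_exp) / (1 - p_obs)`, where
`p_obs` is the observed case fraction and `p_exp` the expected fraction
under an external age-specific incidence table. The weighted case fraction
then equals `p_exp` exactly in every stratum. Sparse strata (fewer than 10
women, or all/none cases) are merged into the adjacent band and reported.
The incidence table is an input, as it would be in practice; for synthetic
cohorts `incidence_from_truth()` derives it from the generator's own
marginal survival so that the weighting target is internally consistent.

This weighting is an approximation, not inverse-probability sampling
theory: it calibrates stratum case fractions rather than inverting the
exact recruitment mechanism. In our recovery experiments (strong effects,
eight-fold family oversampling) the weighted fit lands within Monte-Carlo
error of the generating log hazard ratio while the unweighted fit is
attenuated by many standard errors; at weaker, more realistic effect sizes
a small residual bias of a few percent of the coefficient remains, which is
invisible at the precision any single cohort provides.

### Weighted Cox models with time-varying menopause

`split_episodes()` expands each woman into counting-process episodes on
the age timescale, entering at birth and exiting at the first of ovarian
cancer diagnosis (the only event), breast cancer diagnosis, risk-reducing
salpingo-oophorectomy (RRSO), death, or end of follow-up. Menopausal
status is time-varying: person-time before the age at natural menopause is
premenopausal, later person-time postmenopausal. When postmenopausal
status is known but the age missing, the split falls at 50 years by
default (46 available as a sensitivity setting; both values bracket the
population mean and median). RRSO both censors and induces surgical
menopause, so it contributes no postmenopausal person-time. Because
splitting only partitions person-time, any model without a menopausal term
is numerically unchanged by the choice of split age — a property the test
suite checks.

`fit_weighted_cox()` maximises the weighted Cox partial likelihood via
`survival::coxph()` with Efron tie handling by default (Breslow by flag)
and a robust sandwich variance aggregating score residuals within
families. Degenerate design matrices are rejected by a rank check
(tolerance 1e-10); monotone likelihood is fatal when it affects the
leading exposure term, while a runaway nuisance dummy (a country or
birth-decade level without events inside a subgroup) is flagged but
tolerated, mirroring how such fits are treated in practice. Hazard ratios
are reported per 10 cm of height or per 5 kg/m^2 of BMI via `hr_per_k()`.

Subgroup machinery: `interaction_test()` adds an exposure-by-modifier
product term and reads the robust Wald p of that term; with a time-varying
menopausal modifier this doubles as a proportional-hazards check.
`subtype_analysis()` refits per tumour class after censoring cases of the
complementary class at their diagnosis age, and compares class
coefficients with a two-sample Wald test on robust standard errors under
an independence approximation — the classes share controls, so this p is
mildly conservative, which our null simulations confirm.

### Per-variant scan and IVW combination

`scan_snps()` fits one weighted Cox model per variant (dosage plus the
covariate set) and collects per-allele log hazard ratios `beta_YG` with
robust SEs. Variants that fail to converge or have constant dosage are
flagged, excluded from combination, and enumerated — never silently
dropped. The combined causal effect per trait unit is the
inverse-variance-weighted estimator

    beta_YX = sum_i beta_XGi beta_YGi SE_i^-2 / sum_i beta_XGi^2 SE_i^-2,
    SE_YX   = sqrt(1 / sum_i beta_XGi^2 SE_i^-2),

algebraically identical to an SE^-2-weighted through-origin regression of
`beta_YG` on `beta_XG` (a test asserts agreement to 1e-10, and a second
route checks equality with fixed-effect meta-analysis of the per-variant
Wald ratios). Heterogeneity uses Cochran Q on the Wald ratios
`beta_YG / beta_XG` with first-order SEs `SE_i / |beta_XGi|`, and
`I^2 = max(0, (Q - (k-1))/Q)`. MR-Egger is the same weighted regression
with a free intercept after orienting all trait effects non-negative; the
intercept's normal-approximation Wald p flags directional pleiotropy. The
fixed-effect (known-variance) covariance convention is used rather than
lm's residual rescaling. Instruments are treated as independent — no LD
adjustment — consistent with the estimator's assumptions.

### Two-stage residual inclusion

`tsri_fit()` implements the control-function IV estimator for survival
outcomes: stage one regresses the observed trait on its scaled genetic
score and baseline covariates; stage two fits a weighted Cox model on the
observed trait, the stage-one residual, and the covariates. The stage-two
trait coefficient is the causal log hazard ratio per trait unit. A
noiseless first stage leaves no residual to include and the fit reduces to
the plain Cox model, which the code recognises explicitly. The stage-two
model uses the same ascertainment weights as the main analysis by default
(`use_weights = FALSE` switches them off); whether stage one should also
be restricted to non-cases was left open in the source methodology — we
fit it on all analysable women, since restricting would discard the cases
whose hazard the second stage models.

Uncertainty comes from `bootstrap_ci()`: families are resampled with
replacement (resampled copies become distinct clusters), both stages are
refitted per replicate, and the percentile 2.5/97.5 interval is reported
(inverse-empirical-CDF quantiles, so B = 2 returns the ordered pair).
Family-level resampling matches the family-clustered sandwich variance
used elsewhere; percentile intervals avoid normality assumptions the
replicate distribution may not satisfy at IV-scale noise. Replicate
failures are tolerated up to 10% and counted. The production default is
B = 10,000; tests and the worked examples use B in the hundreds, which is
adequate for percentile endpoints at the precision those checks assert.

## The synthetic-cohort generator

`simulate_cohort()` draws, per family, two unobserved founder haplotype
pairs per variant and transmits one allele from each founder to every
cohort member, so dosages are marginally Hardy-Weinberg while siblings
correlate at 0.5 — enough structure to exercise the clustered variance and
family bootstrap without pedigree machinery. The trait is
`intercept + GS + c_t * U + noise` with `U` a standard-normal per-person
confounder; variant effects are rescaled so the population score-trait R^2
equals the configured target exactly (default 0.13, the height-panel
value; a configuration whose score plus confounder variance exceeds the
trait variance is rejected up front). Event times follow a proportional
hazards model with per-gene Weibull baselines (shape 5, scale anchored so
lifetime risk by 80 is 40% for the higher-risk gene and 15% for the
other — order-of-magnitude realism, not a penetrance model) and log hazard
`gamma * (trait - mean) + c_h * U`. Competing censoring (end of follow-up,
RRSO, breast cancer, death) uses truncated-normal age distributions; age at
natural menopause is truncated-normal (mean 48, SD 4, range 35-60), with a
configurable fraction of postmenopausal women missing the age. Two thirds
of the cohort lack the measured trait by default, matching the fraction
with questionnaire anthropometry in consortium data. `ascertain()`
emulates clinic recruitment by retaining case-containing families with
probability `min(1, factor * p_base)` and case-free families with
`p_base`; at the default `p_base = 1/factor`, a factor of 4 yields a
case fraction near 13%, the consortium-like regime.

All randomness flows through the single integer seed in the
configuration; the same configuration is byte-reproducible. The truth
record carries every generating parameter needed to score recovery.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between instruments
(real panels are LD-pruned imperfectly), population stratification beyond
noise PCs, pleiotropic variants, secular trends in anthropometry,
informative missingness of the trait, and recruitment mechanisms more
selective than family-level case oversampling.

## Numerical choices and problem sizes

Gauss-Hermite quadrature (40 nodes, Golub-Welsch construction) marginalises
the baseline survival over the Gaussian linear predictor when building
incidence tables, keeping them deterministic. Collinearity is rejected at
QR rank tolerance 1e-10. Percentile intervals use inverse-empirical-CDF
quantiles. The test and acceptance suites use cohorts of roughly 1,000 to
50,000 women, 5 to 200 variants, 500 null replicates for interaction-test
size, and 100 outer repetitions with B = 500 for bootstrap coverage —
sizes chosen so that each property is tested at the precision asserted
(e.g. coverage needs enough events per cohort for Cox asymptotics to hold,
so those cohorts use later follow-up, ~70 events each). The bias-recovery
experiment uses a deliberately strong effect (log HR 0.08/cm) and
eight-fold oversampling so that the attenuation of the unweighted fit is
many times its standard error on a single cohort.

## Known limitations

- The kin-cohort weighting is calibration, not exact inverse-probability
  correction; a small residual bias (a few percent of the coefficient)
  is measurable in replicate averages at strong effect sizes.
- Robust variance and family bootstrap address dependence but not shared
  frailty; no frailty or competing-risks models are provided.
- The subtype heterogeneity p treats class estimates as independent
  although they share controls (conservative).
- MR-Egger's intercept test uses the fixed-effect covariance; with
  overdispersed per-variant effects it is anti-conservative relative to
  multiplicative-error MR-Egger.
- Per-variant scans refit the full covariate model per variant; for
  panels far beyond ~600 variants a score-test screen would be the
  practical choice.
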