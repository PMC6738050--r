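# Synthetic carrier-cohort generator.
#
# Emulates the statistical structure of a clinic-ascertained BRCA1/2
# mutation-carrier cohort: family-clustered genotypes via parental
# haplotype transmission, a polygenic quantitative trait with a calibrated
# score-trait R^2, an optional shared confounder acting on both the trait
# and the hazard, Weibull baseline hazards per gene, competing censoring
# events (breast cancer, risk-reducing salpingo-oophorectomy, death, end of
# follow-up), time-anchored menopause, and case-oversampled ascertainment.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' emulate a height-like trait (mean 165 cm, SD 6.9 cm, score R^2 0.13 from
#' 586 variants) in a cohort of roughly 22,000 women from ~9,000 families,
#' with BRCA1-like and BRCA2-like lifetime risks of about 40% and 15% by
#' age 80 and about two thirds of the cohort missing the measured trait.
#'
#' @param n_families Number of families.
#' @param family_size_probs Probability vector over family sizes 1..k.
#' @param prob_gene1 Probability that a family carries the higher-risk gene
#'   (`"BRCA1"`); mutations segregate at family level.
#' @param n_snps Number of independent trait-associated variants.
#' @param eaf_range Interval in (0,1) from which effect-allele frequencies
#'   are drawn uniformly.
#' @param beta_xg_scale Dispersion (trait units/allele) of the raw per-allele
#'   effects before calibration; only the shape of the effect-size
#'   distribution matters because effects are rescaled to hit
#'   `gs_r2_target`.
#' @param trait_mean,trait_sd Population mean and SD of the trait.
#' @param gs_r2_target Fraction of trait variance explained by the genetic
#'   score, in `[0, 1)`.
#' @param causal_log_hr_per_unit Causal log hazard ratio per trait unit.
#' @param confounder_effect Length-2 numeric `c(on_trait, on_log_hazard)`
#'   for a standard-normal per-person confounder.
#' @param baseline_hazard Per-gene Weibull baselines: a named list with
#'   entries `BRCA1` and `BRCA2`, each `list(shape=, lifetime_risk=)`
#'   (cumulative risk by `horizon` at the reference covariate level) or
#'   `list(shape=, scale=)`.
#' @param horizon Age (years) at which `lifetime_risk` is anchored.
#' @param menopause_age_dist `list(mean, sd, lo, hi)` truncated normal for
#'   age at natural menopause (years).
#' @param menopause_missing_fraction Fraction of postmenopausal women whose
#'   age at menopause is masked (status known, age missing).
#' @param censoring Nested list controlling competing censoring:
#'   `followup = list(mean, sd, lo, hi)` and, for each of `rrso`, `breast`,
#'   `death`, `list(frac, mean, sd, lo, hi)`.
#' @param case_oversampling_factor Ascertainment factor `>= 1` applied by
#'   [ascertain()]; stored here for pipeline use.
#' @param missing_trait_fraction Fraction of the cohort with the measured
#'   trait masked.
#' @param trait_name Phenotype column receiving the simulated causal trait,
#'   one of `"height_cm"`, `"bmi_now"`, `"bmi_young"`.
#' @param seed Integer seed; same config and seed give identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 9000,
                       family_size_probs = c(0.25, 0.30, 0.25, 0.20),
                       prob_gene1 = 0.65,
                       n_snps = 586,
                       eaf_range = c(0.05, 0.95),
                       beta_xg_scale = 0.5,
                       trait_mean = 165,
                       trait_sd = 6.9,
                       gs_r2_target = 0.13,
                       causal_log_hr_per_unit = 0.007,
                       confounder_effect = c(0, 0),
                       baseline_hazard = list(
                         BRCA1 = list(shape = 5, lifetime_risk = 0.40),
                         BRCA2 = list(shape = 5, lifetime_risk = 0.15)),
                       horizon = 80,
                       menopause_age_dist = list(mean = 48, sd = 4,
                                                 lo = 35, hi = 60),
                       menopause_missing_fraction = 0.3,
                       censoring = list(
                         followup = list(mean = 50, sd = 12, lo = 21, hi = 85),
                         rrso   = list(frac = 0.18, mean = 45, sd = 8,
                                       lo = 30, hi = 70),
                         breast = list(frac = 0.22, mean = 45, sd = 10,
                                       lo = 25, hi = 80),
                         death  = list(frac = 0.05, mean = 60, sd = 15,
                                       lo = 30, hi = 95)),
                       case_oversampling_factor = 1,
                       missing_trait_fraction = 0.66,
                       trait_name = c("height_cm", "bmi_now", "bmi_young"),
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              family_size_probs = family_size_probs / sum(family_size_probs),
              prob_gene1 = prob_gene1,
              n_snps = as.integer(n_snps),
              eaf_range = eaf_range,
              beta_xg_scale = beta_xg_scale,
              trait_mean = trait_mean, trait_sd = trait_sd,
              gs_r2_target = gs_r2_target,
              causal_log_hr_per_unit = causal_log_hr_per_unit,
              confounder_effect = as.numeric(confounder_effect),
              baseline_hazard = baseline_hazard,
              horizon = horizon,
              menopause_age_dist = menopause_age_dist,
              menopause_missing_fraction = menopause_missing_fraction,
              censoring = censoring,
              case_oversampling_factor = case_oversampling_factor,
              missing_trait_fraction = missing_trait_fraction,
              trait_name = match.arg(trait_name),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_families >= 1, cfg$n_snps >= 1,
            all(cfg$family_size_probs >= 0),
            cfg$prob_gene1 >= 0, cfg$prob_gene1 <= 1,
            length(cfg$eaf_range) == 2,
            cfg$eaf_range[1] > 0, cfg$eaf_range[2] < 1,
            cfg$eaf_range[1] < cfg$eaf_range[2],
            cfg$beta_xg_scale > 0, cfg$trait_sd > 0,
            cfg$gs_r2_target >= 0, cfg$gs_r2_target < 1,
            length(cfg$confounder_effect) == 2,
            cfg$case_oversampling_factor >= 1,
            cfg$missing_trait_fraction >= 0, cfg$missing_trait_fraction <= 1,
            cfg$menopause_missing_fraction >= 0,
            cfg$menopause_missing_fraction <= 1)
  # Residual trait variance must stay positive once the score and the
  # confounder claim their shares.
  resid_var <- cfg$trait_sd^2 * (1 - cfg$gs_r2_target) -
    cfg$confounder_effect[1]^2
  if (resid_var <= 0)
    stop_kinmr(paste("infeasible gs_r2_target %.3f: score plus confounder",
                     "variance exceeds trait variance"), cfg$gs_r2_target)
  invisible(cfg)
}

weibull_scale_for_risk <- function(shape, lifetime_risk, horizon) {
  horizon / (-log(1 - lifetime_risk))^(1 / shape)
}

resolve_baseline <- function(bh, horizon) {
  lapply(bh, function(g) {
    if (is.null(g$scale))
      g$scale <- weibull_scale_for_risk(g$shape, g$lifetime_risk, horizon)
    g[c("shape", "scale")]
  })
}

# Variance of the hazard linear predictor gamma*(trait - mean) + c_hr*U,
# with cov(trait, U) = c_trait.
lp_variance <- function(truth) {
  g <- truth$causal_log_hr_per_unit
  ct <- truth$confounder_effect[1]
  ch <- truth$confounder_effect[2]
  g^2 * truth$trait_sd^2 + ch^2 + 2 * g * ch * ct
}

#' Marginal baseline survival of the generating model
#'
#' Population survival free of censoring, marginalised over the Gaussian
#' linear predictor by Gauss-Hermite quadrature.
#'
#' @param truth Truth record of a [simulate_cohort()] result.
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param ages Vector of ages.
#' @return Survival probabilities at `ages`.
#' @export
marginal_survival <- function(truth, gene, ages) {
  wb <- truth$baseline_hazard[[gene]]
  v <- lp_variance(truth)
  H0 <- (ages / wb$scale)^wb$shape
  if (v <= 0) return(exp(-H0))
  gh_expect(function(x) exp(-outer(exp(x), H0)), v)
}

#' External-style incidence table from the generating model
#'
#' Converts the generator's own marginal incidence into the age-banded
#' conditional-probability format that [build_weights()] consumes, playing
#' the role of the previously observed carrier incidence an analyst would
#' supply from the literature.
#'
#' @param truth Truth record of a [simulate_cohort()] result.
#' @param breaks Age-band boundaries (years), default 5-year bands 20-80.
#' @return Data frame with columns `gene`, `age_lo`, `age_hi`, `prob` where
#'   `prob` is the probability of a first event in `[age_lo, age_hi)` given
#'   event-free at `age_lo`.
#' @export
incidence_from_truth <- function(truth, breaks = seq(20, 80, by = 5)) {
  out <- lapply(names(truth$baseline_hazard), function(g) {
    S <- marginal_survival(truth, g, breaks)
    data.frame(gene = g,
               age_lo = breaks[-length(breaks)],
               age_hi = breaks[-1],
               prob = (S[-length(S)] - S[-1]) / S[-length(S)])
  })
  do.call(rbind, out)
}

# Family-structured dosages: two unobserved founder haplotype pairs per
# family; each cohort member receives one randomly transmitted allele from
# each founder. Marginally Hardy-Weinberg; siblings correlate at 0.5.
sim_genotypes <- function(n_fam, fam_index, eaf) {
  n_snps <- length(eaf)
  n <- length(fam_index)
  draw <- function(nr) matrix(stats::rbinom(nr * n_snps, 1L,
                                            rep(eaf, each = nr)), nr, n_snps)
  m1 <- draw(n_fam); m2 <- draw(n_fam)
  f1 <- draw(n_fam); f2 <- draw(n_fam)
  pick <- function(a, b) {
    s <- matrix(stats::rbinom(n * n_snps, 1L, 0.5), n, n_snps)
    s * a[fam_index, , drop = FALSE] + (1L - s) * b[fam_index, , drop = FALSE]
  }
  pick(m1, m2) + pick(f1, f2)
}

#' Simulate a synthetic carrier cohort
#'
#' Draws family-clustered genotypes, a polygenic trait calibrated to the
#' configured score R^2, proportional-hazards event times, competing
#' censoring, menopause, and questionnaire-style phenotype columns. The
#' returned truth record suffices to score parameter recovery downstream.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"synthetic_cohort"` with elements `phenotypes`
#'   (one row per woman), `genotypes` (`list(person, rsid, dosage)` with an
#'   integer dosage matrix), `snp_weights` (panel data frame in the
#'   weight-file layout), `incidence` (from [incidence_from_truth()]), and
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  sizes <- sample(seq_along(cfg$family_size_probs), cfg$n_families,
                  replace = TRUE, prob = cfg$family_size_probs)
  fam_index <- rep(seq_len(cfg$n_families), sizes)
  n <- length(fam_index)
  person <- sprintf("P%06d", seq_len(n))
  family <- sprintf("F%05d", fam_index)
  gene_fam <- ifelse(stats::runif(cfg$n_families) < cfg$prob_gene1,
                     "BRCA1", "BRCA2")
  gene <- gene_fam[fam_index]

  ## variant panel
  eaf <- stats::runif(cfg$n_snps, cfg$eaf_range[1], cfg$eaf_range[2])
  beta <- abs(stats::rnorm(cfg$n_snps, 0, cfg$beta_xg_scale))
  var_gs_raw <- sum(beta^2 * 2 * eaf * (1 - eaf))
  if (var_gs_raw <= 0)
    stop_kinmr("infeasible gs_r2_target: degenerate variant panel")
  if (cfg$gs_r2_target > 0)
    beta <- beta * sqrt(cfg$gs_r2_target * cfg$trait_sd^2 / var_gs_raw)
  else
    beta <- beta * 0
  rsid <- sprintf("rs%07d", sample.int(9999999, cfg$n_snps))
  alleles <- t(vapply(seq_len(cfg$n_snps),
                      function(i) sample(c("A", "C", "G", "T"), 2), character(2)))

  dosage <- sim_genotypes(cfg$n_families, fam_index, eaf)
  colnames(dosage) <- rsid
  rownames(dosage) <- person

  ## trait
  gs <- drop(dosage %*% beta)
  U <- stats::rnorm(n)
  ct <- cfg$confounder_effect[1]; ch <- cfg$confounder_effect[2]
  resid_sd <- sqrt(cfg$trait_sd^2 * (1 - cfg$gs_r2_target) - ct^2)
  intercept <- cfg$trait_mean - sum(beta * 2 * eaf)
  trait <- intercept + gs + ct * U + stats::rnorm(n, 0, resid_sd)

  ## event times: H(t) = (t/scale)^shape * exp(lp), inverted at Exp(1) draws
  bh <- resolve_baseline(cfg$baseline_hazard, cfg$horizon)
  lp <- cfg$causal_log_hr_per_unit * (trait - cfg$trait_mean) + ch * U
  shape <- vapply(bh, `[[`, numeric(1), "shape")[gene]
  scale <- vapply(bh, `[[`, numeric(1), "scale")[gene]
  t_event <- scale * (stats::rexp(n) * exp(-lp))^(1 / shape)

  ## competing censoring
  cz <- cfg$censoring
  age_fu <- rtnorm(n, cz$followup$mean, cz$followup$sd,
                   cz$followup$lo, cz$followup$hi)
  draw_cens <- function(spec) {
    age <- rtnorm(n, spec$mean, spec$sd, spec$lo, spec$hi)
    age[stats::runif(n) >= spec$frac] <- Inf
    age
  }
  age_rrso <- draw_cens(cz$rrso)
  age_bc <- draw_cens(cz$breast)
  age_death <- draw_cens(cz$death)

  exit_mat <- cbind(ovca = t_event, breast = age_bc, rrso = age_rrso,
                    death = age_death, followup = age_fu)
  exit_type <- colnames(exit_mat)[max.col(-exit_mat, ties.method = "first")]
  exit_age <- exit_mat[cbind(seq_len(n), max.col(-exit_mat,
                                                 ties.method = "first"))]
  case <- exit_type == "ovca"

  keep_if <- function(x, cond) ifelse(cond, x, NA_real_)
  age_ovca <- keep_if(t_event, case)
  age_breast <- keep_if(age_bc, exit_type == "breast")
  age_rrso_o <- keep_if(age_rrso, exit_type == "rrso")
  age_death_o <- keep_if(age_death, exit_type == "death")
  age_fu_o <- keep_if(age_fu, exit_type == "followup")

  ## menopause: natural age known unless masked; RRSO at exit contributes no
  ## postmenopausal person-time, so natural menopause drives the split
  md <- cfg$menopause_age_dist
  meno_age <- rtnorm(n, md$mean, md$sd, md$lo, md$hi)
  postmeno <- meno_age < exit_age
  meno_missing <- postmeno & stats::runif(n) < cfg$menopause_missing_fraction
  age_meno <- ifelse(postmeno & !meno_missing, meno_age, NA_real_)

  ## questionnaire-style covariates
  pcs <- matrix(stats::rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("pc", 1:8)))
  country <- sample(c("US", "UK", "NL", "FR", "DE", "PL", "AU", "CA"), n,
                    replace = TRUE,
                    prob = c(0.25, 0.18, 0.12, 0.1, 0.12, 0.08, 0.08, 0.07))
  birth_year <- sample(1925:1985, n, replace = TRUE)
  parity <- pmin(stats::rpois(n, 1.8), 8L)
  age_menarche <- pmin(pmax(round(stats::rnorm(n, 13, 1.5)), 9L), 18L)

  trait_obs <- trait
  trait_obs[stats::runif(n) < cfg$missing_trait_fraction] <- NA_real_
  other1 <- stats::rnorm(n, 25.3, 5.1)
  other2 <- other1 - abs(stats::rnorm(n, 4, 2))
  anthro <- switch(cfg$trait_name,
    height_cm = list(height_cm = trait_obs, bmi_now = pmax(other1, 15),
                     bmi_young = pmax(other2, 14)),
    bmi_now = list(height_cm = stats::rnorm(n, 164.8, 6.9),
                   bmi_now = trait_obs,
                   bmi_young = pmax(other2, 14)),
    bmi_young = list(height_cm = stats::rnorm(n, 164.8, 6.9),
                     bmi_now = pmax(other1, 15), bmi_young = trait_obs))

  histo <- rep(NA_character_, n)
  grade <- rep(NA_character_, n)
  idx_case <- which(case)
  has_path <- idx_case[stats::runif(length(idx_case)) < 0.45]
  histo[has_path] <- sample(
    c("serous", "mucinous", "endometrioid", "clear cell", "other"),
    length(has_path), replace = TRUE,
    prob = c(0.679, 0.015, 0.107, 0.013, 0.186))
  grade[has_path] <- sample(
    c("well", "moderate", "poor/undiff"), length(has_path),
    replace = TRUE, prob = c(0.046, 0.21, 0.744))

  pheno <- data.frame(person = person, family = family, gene = gene,
                      birth_year = birth_year, country = country,
                      pcs, case = case, age_ovca = age_ovca,
                      age_breast = age_breast, age_rrso = age_rrso_o,
                      age_death = age_death_o, age_end_followup = age_fu_o,
                      age_menopause_natural = age_meno,
                      postmenopausal = postmeno,
                      anthro,
                      parity = parity, age_menarche = age_menarche,
                      histology = histo, grade = grade,
                      stringsAsFactors = FALSE)

  snp_weights <- data.frame(rsid = rsid,
                            chrom = sample(1:22, cfg$n_snps, replace = TRUE),
                            pos = sample.int(2.4e8, cfg$n_snps),
                            effect_allele = alleles[, 1],
                            other_allele = alleles[, 2],
                            beta = beta, eaf = eaf,
                            info = stats::runif(cfg$n_snps, 0.5, 1),
                            stringsAsFactors = FALSE)

  truth <- list(seed = cfg$seed,
                trait_name = cfg$trait_name,
                trait_mean = cfg$trait_mean, trait_sd = cfg$trait_sd,
                gs_r2_target = cfg$gs_r2_target,
                causal_log_hr_per_unit = cfg$causal_log_hr_per_unit,
                confounder_effect = cfg$confounder_effect,
                baseline_hazard = bh, horizon = cfg$horizon,
                beta_xg = beta, eaf = eaf, rsid = rsid,
                resid_sd = resid_sd, intercept = intercept)

  out <- list(phenotypes = pheno,
              genotypes = list(person = person, rsid = rsid, dosage = dosage),
              snp_weights = snp_weights,
              incidence = incidence_from_truth(truth),
              truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic carrier cohort: %d women, %d families, %d variants\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$family)),
              length(x$genotypes$rsid)))
  cat(sprintf("  cases: %d (%.1f%%); trait '%s' observed for %d\n",
              sum(x$phenotypes$case),
              100 * mean(x$phenotypes$case),
              x$truth$trait_name,
              sum(!is.na(x$phenotypes[[x$truth$trait_name]]))))
  invisible(x)
}

#' Case-oversampled ascertainment
#'
#' Emulates clinic-based recruitment: families containing at least one case
#' are retained with probability `min(1, factor * p_base)`, case-free
#' families with probability `p_base`. Sampling operates on whole families,
#' preserving within-family clustering. `factor = 1` gives a uniform
#' subsample; large `factor` with small `p_base` retains essentially only
#' case families.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param factor Oversampling factor, `>= 1`.
#' @param p_base Retention probability for case-free families; default
#'   `1/factor` so case families are always kept.
#' @param seed Integer seed for the sampling.
#' @return A `"synthetic_cohort"` restricted to the sampled families.
#' @export
ascertain <- function(cohort, factor, p_base = 1 / factor, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"), factor >= 1,
            p_base > 0, p_base <= 1)
  ph <- cohort$phenotypes
  if (!any(ph$case)) stop_kinmr("ascertain: cohort contains no cases")
  set.seed(as.integer(seed))
  fam_case <- tapply(ph$case, ph$family, any)
  p_keep <- ifelse(fam_case, pmin(1, factor * p_base), p_base)
  keep_fam <- names(fam_case)[stats::runif(length(fam_case)) < p_keep]
  keep <- ph$family %in% keep_fam
  out <- cohort
  out$phenotypes <- ph[keep, , drop = FALSE]
  rownames(out$phenotypes) <- NULL
  out$genotypes$person <- cohort$genotypes$person[keep]
  out$genotypes$dosage <- cohort$genotypes$dosage[keep, , drop = FALSE]
  out$truth$ascertainment <- list(factor = factor, p_base = p_base,
                                  seed = as.integer(seed))
  out
}

#' Write a synthetic cohort to a directory of plain-text inputs
#'
#' Emits the four analysis inputs (phenotype, dosage, variant-weight, and
#' incidence tables as TSV) plus a JSON truth file, in the layouts the
#' loaders and [run_pipeline()] consume. The dosage TSV has a `person`
#' column followed by one column per rsID.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             dosages = file.path(dir, "dosages.tsv"),
             snp_weights = file.path(dir, "snp_weights.tsv"),
             incidence = file.path(dir, "incidence.tsv"),
             truth = file.path(dir, "truth.json"))
  wt <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$phenotypes, paths["phenotypes"])
  dos <- data.frame(person = cohort$genotypes$person,
                    cohort$genotypes$dosage, check.names = FALSE)
  wt(dos, paths["dosages"])
  wt(cohort$snp_weights, paths["snp_weights"])
  wt(cohort$incidence, paths["incidence"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a truth record written by [write_cohort()]
#' @param path Path to `truth.json`.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a phenotype table
#' @param path Path to a phenotype TSV.
#' @return Data frame, one row per woman.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(ph, c("person", "family", "gene", "case"), "phenotype table")
  ph$case <- as.logical(ph$case)
  if ("postmenopausal" %in% names(ph))
    ph$postmenopausal <- as.logical(ph$postmenopausal)
  ph
}

#' Read a dosage matrix
#' @param path Path to a dosage TSV (`person` column then one column per
#'   rsID).
#' @return `list(person, rsid, dosage)` with a numeric dosage matrix.
#' @export
read_dosages <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(d, "person", "dosage matrix")
  dosage <- as.matrix(d[, setdiff(names(d), "person"), drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- d$person
  list(person = d$person, rsid = colnames(dosage), dosage = dosage)
}

#' Read an age-banded incidence table
#' @param path Path to a TSV with columns `gene`, `age_lo`, `age_hi`,
#'   `prob`.
#' @return Data frame.
#' @export
read_incidence <- function(path) {
  inc <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(inc, c("gene", "age_lo", "age_hi", "prob"),
                  "incidence table")
  if (any(inc$prob <= 0 | inc$prob >= 1))
    stop_kinmr("incidence table probabilities must lie in (0,1)")
  inc
}
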