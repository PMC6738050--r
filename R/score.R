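# Polygenic-score construction and trait-unit scaling.
#
# A genetic score is the weighted sum of effect-allele dosages,
# GS = sum_i beta_XGi * SNP_i, under an additive model with no
# interactions. Raw scores live in weighted-sum units; a scaling model
# fitted among non-case carriers (ordinary least squares of the observed
# trait on the raw score) converts them to trait units (cm or kg/m^2).

#' Load a variant-weight table
#'
#' Reads the SNP panel (per-allele trait effects and metadata) and applies
#' the imputation-quality filter: rows with `info < min_quality` are
#' dropped, so quality exactly at the threshold is retained.
#'
#' @param path Path to a TSV with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `eaf`, `info`.
#' @param min_quality Minimum imputation quality, default 0.5.
#' @return Data frame of retained variants with attribute `n_dropped`.
#' @export
load_snp_weights <- function(path, min_quality = 0.5) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(w, c("rsid", "chrom", "pos", "effect_allele",
                       "other_allele", "beta", "eaf", "info"),
                  "variant-weight table")
  if (anyDuplicated(w$rsid))
    stop_kinmr("duplicate rsID(s) in weight table: %s",
               paste(unique(w$rsid[duplicated(w$rsid)]), collapse = ", "))
  bad <- !(w$effect_allele %in% c("A", "C", "G", "T")) |
    !(w$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop_kinmr("non-ACGT allele(s) for: %s",
               paste(w$rsid[bad], collapse = ", "))
  if (!all(is.finite(w$beta)))
    stop_kinmr("non-finite beta in weight table")
  keep <- w$info >= min_quality
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  message(sprintf("load_snp_weights: %d variant(s) dropped at info < %g, %d retained",
                  sum(!keep), min_quality, nrow(out)))
  out
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)

# Resolve the counted allele of each dosage column against the weight
# panel. Returns +1 (dosage counts the effect allele), -1 (counts the other
# allele; use 2 - dosage), or an error listing unresolvable variants.
# Palindromic A/T and C/G variants are rejected only when the allele
# frequency makes strand orientation genuinely ambiguous (EAF in
# [0.4, 0.6]).
align_alleles <- function(weights, dosage_alleles) {
  require_columns(dosage_alleles, c("rsid", "counted_allele", "other_allele"),
                  "dosage allele table")
  m <- match(weights$rsid, dosage_alleles$rsid)
  if (anyNA(m))
    stop_kinmr("dosage allele table lacks rsID(s): %s",
               paste(weights$rsid[is.na(m)], collapse = ", "))
  cnt <- dosage_alleles$counted_allele[m]
  oth <- dosage_alleles$other_allele[m]
  ea <- weights$effect_allele
  oa <- weights$other_allele
  palindromic <- ea == dna_complement(oa)
  ambiguous <- palindromic & weights$eaf >= 0.4 & weights$eaf <= 0.6
  sign <- rep(NA_real_, nrow(weights))
  sign[cnt == ea & oth == oa] <- 1
  sign[cnt == oa & oth == ea] <- -1
  flip_ok <- is.na(sign) & !palindromic
  sign[flip_ok & dna_complement(cnt) == ea & dna_complement(oth) == oa] <- 1
  sign[flip_ok & dna_complement(cnt) == oa & dna_complement(oth) == ea] <- -1
  sign[ambiguous] <- NA_real_
  if (anyNA(sign))
    stop_kinmr("unresolvable allele orientation for: %s",
               paste(weights$rsid[is.na(sign)], collapse = ", "))
  sign
}

#' Build raw weighted genetic scores
#'
#' `raw_score(person) = sum_i beta_i * dosage_i(person)` over the variant
#' panel, after orienting every dosage column to its effect allele. Missing
#' person-variant dosages are mean-imputed as `2 * EAF` from the weight
#' table.
#'
#' @param genotypes `list(person, rsid, dosage)` as returned by
#'   [read_dosages()] or found in a synthetic cohort.
#' @param weights Variant-weight data frame ([load_snp_weights()] layout).
#' @param dosage_alleles Optional data frame (`rsid`, `counted_allele`,
#'   `other_allele`) describing which allele each dosage column counts;
#'   when omitted, dosages are assumed already oriented to the effect
#'   allele.
#' @return Data frame with columns `person`, `raw`.
#' @export
build_raw_scores <- function(genotypes, weights, dosage_alleles = NULL) {
  m <- match(weights$rsid, genotypes$rsid)
  if (anyNA(m))
    stop_kinmr("dosage matrix lacks panel rsID(s): %s",
               paste(weights$rsid[is.na(m)], collapse = ", "))
  dos <- genotypes$dosage[, m, drop = FALSE]
  if (any(dos < 0 | dos > 2, na.rm = TRUE))
    stop_kinmr("dosages outside [0, 2]")
  if (!is.null(dosage_alleles)) {
    sgn <- align_alleles(weights, dosage_alleles)
    flip <- sgn < 0
    if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  }
  if (anyNA(dos)) {
    imp <- 2 * weights$eaf
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- imp[j]
  }
  data.frame(person = genotypes$person,
             raw = drop(dos %*% weights$beta),
             stringsAsFactors = FALSE)
}

#' Fit the trait-unit scaling model among non-case carriers
#'
#' Ordinary least squares of the observed trait on the raw score,
#' restricted to non-cases with both values present. The fitted intercept
#' and slope convert raw scores to trait units; R^2 is the fraction of
#' trait variation explained by the score.
#'
#' @param scores Data frame with `person`, `raw` ([build_raw_scores()]).
#' @param trait Named numeric vector of observed trait values (names are
#'   person ids) or a numeric vector aligned with `scores`.
#' @param non_case Logical vector aligned with `scores`: TRUE for non-case
#'   carriers.
#' @return List of class `"scaling_model"`: `beta0`, `beta1`, `r2`,
#'   `n_used`.
#' @export
fit_scaling <- function(scores, trait, non_case) {
  if (!is.null(names(trait))) trait <- trait[scores$person]
  stopifnot(length(trait) == nrow(scores),
            length(non_case) == nrow(scores))
  use <- non_case & !is.na(trait) & !is.na(scores$raw)
  if (sum(use) < 3)
    stop_kinmr("fit_scaling needs >= 3 non-case carriers with trait and score (got %d)",
               sum(use))
  x <- scores$raw[use]; y <- trait[use]
  if (stats::var(x) == 0)
    stop_kinmr("fit_scaling: raw scores have zero variance")
  fit <- stats::lm(y ~ x)
  out <- list(beta0 = unname(stats::coef(fit)[1]),
              beta1 = unname(stats::coef(fit)[2]),
              r2 = summary(fit)$r.squared,
              n_used = sum(use))
  class(out) <- "scaling_model"
  out
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("scaling model: trait = %.3f + %.3f * raw (R^2 = %.3f, n = %d non-cases)\n",
              x$beta0, x$beta1, x$r2, x$n_used))
  invisible(x)
}

#' Apply a scaling model to raw scores
#'
#' @param scores Data frame with `person`, `raw`.
#' @param model A `"scaling_model"`.
#' @return `scores` with an added `scaled` column (trait units), exactly
#'   `beta0 + beta1 * raw`.
#' @export
scale_scores <- function(scores, model) {
  stopifnot(inherits(model, "scaling_model"))
  scores$scaled <- model$beta0 + model$beta1 * scores$raw
  scores
}

#' Cross-trait association check for a scaled score
#'
#' Simple linear regression of a secondary trait on the scaled score; a
#' pleiotropy-inspection report with no decision logic attached.
#'
#' @param scaled Numeric vector of scaled scores.
#' @param other_trait Numeric vector of the secondary trait (NA allowed).
#' @return List with `slope`, `se`, `p`, `n`.
#' @export
cross_trait_check <- function(scaled, other_trait) {
  use <- !is.na(scaled) & !is.na(other_trait)
  x <- scaled[use]; y <- other_trait[use]
  if (length(y) < 3 || stats::var(y) == 0)
    stop_kinmr("cross_trait_check: secondary trait constant or too few values")
  fit <- summary(stats::lm(y ~ x))
  list(slope = unname(fit$coefficients["x", "Estimate"]),
       se = unname(fit$coefficients["x", "Std. Error"]),
       p = unname(fit$coefficients["x", "Pr(>|t|)"]),
       n = length(y))
}
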