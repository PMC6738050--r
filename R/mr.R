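# Per-variant outcome associations and their combination into causal
# estimates.
#
# Each variant's per-allele log hazard ratio beta_YG (with SE) comes from a
# weighted Cox fit; the combined causal effect per trait unit is the
# inverse-variance-weighted (IVW) estimator
#   beta_YX = sum_i beta_XGi * beta_YGi * SE(beta_YGi)^-2 /
#             sum_i beta_XGi^2 * SE(beta_YGi)^-2,
#   SE_YX   = sqrt(1 / sum_i beta_XGi^2 * SE(beta_YGi)^-2),
# equivalent to an SE^-2-weighted through-origin regression of beta_YG on
# beta_XG. Cochran Q / I^2 on the per-variant Wald ratios quantify
# heterogeneity; MR-Egger's intercept tests directional pleiotropy.

#' Per-variant outcome association scan
#'
#' One weighted Cox fit per variant: the dosage (counting the
#' trait-increasing allele) enters alongside the stated covariates, and the
#' per-allele log hazard ratio, robust SE, and Wald p are collected.
#' Variants whose fit fails, or with constant dosage, are flagged and
#' excluded from downstream combination.
#'
#' @param episodes Episode table ([split_episodes()]).
#' @param genotypes `list(person, rsid, dosage)`.
#' @param weights Variant panel data frame (`rsid`, `beta`, ...); `beta` is
#'   carried through as `beta_xg`.
#' @param covariates Adjustment terms for every per-variant model.
#' @param ... Passed to [fit_weighted_cox()].
#' @return Data frame (`rsid`, `beta_xg`, `beta_yg`, `se_yg`, `p`,
#'   `status`) with `status` one of `"ok"`, `"constant"`, `"failed"`.
#' @export
scan_snps <- function(episodes, genotypes, weights, covariates, ...) {
  idx <- match(episodes$person, genotypes$person)
  if (anyNA(idx))
    stop_kinmr("dosage matrix lacks %d episode person(s)", sum(is.na(idx)))
  out <- data.frame(rsid = weights$rsid, beta_xg = weights$beta,
                    beta_yg = NA_real_, se_yg = NA_real_, p = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(weights))) {
    j <- match(weights$rsid[i], genotypes$rsid)
    if (is.na(j)) { out$status[i] <- "failed"; next }
    dos <- genotypes$dosage[idx, j]
    if (length(unique(dos)) < 2) { out$status[i] <- "constant"; next }
    episodes$.dosage <- dos
    fit <- tryCatch(fit_weighted_cox(episodes, c(".dosage", covariates), ...),
                    error = function(e) NULL)
    if (is.null(fit)) { out$status[i] <- "failed"; next }
    k <- match(".dosage", fit$term)
    out$beta_yg[i] <- fit$coef[k]
    out$se_yg[i] <- fit$robust_se[k]
    out$p[i] <- fit$p[k]
  }
  n_bad <- sum(out$status != "ok")
  if (n_bad)
    message(sprintf("scan_snps: %d variant(s) flagged and excluded (%s)",
                    n_bad, paste(out$rsid[out$status != "ok"], collapse = ", ")))
  out
}

ok_assocs <- function(assocs) {
  a <- assocs[!is.na(assocs$beta_yg) & !is.na(assocs$se_yg), , drop = FALSE]
  if (!is.null(a$status)) a <- a[a$status == "ok", , drop = FALSE]
  if (any(a$se_yg <= 0)) stop_kinmr("non-positive se_yg in associations")
  a
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-variant associations into the causal log hazard ratio per
#' trait unit using the IVW formulas, with Cochran Q / I^2 heterogeneity
#' diagnostics attached from [heterogeneity()] (when at least two variants
#' are available).
#'
#' @param assocs Data frame with `beta_xg`, `beta_yg`, `se_yg` (e.g. from
#'   [scan_snps()]).
#' @return List of class `"ivw_estimate"`: `beta_yx`, `se_yx`, `p`, `k`
#'   (variants used), `q`, `i2`.
#' @export
ivw_estimate <- function(assocs) {
  a <- ok_assocs(assocs)
  if (nrow(a) < 1) stop_kinmr("ivw_estimate needs >= 1 association")
  if (all(a$beta_xg == 0))
    stop_kinmr("ivw_estimate undefined: all trait effects are zero")
  w <- a$se_yg^-2
  beta_yx <- sum(a$beta_xg * a$beta_yg * w) / sum(a$beta_xg^2 * w)
  se_yx <- sqrt(1 / sum(a$beta_xg^2 * w))
  het <- if (nrow(a) >= 2) heterogeneity(a) else list(q = NA_real_,
                                                      i2 = NA_real_)
  out <- list(beta_yx = beta_yx, se_yx = se_yx,
              p = wald_p(beta_yx, se_yx), k = nrow(a),
              q = het$q, i2 = het$i2)
  class(out) <- "ivw_estimate"
  out
}

#' @export
print.ivw_estimate <- function(x, ...) {
  cat(sprintf("IVW causal estimate: beta = %.4f (SE %.4f, p = %.3g) from %d variants\n",
              x$beta_yx, x$se_yx, x$p, x$k))
  if (!is.na(x$i2))
    cat(sprintf("  heterogeneity: Q = %.2f on %d df, I^2 = %.1f%%\n",
                x$q, x$k - 1, 100 * x$i2))
  invisible(x)
}

#' Cochran Q and I-squared across per-variant causal ratios
#'
#' Q is computed on the per-variant Wald ratios `beta_yg / beta_xg` with
#' first-order SEs `se_yg / |beta_xg|` about the IVW estimate;
#' `I^2 = max(0, (Q - (k - 1)) / Q)`.
#'
#' @param assocs Data frame with `beta_xg`, `beta_yg`, `se_yg`.
#' @return List with `q`, `i2`, `df`.
#' @export
heterogeneity <- function(assocs) {
  a <- ok_assocs(assocs)
  if (nrow(a) < 2) stop_kinmr("heterogeneity needs >= 2 associations")
  if (any(a$beta_xg == 0))
    stop_kinmr("heterogeneity: zero trait effect makes a Wald ratio undefined")
  ratio <- a$beta_yg / a$beta_xg
  se_r <- a$se_yg / abs(a$beta_xg)
  w <- se_r^-2
  center <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - center)^2)
  i2 <- max(0, (q - (nrow(a) - 1)) / q)
  if (q == 0) i2 <- 0
  list(q = q, i2 = i2, df = nrow(a) - 1)
}

#' MR-Egger regression
#'
#' SE^-2-weighted linear regression of `beta_yg` on `beta_xg` with a free
#' intercept, after orienting all trait effects non-negative (flipping
#' `beta_yg` with `beta_xg`). A non-zero intercept indicates directional
#' pleiotropy; its p-value is a normal-approximation Wald test.
#'
#' @param assocs Data frame with `beta_xg`, `beta_yg`, `se_yg` for at least
#'   3 variants with variation in `beta_xg`.
#' @return List with `intercept`, `intercept_se`, `intercept_p`, `slope`,
#'   `slope_se`, `k`.
#' @export
egger_test <- function(assocs) {
  a <- ok_assocs(assocs)
  if (nrow(a) < 3) stop_kinmr("egger_test needs >= 3 associations")
  flip <- a$beta_xg < 0
  a$beta_yg[flip] <- -a$beta_yg[flip]
  a$beta_xg[flip] <- -a$beta_xg[flip]
  if (stats::var(a$beta_xg) == 0)
    stop_kinmr("egger_test: no variation in trait effects")
  w <- a$se_yg^-2
  fit <- stats::lm(beta_yg ~ beta_xg, data = a, weights = w)
  # weighted least squares with known per-point variances: drop the
  # residual-variance scaling of lm's covariance (fixed-effect convention)
  V <- summary(fit)$cov.unscaled
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  list(intercept = unname(est[1]), intercept_se = unname(se[1]),
       intercept_p = wald_p(est[1], se[1]),
       slope = unname(est[2]), slope_se = unname(se[2]),
       k = nrow(a))
}

#' Rescale a per-SD causal effect to conventional reporting units
#'
#' `HR = exp(beta_per_sd * k / trait_sd)`: a log hazard ratio per z-score
#' of the trait (SD taken among unaffected carriers) re-expressed per `k`
#' trait units, e.g. per 10 cm or per 5 kg/m^2.
#'
#' @param beta_per_sd Log hazard ratio per trait SD.
#' @param trait_sd Trait SD among controls, `> 0`.
#' @param k Reporting multiple in trait units.
#' @return Hazard ratio per `k` units.
#' @export
rescale_per_sd <- function(beta_per_sd, trait_sd, k) {
  if (trait_sd <= 0) stop_kinmr("rescale_per_sd: trait_sd must be positive")
  exp(beta_per_sd * k / trait_sd)
}

#' Count nominal and multiplicity-corrected association hits
#'
#' @param assocs Data frame with a `p` column (NA rows ignored).
#' @param alpha Nominal level, default 0.05.
#' @param bonferroni Also count hits at `alpha / k`, default TRUE.
#' @return List with `k`, `n_nominal`, `nominal_rsids`, and (when
#'   requested) `n_bonferroni`, `bonferroni_rsids`.
#' @export
count_nominal_hits <- function(assocs, alpha = 0.05, bonferroni = TRUE) {
  p <- assocs$p[!is.na(assocs$p)]
  ids <- if (!is.null(assocs$rsid)) assocs$rsid[!is.na(assocs$p)]
         else as.character(seq_along(p))
  out <- list(k = length(p),
              n_nominal = sum(p < alpha),
              nominal_rsids = ids[p < alpha])
  if (bonferroni) {
    thr <- alpha / length(p)
    out$n_bonferroni <- sum(p < thr)
    out$bonferroni_rsids <- ids[p < thr]
  }
  out
}
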