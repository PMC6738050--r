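# Two-stage residual inclusion (TSRI) instrumental-variable estimation.
#
# Stage one regresses the observed trait on its genetic score and baseline
# covariates; stage two fits a weighted Cox model for the outcome against
# the observed trait, the same covariates, and the stage-one residual (the
# control function). The stage-two trait coefficient is the causal log
# hazard ratio per trait unit. Uncertainty comes from a family-level
# percentile bootstrap, consistent with the family-clustered sandwich
# variance used elsewhere.

#' Two-stage residual-inclusion point estimate
#'
#' @param pheno Phenotype table restricted implicitly to women with the
#'   trait, score, and covariates observed (rows with missing values are
#'   dropped).
#' @param scores Data frame `person`, `raw`, `scaled`
#'   ([build_raw_scores()] + [scale_scores()]); stage one uses the scaled
#'   score as instrument.
#' @param trait_col Trait column of `pheno` (e.g. `"height_cm"`).
#' @param covariates Baseline adjustment terms for both stages (no
#'   time-varying terms in stage one).
#' @param weights Optional `person`/`weight` data frame; stage two uses
#'   the same ascertainment weights as the main survival models by
#'   default (`use_weights = FALSE` switches them off).
#' @param menopause_imputation_age Passed to [split_episodes()].
#' @param use_weights Apply `weights` in stage two, default TRUE.
#' @param min_n Minimum analysable sample size, default 50.
#' @param ... Passed to [fit_weighted_cox()].
#' @return List of class `"tsri_result"`: `estimate` (causal log HR per
#'   trait unit), `naive_se`, `stage1` (coefficients, `f_stat`, `r2`,
#'   `n`), `stage2` (the `"cox_result"`), `n`.
#' @export
tsri_fit <- function(pheno, scores, trait_col, covariates = character(0),
                     weights = NULL, menopause_imputation_age = 50,
                     use_weights = TRUE, min_n = 50, ...) {
  m <- match(pheno$person, scores$person)
  if (anyNA(m)) stop_kinmr("scores missing for %d person(s)", sum(is.na(m)))
  pheno$.gs <- scores$scaled[m]
  keep <- !is.na(pheno[[trait_col]]) & !is.na(pheno$.gs)
  for (cv in covariates) keep <- keep & !is.na(pheno[[cv]])
  pheno <- pheno[keep, , drop = FALSE]
  if (nrow(pheno) < min_n)
    stop_kinmr("tsri_fit: only %d analysable women (< %d)", nrow(pheno),
               min_n)
  if (stats::var(pheno$.gs) == 0)
    stop_kinmr("tsri_fit: genetic score is constant (degenerate instrument)")

  ## stage 1: trait on instrument + baseline covariates
  s1_terms <- c(".gs", covariates)
  f1 <- stats::as.formula(paste(trait_col, "~",
                                paste(s1_terms, collapse = " + ")))
  s1 <- stats::lm(f1, data = pheno)
  s1_sum <- summary(s1)
  gs_row <- match(".gs", rownames(s1_sum$coefficients))
  f_stat <- s1_sum$coefficients[gs_row, "t value"]^2
  if (s1_sum$coefficients[gs_row, "Estimate"] == 0 || !is.finite(f_stat))
    stop_kinmr("tsri_fit: instrument explains no trait variance")
  pheno$.s1_resid <- stats::resid(s1)
  # a noiseless first stage leaves nothing to include; stage 2 then reduces
  # to the plain Cox fit on the observed trait
  resid_dropped <- stats::sd(pheno$.s1_resid) < 1e-10 * max(1, stats::sd(pheno[[trait_col]]))

  ## stage 2: weighted Cox on trait + residual + covariates
  episodes <- split_episodes(pheno, menopause_imputation_age,
                             weights = if (use_weights) weights else NULL)
  s2_terms <- if (resid_dropped) c(trait_col, covariates)
              else c(trait_col, ".s1_resid", covariates)
  fit2 <- fit_weighted_cox(episodes, s2_terms, ...)
  i <- match(trait_col, fit2$term)
  out <- list(estimate = fit2$coef[i],
              naive_se = fit2$naive_se[i],
              robust_se = fit2$robust_se[i],
              stage1 = list(coef = stats::coef(s1), f_stat = f_stat,
                            r2 = s1_sum$r.squared, n = nrow(pheno)),
              stage2 = fit2,
              resid_dropped = resid_dropped,
              n = nrow(pheno))
  class(out) <- "tsri_result"
  out
}

#' @export
print.tsri_result <- function(x, ...) {
  cat(sprintf("TSRI estimate: %.4f log HR per trait unit (naive SE %.4f, n = %d)\n",
              x$estimate, x$naive_se, x$n))
  cat(sprintf("  stage-1 instrument F = %.1f, R^2 = %.3f\n",
              x$stage1$f_stat, x$stage1$r2))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap %d reps: SD %.4f, 95%% CI [%.4f, %.4f]\n",
                x$B, x$boot_sd, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Family-level bootstrap confidence interval for the TSRI estimate
#'
#' Families are resampled with replacement (all members kept, resampled
#' families treated as new clusters); both stages are refitted per
#' replicate; the percentile 2.5/97.5 interval and replicate SD are
#' returned. Replicate-level failures are tolerated up to 10%.
#'
#' @param pheno,scores,trait_col,covariates,weights,menopause_imputation_age,use_weights,min_n,...
#'   As [tsri_fit()].
#' @param ties Tie handling for the stage-2 fits.
#' @param B Number of bootstrap replicates, `>= 2`.
#' @param seed Integer seed; the same seed reproduces the interval
#'   exactly.
#' @return The [tsri_fit()] result augmented with `ci`, `boot_sd`, `B`,
#'   `n_failed`, `seed`, `replicates`.
#' @export
bootstrap_ci <- function(pheno, scores, trait_col,
                         covariates = character(0), weights = NULL,
                         B = 10000, seed = 1L,
                         menopause_imputation_age = 50,
                         use_weights = TRUE, min_n = 50,
                         ties = c("efron", "breslow"), ...) {
  stopifnot(B >= 2)
  ties <- match.arg(ties)
  point <- tsri_fit(pheno, scores, trait_col, covariates,
                    weights = weights,
                    menopause_imputation_age = menopause_imputation_age,
                    use_weights = use_weights, min_n = min_n,
                    ties = ties, ...)

  ## precompute the analysable person-level design and its episode
  ## expansion once; replicates only reindex rows by family
  m <- match(pheno$person, scores$person)
  pheno$.gs <- scores$scaled[m]
  keep <- !is.na(pheno[[trait_col]]) & !is.na(pheno$.gs)
  for (cv in covariates) keep <- keep & !is.na(pheno[[cv]])
  ph <- pheno[keep, , drop = FALSE]
  ep <- split_episodes(ph, menopause_imputation_age,
                       weights = if (use_weights) weights else NULL)
  X1 <- stats::model.matrix(
    stats::as.formula(paste("~ .gs +",
                            paste(c(covariates, "1"), collapse = " + "))),
    data = ph)
  y1 <- ph[[trait_col]]
  X2 <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c(trait_col, covariates, "1"),
                                       collapse = " + "))),
    data = ep)[, -1, drop = FALSE]
  ep_person <- match(ep$person, ph$person)

  fam <- factor(ph$family)
  fam_rows <- split(seq_len(nrow(ph)), fam)
  ep_fam_rows <- split(seq_len(nrow(ep)), factor(ep$family, levels(fam)))
  n_fam <- length(fam_rows)
  surv2 <- survival::Surv(ep$start, ep$stop, ep$event)
  w2 <- ep$weight

  one_rep <- function(draw) {
    r1 <- unlist(fam_rows[draw], use.names = FALSE)
    b1 <- stats::lm.fit(X1[r1, , drop = FALSE], y1[r1])$coefficients
    b1[is.na(b1)] <- 0
    resid_all <- y1 - drop(X1 %*% b1)  # residuals under replicate fit
    r2 <- unlist(ep_fam_rows[draw], use.names = FALSE)
    Z <- cbind(X2[r2, , drop = FALSE], .s1_resid = resid_all[ep_person[r2]])
    fit <- survival::coxph(surv2[r2] ~ Z, weights = w2[r2], ties = ties,
                           robust = FALSE)
    unname(stats::coef(fit)[1])
  }
  set.seed(as.integer(seed))
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    draw <- sample.int(n_fam, n_fam, replace = TRUE)
    est[b] <- tryCatch(suppressWarnings(one_rep(draw)),
                       error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(est))
  if (n_failed > 0.1 * B)
    stop_kinmr("bootstrap_ci: %d of %d replicates failed", n_failed, B)
  good <- est[!is.na(est)]
  # type = 1 (inverse empirical CDF): with B = 2 the interval is exactly
  # the ordered pair of replicate estimates
  point$ci <- unname(stats::quantile(good, c(0.025, 0.975), type = 1))
  point$boot_sd <- stats::sd(good)
  point$B <- B
  point$n_failed <- n_failed
  point$seed <- as.integer(seed)
  point$replicates <- est
  point
}
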