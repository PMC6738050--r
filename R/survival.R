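# Ascertainment-weighted Cox modelling on the age timescale.
#
# Carriers enter the risk set at birth and exit at the first of ovarian
# cancer diagnosis (the event), breast cancer diagnosis, risk-reducing
# bilateral salpingo-oophorectomy, death, or end of follow-up. Clinic-based
# recruitment oversamples affected families, so case/non-case weights are
# calibrated per gene and exit-age band against external incidence
# (kin-cohort weighting). Menopausal status is a time-varying covariate via
# counting-process episode splitting; robust sandwich variance aggregates
# score residuals within families.

exit_age_cols <- c("age_ovca", "age_breast", "age_rrso", "age_death",
                   "age_end_followup")

# Exit age, exit cause, and event flag per person. The event is ovarian
# cancer only; everything else censors.
exit_summary <- function(pheno) {
  present <- intersect(exit_age_cols, names(pheno))
  if (!length(present)) stop_kinmr("phenotype table has no exit-age columns")
  mat <- as.matrix(pheno[present])
  mat[is.na(mat)] <- Inf
  j <- max.col(-mat, ties.method = "first")
  exit_age <- mat[cbind(seq_len(nrow(mat)), j)]
  if (any(!is.finite(exit_age)))
    stop_kinmr("%d person(s) have no exit age", sum(!is.finite(exit_age)))
  if (any(exit_age <= 0 | exit_age >= 110))
    stop_kinmr("exit ages must lie in (0, 110)")
  event <- present[j] == "age_ovca" & !is.na(pheno$age_ovca)
  data.frame(person = pheno$person, exit_age = exit_age, event = event,
             stringsAsFactors = FALSE)
}

#' Kin-cohort ascertainment weights
#'
#' Within each stratum of gene and exit-age band, cases receive weight
#' `p_exp / p_obs` and non-cases `(1 - p_exp) / (1 - p_obs)`, where `p_obs`
#' is the observed case fraction in the stratum and `p_exp` the expected
#' fraction under the external incidence table, so the weighted case
#' fraction equals `p_exp` exactly. Sparse strata (fewer than
#' `min_stratum` women, or an observed case fraction of 0 or 1) are merged
#' into the next older band of the same gene, with merges reported via
#' `message()`.
#'
#' @param pheno Phenotype table (see [simulate_cohort()] /
#'   [read_phenotypes()]).
#' @param incidence Incidence table (`gene`, `age_lo`, `age_hi`, `prob`):
#'   probability of a first event in the band given event-free at its
#'   start.
#' @param band_width Exit-age band width in years, default 5.
#' @param min_stratum Minimum women per stratum before merging, default 10.
#' @return Data frame `person`, `weight` (all `> 0`), with attribute
#'   `strata` describing each final stratum.
#' @export
build_weights <- function(pheno, incidence, band_width = 5,
                          min_stratum = 10) {
  ex <- exit_summary(pheno)
  genes <- unique(pheno$gene)
  if (!all(genes %in% incidence$gene))
    stop_kinmr("incidence table lacks gene(s): %s",
               paste(setdiff(genes, incidence$gene), collapse = ", "))

  lo_all <- min(incidence$age_lo)
  hi_all <- max(incidence$age_hi)
  breaks <- seq(lo_all, hi_all, by = band_width)
  if (breaks[length(breaks)] < hi_all) breaks <- c(breaks, hi_all)
  # clamp exits outside the table's range into its first/last band
  age <- pmin(pmax(ex$exit_age, lo_all + 1e-9), hi_all - 1e-9)
  band <- cut(age, breaks, right = FALSE, labels = FALSE)

  # expected fraction for [a,b): compose table bands, conditional on
  # event-free at a
  p_exp_band <- function(g, a, b) {
    rows <- incidence[incidence$gene == g & incidence$age_hi > a &
                        incidence$age_lo < b, , drop = FALSE]
    if (!nrow(rows)) stop_kinmr("incidence table does not cover [%g, %g)", a, b)
    1 - prod(1 - rows$prob)
  }

  weight <- rep(NA_real_, nrow(pheno))
  strata_log <- list()
  for (g in genes) {
    in_g <- pheno$gene == g
    # merge sparse/degenerate bands upward (into the next older band);
    # a trailing sparse band merges downward
    groups <- list()
    pending <- integer(0)
    for (b in seq_len(length(breaks) - 1)) {
      idx <- which(in_g & band == b)
      pending <- c(pending, idx)
      n <- length(pending)
      if (n == 0) next
      p_obs <- mean(ex$event[pending])
      if (n >= min_stratum && p_obs > 0 && p_obs < 1) {
        groups[[length(groups) + 1]] <-
          list(idx = pending, lo = breaks[b + 1 - 1], hi = breaks[b + 1])
        pending <- integer(0)
      }
    }
    if (length(pending)) {
      if (!length(groups))
        stop_kinmr("gene %s: no stratum with both cases and non-cases", g)
      g_last <- groups[[length(groups)]]
      message(sprintf("build_weights: %s merged trailing sparse band (%d women) downward",
                      g, length(pending)))
      g_last$idx <- c(g_last$idx, pending)
      groups[[length(groups)]] <- g_last
    }
    for (grp in groups) {
      idx <- grp$idx
      a <- min(breaks[band[idx]])
      b <- max(breaks[band[idx] + 1])
      p_obs <- mean(ex$event[idx])
      p_exp <- p_exp_band(g, a, b)
      weight[idx] <- ifelse(ex$event[idx], p_exp / p_obs,
                            (1 - p_exp) / (1 - p_obs))
      strata_log[[length(strata_log) + 1]] <-
        data.frame(gene = g, age_lo = a, age_hi = b, n = length(idx),
                   p_obs = p_obs, p_exp = p_exp)
    }
  }
  stopifnot(!anyNA(weight), all(weight > 0))
  out <- data.frame(person = pheno$person, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "strata") <- do.call(rbind, strata_log)
  out
}

#' Expand carriers into counting-process episodes
#'
#' One or two `(start, stop]` rows per woman on the age timescale, entering
#' at birth (age 0). Women who reach menopause before exit contribute a
#' premenopausal row `[0, m)` and a postmenopausal row `[m, exit)`; the
#' split age `m` is the age at natural menopause or, when postmenopausal
#' status is known but the age missing, `menopause_imputation_age`.
#' Menopause at or after exit yields a single premenopausal row. The event
#' flag sits on the final row only.
#'
#' @param pheno Phenotype table.
#' @param menopause_imputation_age Imputation age in years, default 50
#'   (46 as a sensitivity alternative).
#' @param weights Optional data frame `person`, `weight`
#'   ([build_weights()]); defaults to weight 1.
#' @return Data frame with `person`, `family`, `start`, `stop`, `event`,
#'   `postmeno`, `weight`, plus all phenotype covariate columns and a
#'   `birth_decade` factor.
#' @export
split_episodes <- function(pheno, menopause_imputation_age = 50,
                           weights = NULL) {
  ex <- exit_summary(pheno)
  m <- pheno$age_menopause_natural
  if (is.null(m)) m <- rep(NA_real_, nrow(pheno))
  post_flag <- pheno$postmenopausal %||% rep(FALSE, nrow(pheno))
  post_flag[is.na(post_flag)] <- FALSE
  m[is.na(m) & post_flag] <- menopause_imputation_age
  split <- !is.na(m) & m > 0 & m < ex$exit_age

  w <- rep(1, nrow(pheno))
  if (!is.null(weights)) {
    mw <- match(pheno$person, weights$person)
    if (anyNA(mw)) stop_kinmr("weights missing for some persons")
    w <- weights$weight[mw]
  }

  covar_cols <- setdiff(names(pheno), c(exit_age_cols))
  base <- pheno[covar_cols]
  base$birth_decade <- factor(10 * (pheno$birth_year %/% 10))

  pre <- cbind(base,
               start = 0,
               stop = ifelse(split, m, ex$exit_age),
               event = ifelse(split, FALSE, ex$event),
               postmeno = 0,
               weight = w)
  out <- pre
  if (any(split)) {
    post <- cbind(base[split, , drop = FALSE],
                  start = m[split],
                  stop = ex$exit_age[split],
                  event = ex$event[split],
                  postmeno = 1,
                  weight = w[split])
    out <- rbind(pre, post)
  }
  out <- out[order(match(out$person, pheno$person), out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$stop <= out$start))
    stop_kinmr("negative or empty episode span produced")
  out
}

#' Fit a weighted Cox model with family-clustered robust variance
#'
#' Maximises the weighted Cox partial likelihood on the age timescale
#' (left-truncated `(start, stop]` risk sets) via [survival::coxph()], with
#' the sandwich variance aggregating score residuals within clusters.
#'
#' @param episodes Episode table from [split_episodes()].
#' @param covariates Character vector of covariate terms (columns of
#'   `episodes`, e.g. `c("height_cm", "pc1", "country")`).
#' @param cluster_col Cluster column for the robust variance, default
#'   `"family"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights_col Weight column, default `"weight"`; `NULL` for
#'   unweighted.
#' @return Object of class `"cox_result"`: per-term `coef`, `robust_se`,
#'   `naive_se`, `hr`, `ci_lo`, `ci_hi`, `p` (robust Wald), plus `n`,
#'   `n_events`, `ties`, `loglik`, `converged`.
#' @export
fit_weighted_cox <- function(episodes, covariates,
                             cluster_col = "family",
                             ties = c("efron", "breslow"),
                             weights_col = "weight") {
  ties <- match.arg(ties)
  miss <- setdiff(covariates, names(episodes))
  if (length(miss))
    stop_kinmr("episode table lacks covariate(s): %s",
               paste(miss, collapse = ", "))
  if (sum(episodes$event) < 1) stop_kinmr("no events in episode table")

  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = episodes)
  if (qr(mm, tol = 1e-10)$rank < ncol(mm))
    stop_kinmr("collinear covariate specification: %s",
               paste(covariates, collapse = ", "))

  w <- if (is.null(weights_col)) rep(1, nrow(episodes))
       else episodes[[weights_col]]
  cl <- episodes[[cluster_col]]
  f <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~",
    paste(covariates, collapse = " + ")))
  env <- new.env(parent = environment())
  assign("w", w, env); assign("cl", cl, env)
  environment(f) <- env
  fit <- withCallingHandlers(
    survival::coxph(f, data = episodes, weights = w, cluster = cl,
                    ties = ties, robust = TRUE, model = FALSE,
                    x = FALSE, y = FALSE),
    warning = function(cnd) {
      if (grepl("did not converge", conditionMessage(cnd)))
        stop_kinmr("coxph failed: %s", conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop_kinmr("coxph produced NA coefficient(s)")
  # monotone likelihood is fatal for the leading (exposure) term; a
  # runaway nuisance dummy (a factor level with no events in a subgroup)
  # is flagged in the result but tolerated
  diverged <- names(cf)[abs(cf) > 15]
  lead <- startsWith(names(cf), covariates[1])
  if (any(abs(cf[lead]) > 15))
    stop_kinmr("apparent separation (|coef| > 15) in '%s'", covariates[1])
  rse <- sqrt(diag(fit$var))
  nse <- sqrt(diag(fit$naive.var %||% fit$var))
  z <- cf / rse
  res <- list(term = names(cf), coef = unname(cf),
              robust_se = unname(rse), naive_se = unname(nse),
              hr = exp(unname(cf)),
              ci_lo = exp(unname(cf) - 1.96 * unname(rse)),
              ci_hi = exp(unname(cf) + 1.96 * unname(rse)),
              p = unname(2 * stats::pnorm(-abs(z))),
              n = length(unique(episodes$person)),
              n_events = sum(episodes$event),
              ties = ties,
              loglik = unname(fit$loglik[length(fit$loglik)]),
              diverged_terms = diverged,
              converged = fit$iter < 100)
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  df <- data.frame(term = x$term, coef = x$coef, robust_se = x$robust_se,
                   HR = x$hr, ci_lo = x$ci_lo, ci_hi = x$ci_hi, p = x$p)
  cat(sprintf("weighted Cox fit: %d women, %d events (ties = %s)\n",
              x$n, x$n_events, x$ties))
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Two-sided Wald p-value
#'
#' `p = 2 * (1 - Phi(|coef| / se))` under the standard normal.
#'
#' @param coef Log hazard ratio.
#' @param se Standard error, `> 0`.
#' @return p-value in `(0, 1]`.
#' @export
wald_p <- function(coef, se) {
  if (any(se <= 0)) stop_kinmr("wald_p: standard error must be positive")
  2 * stats::pnorm(-abs(coef / se))
}

#' Report a fitted term per k trait units
#'
#' Hazard ratios are conventionally reported per 10 cm of height or per
#' 5 kg/m^2 of BMI; this rescales a per-unit coefficient accordingly.
#'
#' @param result A `"cox_result"`.
#' @param term Term name.
#' @param k Reporting multiple in trait units.
#' @return List with `log_hr`, `se`, `hr`, `ci_lo`, `ci_hi`, `p` on the
#'   per-k-units scale.
#' @export
hr_per_k <- function(result, term, k) {
  i <- match(term, result$term)
  if (is.na(i)) stop_kinmr("term '%s' not in fit", term)
  b <- k * result$coef[i]; s <- k * result$robust_se[i]
  list(log_hr = b, se = s, hr = exp(b),
       ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
       p = wald_p(b, s))
}

#' Exposure-by-modifier interaction test
#'
#' Adds the product term to the model; the interaction p is the robust
#' Wald p of the product coefficient. With a time-varying menopausal
#' modifier this is essentially a test of proportional hazards for the
#' exposure across the menopausal transition.
#'
#' @param episodes Episode table.
#' @param exposure,modifier Numeric covariate columns.
#' @param covariates Additional adjustment terms.
#' @param ... Passed to [fit_weighted_cox()].
#' @return List with `fit` (the `"cox_result"`) and `p_interaction`.
#' @export
interaction_test <- function(episodes, exposure, modifier,
                             covariates = character(0), ...) {
  if (length(unique(episodes[[modifier]])) < 2)
    stop_kinmr("modifier '%s' is constant", modifier)
  inter <- paste0(exposure, "_x_", modifier)
  episodes[[inter]] <- episodes[[exposure]] * episodes[[modifier]]
  fit <- fit_weighted_cox(episodes,
                          c(exposure, modifier, inter, covariates), ...)
  list(fit = fit, p_interaction = fit$p[match(inter, fit$term)])
}

#' Subtype-specific fits with a heterogeneity test
#'
#' For each tumour class, cases of the complementary class are treated as
#' censored at their diagnosis age (their exit age is unchanged; only the
#' event flag is dropped), and the model is refitted. Classes without
#' events are reported absent. The between-class heterogeneity p is a
#' two-sample Wald test on the difference of the class coefficients using
#' robust SEs under an independence approximation.
#'
#' @param episodes Episode table carrying the class label column.
#' @param exposure Exposure term whose coefficient is compared.
#' @param class_col Label column (e.g. `"histology"` or `"grade"`).
#' @param classes Named list mapping class name to the label values it
#'   contains, e.g. `list(serous = "serous", non_serous = c("mucinous",
#'   "endometrioid", "clear cell", "other"))`.
#' @param covariates Additional adjustment terms.
#' @param ... Passed to [fit_weighted_cox()].
#' @return List with per-class `"cox_result"`s (or `NULL` when a class has
#'   no events) and `p_het` (`NA` when fewer than two classes were
#'   fitted).
#' @export
subtype_analysis <- function(episodes, exposure, class_col, classes,
                             covariates = character(0), ...) {
  fits <- lapply(classes, function(values) {
    ep <- episodes
    ep$event <- ep$event & ep[[class_col]] %in% values
    if (sum(ep$event) < 1) return(NULL)
    fit_weighted_cox(ep, c(exposure, covariates), ...)
  })
  ok <- !vapply(fits, is.null, logical(1))
  p_het <- NA_real_
  if (sum(ok) >= 2) {
    two <- which(ok)[1:2]
    b <- vapply(fits[two], function(f) f$coef[match(exposure, f$term)],
                numeric(1))
    s <- vapply(fits[two], function(f) f$robust_se[match(exposure, f$term)],
                numeric(1))
    p_het <- wald_p(b[1] - b[2], sqrt(sum(s^2)))
  }
  c(fits, list(p_het = p_het))
}
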