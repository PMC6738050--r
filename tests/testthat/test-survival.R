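toy_pheno <- function(case, exit, gene = "BRCA1", meno = NA_real_,
                      post = FALSE) {
  n <- length(case)
  data.frame(person = paste0("P", seq_len(n)),
             family = paste0("F", seq_len(n)),
             gene = gene, birth_year = 1950,
             case = case,
             age_ovca = ifelse(case, exit, NA_real_),
             age_end_followup = ifelse(case, NA_real_, exit),
             age_menopause_natural = meno,
             postmenopausal = post,
             stringsAsFactors = FALSE)
}

test_that("calibrated weights reproduce the expected case fractions", {
  inc <- data.frame(gene = "BRCA1", age_lo = c(20, 40, 60),
                    age_hi = c(40, 60, 80), prob = c(0.1, 0.2, 0.3))
  # one stratum per band, chosen observed fractions
  ph <- toy_pheno(case = rep(c(TRUE, FALSE), times = c(15, 15)),
                  exit = c(rep(30, 10), rep(50, 5),
                           rep(30, 10), rep(50, 5)))
  w <- build_weights(ph, inc, band_width = 20, min_stratum = 2)
  # stratum [20,40): p_obs = 10/20 = 0.5, p_exp = 0.1 -> weights 0.2 / 1.8
  expect_equal(w$weight[c(1, 16)], c(0.1 / 0.5, 0.9 / 0.5),
               tolerance = 1e-12)
  # weighted case fraction equals p_exp exactly within each stratum
  exit <- ifelse(ph$case, ph$age_ovca, ph$age_end_followup)
  for (band in list(c(20, 40), c(40, 60))) {
    in_b <- exit >= band[1] & exit < band[2]
    p_exp <- inc$prob[inc$age_lo == band[1]]
    expect_equal(sum(w$weight[in_b & ph$case]) / sum(w$weight[in_b]),
                 p_exp, tolerance = 1e-12)
  }
})

test_that("weights are unity when observed fractions match expectation", {
  inc <- data.frame(gene = "BRCA1", age_lo = 20, age_hi = 80, prob = 0.25)
  ph <- toy_pheno(case = rep(c(TRUE, FALSE), times = c(5, 15)),
                  exit = rep(50, 20))
  w <- build_weights(ph, inc, band_width = 60, min_stratum = 2)
  expect_equal(w$weight, rep(1, 20), tolerance = 1e-12)
})

test_that("sparse and degenerate strata are merged with a report", {
  inc <- data.frame(gene = "BRCA1", age_lo = c(20, 50), age_hi = c(50, 80),
                    prob = c(0.15, 0.2))
  # young band has cases only: would give p_obs = 1 -> merged upward
  ph <- toy_pheno(case = c(rep(TRUE, 3), rep(c(TRUE, FALSE), c(4, 13))),
                  exit = c(rep(30, 3), rep(60, 17)))
  expect_message(w <- build_weights(ph, inc, band_width = 30,
                                    min_stratum = 5), NA)
  expect_true(all(w$weight > 0))
  expect_equal(nrow(attr(w, "strata")), 1)  # single merged stratum
})

test_that("episode splitting handles menopause timing and imputation", {
  # natural menopause 48, diagnosis 52
  ep <- split_episodes(toy_pheno(TRUE, 52, meno = 48, post = TRUE))
  expect_equal(nrow(ep), 2)
  expect_equal(ep$start, c(0, 48))
  expect_equal(ep$stop, c(48, 52))
  expect_equal(ep$postmeno, c(0, 1))
  expect_equal(ep$event, c(FALSE, TRUE))

  # age missing but status known: split at the imputation age
  ep50 <- split_episodes(toy_pheno(TRUE, 60, post = TRUE))
  expect_equal(ep50$start, c(0, 50))
  ep46 <- split_episodes(toy_pheno(TRUE, 60, post = TRUE),
                         menopause_imputation_age = 46)
  expect_equal(ep46$start, c(0, 46))

  # menopause after exit: a single premenopausal row
  ep1 <- split_episodes(toy_pheno(TRUE, 45, meno = 48))
  expect_equal(nrow(ep1), 1)
  expect_equal(ep1$postmeno, 0)
})

test_that("a six-person table expands exactly as enumerated by hand", {
  ph <- toy_pheno(case = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                  exit = c(52, 45, 70, 40, 49.5, 55),
                  meno = c(48, NA, 51, NA, NA, NA),
                  post = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  ep <- split_episodes(ph)
  # split: P1 (48), P3 (51), P5 (imputed 50 < 49.5? no -> single row)
  expect_equal(nrow(ep), 6 + 2)
  expect_equal(sum(ep$event), 3)
  expect_equal(as.numeric(tapply(ep$stop - ep$start, ep$person,
                                 sum)[ph$person]),
               c(52, 45, 70, 40, 49.5, 55))
  p5 <- ep[ep$person == "P5", ]
  expect_equal(nrow(p5), 1)   # imputed age 50 is after her exit at 49.5
  expect_equal(p5$postmeno, 0)
})

test_that("episode splitting preserves follow-up time and events on cohorts", {
  co <- small_cohort(seed = 51, n_families = 400)
  ph <- co$phenotypes
  ep <- split_episodes(ph)
  expect_equal(sum(ep$event), sum(ph$case))
  ex <- kinmr:::exit_summary(ph)
  expect_equal(as.numeric(tapply(ep$stop - ep$start, ep$person,
                                 sum)[ph$person]),
               ex$exit_age, tolerance = 1e-12)
  expect_true(all(tapply(ep$event, ep$person, sum) <= 1))
})

test_that("the three-subject fit matches the closed-form solution", {
  # events at t=1 (x=1) and t=2 (x=0), third (x=1) censored later:
  # the score equation reduces to 2 u^2 = 1, beta = -log(2)/2
  ep <- make_episodes(start = c(0, 0, 0), stop = c(1, 2, 2.5),
                      event = c(TRUE, TRUE, FALSE), x = c(1, 0, 1))
  fit <- fit_weighted_cox(ep, "x", ties = "breslow")
  expect_equal(fit$coef, -0.5 * log(2), tolerance = 1e-6)
  expect_equal(fit$coef,
               oracle_cox_1cov(ep$start, ep$stop, ep$event, ep$x),
               tolerance = 1e-6)
})

test_that("weighted fits agree with brute-force partial-likelihood maximisation", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    ep <- make_episodes(start = rep(0, n),
                        stop = round(stats::runif(n, 1, 10), 3),
                        event = stats::runif(n) < 0.6,
                        x = round(stats::rnorm(n), 2),
                        w = round(stats::runif(n, 0.3, 3), 2))
    if (sum(ep$event) < 2 || stats::var(ep$x[ep$event]) == 0) next
    fit <- fit_weighted_cox(ep, "x", ties = "breslow")
    orc <- oracle_cox_1cov(ep$start, ep$stop, ep$event, ep$x, ep$weight)
    expect_equal(fit$coef, orc, tolerance = 1e-6)
  }
  # two covariates, left truncation, against multi-dimensional oracle
  ep2 <- make_episodes(start = c(0, 0, 1, 2, 0, 3, 0, 1),
                       stop = c(4, 5.5, 6, 7, 8, 9, 3.2, 6.8),
                       event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                                 TRUE, FALSE),
                       x = c(0.5, -1, 0.2, 1.4, -0.3, 0.9, -1.2, 0.1),
                       w = c(1, 2, 0.5, 1, 1.5, 1, 2, 1))
  ep2$z <- c(0, 1, 1, 0, 1, 0, 1, 0)
  fit2 <- fit_weighted_cox(ep2, c("x", "z"), ties = "breslow")
  orc2 <- oracle_cox(ep2$start, ep2$stop, ep2$event,
                     cbind(ep2$x, ep2$z), ep2$weight)
  expect_equal(fit2$coef, orc2, tolerance = 1e-5)
})

test_that("negating a covariate negates its coefficient, robust SE unchanged", {
  co <- small_cohort(seed = 53, n_families = 300)
  ep <- split_episodes(co$phenotypes)
  f1 <- fit_weighted_cox(ep, "height_cm")
  ep$neg <- -ep$height_cm
  f2 <- fit_weighted_cox(ep, "neg")
  expect_equal(f1$coef, -f2$coef, tolerance = 1e-8)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-8)
})

test_that("rescaling all weights leaves coefficients and robust SEs unchanged", {
  co <- small_cohort(seed = 54, n_families = 300)
  ph <- co$phenotypes
  w <- build_weights(ph, co$incidence)
  ep <- split_episodes(ph, weights = w)
  f1 <- fit_weighted_cox(ep, c("height_cm", "gene"))
  ep$weight <- 2 * ep$weight
  f2 <- fit_weighted_cox(ep, c("height_cm", "gene"))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-6)
})

test_that("degenerate model specifications fail loudly", {
  co <- small_cohort(seed = 55, n_families = 100)
  ep <- split_episodes(co$phenotypes)
  ep$dup <- ep$height_cm
  expect_error(fit_weighted_cox(ep, c("height_cm", "dup")), "collinear")
  ep0 <- ep; ep0$event <- FALSE
  expect_error(fit_weighted_cox(ep0, "height_cm"), "no events")
  expect_error(fit_weighted_cox(ep, "not_a_column"), "not_a_column")
})

test_that("Wald p-values match hand-computed normal tail probabilities", {
  expect_equal(round(wald_p(0.127, 0.036), 4), 0.0004)
  expect_equal(round(wald_p(-0.203, 0.068), 3), 0.003)
  expect_equal(wald_p(0, 1), 1)
  expect_equal(wald_p(1.96, 1), 0.05, tolerance = 1e-3)
  expect_error(wald_p(1, 0), "positive")
})

test_that("interaction test rejects reliably under a generated interaction", {
  gen <- function(seed, n = 5000, b_int = 0.5) {
    set.seed(seed)
    x <- stats::rnorm(n); m <- stats::rbinom(n, 1, 0.5)
    lp <- 0.2 * x + 0.3 * m + b_int * x * m
    t_ev <- 60 * (stats::rexp(n) * exp(-lp))^(1 / 4)
    cens <- stats::runif(n, 30, 70)
    data.frame(person = seq_len(n), family = seq_len(n), start = 0,
               stop = pmin(t_ev, cens), event = t_ev <= cens,
               x = x, m = m, weight = 1)
  }
  p <- vapply(1:20, function(s)
    interaction_test(gen(s), "x", "m")$p_interaction, numeric(1))
  expect_gte(mean(p < 0.01), 0.9)
  # duplicated binary exposure as its own modifier is collinear
  ep <- gen(99)
  ep$xb <- as.numeric(ep$x > 0)
  expect_error(interaction_test(ep, "xb", "xb"), "collinear")
  expect_error(interaction_test(within(ep, cm <- 1), "x", "cm"), "constant")
})

test_that("subtype censoring reassignment matches manual bookkeeping", {
  ph <- toy_pheno(case = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                           FALSE),
                  exit = c(45, 50, 55, 60, 48, 52, 58, 62))
  ph$histology <- c("serous", "other", NA, NA, "serous", NA,
                    "endometrioid", NA)
  ph$x <- c(1, 0, 1, 0, 0, 1, 1, 0)
  ep <- split_episodes(ph)
  res <- subtype_analysis(ep, "x", "histology",
                          list(serous = "serous",
                               non_serous = c("mucinous", "endometrioid",
                                              "clear cell", "other")))
  # manual enumeration: serous events P1, P5; non-serous events P2, P7;
  # unlabelled cases (P3) censored at diagnosis age in both fits
  expect_equal(res$serous$n_events, 2)
  expect_equal(res$non_serous$n_events, 2)
  expect_equal(res$serous$n, 8)       # everyone stays in the risk sets
  expect_false(is.na(res$p_het))
})

test_that("subtype heterogeneity p is calibrated when classes share one effect", {
  p_het <- vapply(1:60, function(s) {
    co <- small_cohort(seed = 500 + s, n_families = 1200)
    ep <- split_episodes(co$phenotypes)
    tryCatch(subtype_analysis(ep, "height_cm", "histology",
                              list(serous = "serous",
                                   non_serous = c("mucinous", "endometrioid",
                                                  "clear cell", "other")),
                              weights_col = NULL)$p_het,
             error = function(e) NA_real_)
  }, numeric(1))
  p_het <- p_het[!is.na(p_het)]
  expect_gt(length(p_het), 50)
  expect_lt(mean(p_het < 0.05), 0.15)
  expect_gt(stats::sd(p_het), 0.15)   # spread out, not clustered at 0 or 1
})

test_that("a class without events is reported absent", {
  ph <- toy_pheno(case = c(TRUE, TRUE, FALSE, FALSE),
                  exit = c(45, 50, 60, 62))
  ph$histology <- c("serous", "serous", NA, NA)
  ph$x <- c(1, 0, 1, 0)
  ep <- split_episodes(ph)
  res <- subtype_analysis(ep, "x", "histology",
                          list(serous = "serous", non_serous = "other"))
  expect_null(res$non_serous)
  expect_true(is.na(res$p_het))
  expect_s3_class(res$serous, "cox_result")
})
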