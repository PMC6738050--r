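test_that("imputation-quality filter drops below-threshold variants only", {
  path <- write_weight_file(toy_weights())
  w <- suppressMessages(load_snp_weights(path, 0.5))
  expect_equal(nrow(w), 3)                      # 0.5 itself is retained
  expect_setequal(w$rsid, c("rs1", "rs2", "rs4"))
  expect_equal(attr(w, "n_dropped"), 2)
  expect_equal(nrow(suppressMessages(load_snp_weights(path, 0))), 5)
})

test_that("a full-size panel with adequate quality is fully retained", {
  panel <- toy_weights(586, info = stats::runif(586, 0.5, 1))
  panel$rsid <- sprintf("rs%d", 1:586)
  w <- suppressMessages(load_snp_weights(write_weight_file(panel), 0.5))
  expect_equal(nrow(w), 586)
})

test_that("weight-table defects are reported by name", {
  dup <- toy_weights()
  dup$rsid[2] <- "rs1"
  expect_error(suppressMessages(load_snp_weights(write_weight_file(dup))),
               "duplicate rsID.*rs1")
  noeaf <- toy_weights()
  noeaf$eaf <- NULL
  expect_error(suppressMessages(load_snp_weights(write_weight_file(noeaf))),
               "eaf")
  badallele <- toy_weights()
  badallele$effect_allele[1] <- "N"
  expect_error(suppressMessages(load_snp_weights(write_weight_file(badallele))),
               "non-ACGT")
})

test_that("raw scores equal the weighted dosage sum", {
  set.seed(31)
  n <- 10; m <- 8
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  w <- toy_weights(m, info = rep(1, m))
  w$beta <- round(stats::rnorm(m, 0, 0.05), 4)
  geno <- list(person = paste0("P", 1:n), rsid = w$rsid, dosage = dos)
  colnames(geno$dosage) <- w$rsid
  sc <- build_raw_scores(geno, w)
  expect_equal(sc$raw, score_oracle(dos, w$beta), tolerance = 1e-12)

  # degenerate and single-variant cases
  geno0 <- geno; geno0$dosage[] <- 0
  expect_equal(build_raw_scores(geno0, w)$raw, rep(0, n))
  w1 <- w[1, , drop = FALSE]; w1$beta <- 0.05
  g1 <- list(person = "P1", rsid = w1$rsid,
             dosage = matrix(2, 1, 1, dimnames = list(NULL, w1$rsid)))
  expect_equal(build_raw_scores(g1, w1)$raw, 0.10)
})

test_that("raw scores are additive over panels and column-order invariant", {
  set.seed(32)
  co <- small_cohort(seed = 33, n_families = 80, n_snps = 12)
  w <- co$snp_weights
  sc_all <- build_raw_scores(co$genotypes, w)
  sc_a <- build_raw_scores(co$genotypes, w[1:5, ])
  sc_b <- build_raw_scores(co$genotypes, w[6:12, ])
  expect_equal(sc_all$raw, sc_a$raw + sc_b$raw, tolerance = 1e-12)
  perm <- sample(nrow(w))
  geno_perm <- co$genotypes
  geno_perm$dosage <- geno_perm$dosage[, perm]
  geno_perm$rsid <- geno_perm$rsid[perm]
  expect_equal(build_raw_scores(geno_perm, w)$raw, sc_all$raw,
               tolerance = 1e-12)
})

test_that("allele orientation is resolved, flipped, or rejected correctly", {
  w <- toy_weights(3, info = rep(1, 3))
  w$effect_allele <- c("A", "A", "A")
  w$other_allele <- c("G", "G", "T")   # rs3 palindromic A/T
  w$eaf <- c(0.3, 0.3, 0.5)
  w$beta <- c(0.1, 0.1, 0.1)
  dos <- matrix(c(2, 1, 0), 1, 3, dimnames = list(NULL, w$rsid))
  geno <- list(person = "P1", rsid = w$rsid, dosage = dos)

  # counted allele = other allele: dosage flips to 2 - d
  da <- data.frame(rsid = w$rsid,
                   counted_allele = c("A", "G", "A"),
                   other_allele = c("G", "A", "T"))
  expect_error(build_raw_scores(geno, w, da), "rs3")  # ambiguous palindrome
  da2 <- da[1:2, ]; w2 <- w[1:2, ]
  g2 <- list(person = "P1", rsid = w2$rsid,
             dosage = dos[, 1:2, drop = FALSE])
  sc <- build_raw_scores(g2, w2, da2)
  expect_equal(sc$raw, 0.1 * 2 + 0.1 * (2 - 1))
  # strand-complement match resolves for non-palindromic variants
  da3 <- data.frame(rsid = w2$rsid, counted_allele = c("T", "T"),
                    other_allele = c("C", "C"))
  expect_equal(build_raw_scores(g2, w2, da3)$raw, 0.1 * 2 + 0.1 * 1)
  # unresolvable mismatch names the variant
  da4 <- data.frame(rsid = w2$rsid, counted_allele = c("C", "A"),
                    other_allele = c("A", "G"))
  expect_error(build_raw_scores(g2, w2, da4), "rs1")
})

test_that("missing dosages are mean-imputed from the allele frequency", {
  w <- toy_weights(2, info = c(1, 1))
  w$beta <- c(1, 1); w$eaf <- c(0.25, 0.4)
  dos <- matrix(c(NA, 1, 2, NA), 2, 2, dimnames = list(NULL, w$rsid))
  geno <- list(person = c("P1", "P2"), rsid = w$rsid, dosage = dos)
  sc <- build_raw_scores(geno, w)
  expect_equal(sc$raw, c(2 * 0.25 + 2, 1 + 2 * 0.4))
})

test_that("scaling regression reproduces closed-form fits", {
  sc <- data.frame(person = c("a", "b"), raw = c(0, 1))
  m <- suppressWarnings(fit_scaling(rbind(sc, sc, sc),
                                    rep(c(160, 165), 3), rep(TRUE, 6)))
  expect_equal(m$beta0, 160, tolerance = 1e-10)
  expect_equal(m$beta1, 5, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)

  set.seed(41)
  sc2 <- data.frame(person = paste0("P", 1:50), raw = stats::rnorm(50))
  ident <- suppressWarnings(fit_scaling(sc2, sc2$raw, rep(TRUE, 50)))
  expect_equal(ident$beta0, 0, tolerance = 1e-10)
  expect_equal(ident$beta1, 1, tolerance = 1e-10)

  expect_error(fit_scaling(sc2, sc2$raw, c(rep(TRUE, 2), rep(FALSE, 48))),
               ">= 3 non-case")
  const <- data.frame(person = paste0("P", 1:5), raw = rep(1, 5))
  expect_error(fit_scaling(const, stats::rnorm(5), rep(TRUE, 5)),
               "zero variance")
})

test_that("scaling recovers a literature-style slope from noisy cohorts", {
  co <- simulate_cohort(sim_config(n_families = 4200, n_snps = 20,
                                   missing_trait_fraction = 0, seed = 42))
  ph <- co$phenotypes
  # express weights in per-unit-of-slope terms so the generating slope is
  # the height-panel scaling value 5.217
  w <- co$snp_weights
  w$beta <- w$beta / 5.217
  sc <- build_raw_scores(co$genotypes, w)
  m <- fit_scaling(sc, stats::setNames(ph$height_cm, ph$person), !ph$case)
  se <- sqrt(stats::vcov(stats::lm(ph$height_cm[!ph$case] ~
                                     sc$raw[!ph$case]))[2, 2])
  expect_lt(abs(m$beta1 - 5.217), 3 * se)
})

test_that("scaled scores satisfy the unit regression identity on the fitting set", {
  s <- scored(small_cohort(seed = 43, n_families = 500))
  use <- !s$pheno$case & !is.na(s$pheno$height_cm)
  fit <- stats::lm(s$pheno$height_cm[use] ~ s$scores$scaled[use])
  expect_equal(unname(stats::coef(fit)), c(0, 1), tolerance = 1e-8)
  expect_equal(s$scores$scaled,
               s$scaling$beta0 + s$scaling$beta1 * s$scores$raw,
               tolerance = 1e-12)
})

test_that("cross-trait checks report null, identity, and degenerate cases", {
  set.seed(44)
  x <- stats::rnorm(10000)
  indep <- cross_trait_check(x, stats::rnorm(10000))
  expect_lt(abs(indep$slope), 3 * indep$se)
  self <- suppressWarnings(cross_trait_check(x, x))
  expect_equal(self$slope, 1, tolerance = 1e-10)
  expect_error(cross_trait_check(x, rep(2, 10000)), "constant")
})
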