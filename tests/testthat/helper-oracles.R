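# Independent oracles and small fixture builders, deliberately naive:
# explicit loops over risk sets, no reuse of package internals.

# Weighted Cox partial log-likelihood, Breslow ties, left-truncated
# (start, stop] episodes, covariate matrix X.
pl_loglik <- function(beta, start, stop, event, X, w) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event)) {
    t_i <- stop[i]
    risk <- which(start < t_i & stop >= t_i)
    ll <- ll + w[i] * (eta[i] - log(sum(w[risk] * exp(eta[risk]))))
  }
  ll
}

# One-covariate brute-force maximiser.
oracle_cox_1cov <- function(start, stop, event, x, w = rep(1, length(x))) {
  X <- matrix(x, ncol = 1)
  stats::optimize(function(b) -pl_loglik(b, start, stop, event, X, w),
                  c(-8, 8), tol = 1e-10)$minimum
}

# Multi-covariate brute-force maximiser.
oracle_cox <- function(start, stop, event, X, w = rep(1, nrow(X))) {
  stats::optim(rep(0, ncol(X)),
               function(b) -pl_loglik(b, start, stop, event, X, w),
               method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}

# Double-loop raw-score oracle.
score_oracle <- function(dosage, beta) {
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage)))
    for (j in seq_len(ncol(dosage)))
      out[i] <- out[i] + beta[j] * dosage[i, j]
  out
}

# Minimal episode table from parallel vectors.
make_episodes <- function(start, stop, event, x,
                          w = rep(1, length(x)),
                          family = seq_along(x)) {
  data.frame(person = seq_along(x), family = family,
             start = start, stop = stop, event = event,
             x = x, weight = w)
}

# Small cohort + derived objects used across tests.
small_cohort <- function(seed = 5, n_families = 850, n_snps = 5, ...) {
  simulate_cohort(sim_config(n_families = n_families, n_snps = n_snps,
                             missing_trait_fraction = 0, seed = seed, ...))
}

scored <- function(cohort) {
  ph <- cohort$phenotypes
  sc <- build_raw_scores(cohort$genotypes, cohort$snp_weights)
  sm <- fit_scaling(sc, stats::setNames(ph[[cohort$truth$trait_name]],
                                        ph$person), !ph$case)
  list(pheno = ph, scores = scale_scores(sc, sm), scaling = sm)
}

# Weight-table writer for loader tests.
write_weight_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_weights <- function(n = 5,
                        info = c(0.9, 0.7, 0.49, 0.5, 0.3)[seq_len(n)]) {
  data.frame(rsid = paste0("rs", seq_len(n)), chrom = 1,
             pos = seq_len(n) * 1000,
             effect_allele = "A", other_allele = "G",
             beta = seq_len(n) / 100, eaf = 0.3, info = info,
             stringsAsFactors = FALSE)
}
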