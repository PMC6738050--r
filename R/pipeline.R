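# Configuration-driven orchestration: simulate or load inputs, build and
# scale scores, construct weights and episodes, fit the
# sequential-adjustment ladder and subgroup models, run the per-variant
# scan with IVW/Egger/I^2, run TSRI with its family bootstrap, and emit a
# reproducible report bundle.

#' Pipeline configuration
#'
#' Assembles and validates a run configuration. Exactly one of `simulate`
#' (a [sim_config()]) or `inputs` (named paths `phenotypes`, `dosages`,
#' `snp_weights`, `incidence`) must be supplied.
#'
#' @param simulate Optional [sim_config()] describing a synthetic cohort.
#' @param inputs Optional named list/vector of input file paths.
#' @param trait One of `"height_cm"`, `"bmi_now"`, `"bmi_young"`.
#' @param report_k Reporting multiple in trait units (10 for height cm,
#'   5 for BMI kg/m^2).
#' @param min_quality Imputation-quality threshold for the variant panel.
#' @param menopause_imputation_age Default 50 (46 as sensitivity).
#' @param ties `"efron"` or `"breslow"`.
#' @param band_width,min_stratum Weight-stratum controls
#'   ([build_weights()]).
#' @param alpha Nominal significance level for the per-variant hit count.
#' @param B Bootstrap replicates for TSRI.
#' @param seed Integer seed governing every stochastic step of the run.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       trait = c("height_cm", "bmi_now", "bmi_young"),
                       report_k = 10,
                       min_quality = 0.5,
                       menopause_imputation_age = 50,
                       ties = c("efron", "breslow"),
                       band_width = 5, min_stratum = 10,
                       alpha = 0.05, B = 10000, seed = 1L) {
  if (is.null(simulate) == is.null(inputs))
    stop_kinmr("supply exactly one of 'simulate' or 'inputs'")
  if (!is.null(inputs)) {
    need <- c("phenotypes", "dosages", "snp_weights", "incidence")
    inputs <- as.list(inputs)
    if (!all(need %in% names(inputs)))
      stop_kinmr("inputs must name: %s", paste(need, collapse = ", "))
    missing_files <- !file.exists(unlist(inputs[need]))
    if (any(missing_files))
      stop_kinmr("input file(s) not found: %s",
                 paste(unlist(inputs[need])[missing_files], collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs,
                 trait = match.arg(trait), report_k = report_k,
                 min_quality = min_quality,
                 menopause_imputation_age = menopause_imputation_age,
                 ties = match.arg(ties),
                 band_width = band_width, min_stratum = min_stratum,
                 alpha = alpha, B = as.integer(B), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments; a `simulate:` block is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

#' Validate analysis input files
#'
#' Schema, range, and cross-file consistency checks. Problems are returned
#' as a character vector of diagnostics (empty on success), never raised.
#'
#' @param paths Named paths as in [run_config()]'s `inputs`.
#' @return Character vector of diagnostics.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  diags <- character(0)
  note <- function(...) diags <<- c(diags, sprintf(...))
  ph <- dos <- wts <- NULL
  try_read <- function(f, path, what) {
    tryCatch(f(path), error = function(e) {
      note("%s (%s): %s", what, path, conditionMessage(e)); NULL
    })
  }
  ph <- try_read(read_phenotypes, paths$phenotypes, "phenotype table")
  dos <- try_read(read_dosages, paths$dosages, "dosage matrix")
  wts <- try_read(function(p) suppressMessages(load_snp_weights(p, 0)),
                  paths$snp_weights, "variant-weight table")
  inc <- try_read(read_incidence, paths$incidence, "incidence table")
  if (!is.null(dos) && any(dos$dosage < 0 | dos$dosage > 2, na.rm = TRUE))
    note("dosage matrix: values outside [0, 2]")
  if (!is.null(ph) && !is.null(dos)) {
    absent <- setdiff(ph$person, dos$person)
    if (length(absent))
      note("dosage matrix lacks %d phenotype person(s), e.g. %s",
           length(absent), absent[1])
  }
  if (!is.null(wts) && !is.null(dos)) {
    absent <- setdiff(wts$rsid, dos$rsid)
    if (length(absent))
      note("dosage matrix lacks %d panel rsID(s), e.g. %s",
           length(absent), absent[1])
  }
  if (!is.null(ph) && !is.null(inc)) {
    absent <- setdiff(unique(ph$gene), inc$gene)
    if (length(absent))
      note("incidence table lacks gene(s): %s", paste(absent, collapse = ", "))
  }
  diags
}

# Adjustment ladder mirroring the sequential-confounding presentation:
# principal components first, then country, birth cohort, gene, menopause.
ladder_steps <- function() {
  pcs <- paste0("pc", 1:8)
  list("principal components" = pcs,
       "+ country" = c(pcs, "country"),
       "+ birth cohort" = c(pcs, "country", "birth_decade"),
       "+ mutation status" = c(pcs, "country", "birth_decade", "gene"),
       "+ menopausal status" = c(pcs, "country", "birth_decade", "gene",
                                 "postmeno"))
}

cox_row <- function(fit, term, k, label, n_label = NULL) {
  h <- hr_per_k(fit, term, k)
  data.frame(model = label,
             n = n_label %||% fit$n, n_events = fit$n_events,
             hr = h$hr, ci_lo = h$ci_lo, ci_hi = h$ci_hi, p = h$p,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, score construction and scaling, weight and
#' episode construction, the sequential-adjustment ladder, subgroup fits
#' (gene, menopausal status, histology, grade) with interaction or
#' heterogeneity p-values, the per-variant scan with IVW, Egger, and I^2,
#' and TSRI with a family bootstrap, writing six artifacts to `out_dir`:
#' `ladder.tsv`, `subgroups.tsv`, `per_snp.tsv`, `ivw.json`, `tsri.json`,
#' and `manifest.json` (plus `config.json`). Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config A `"run_config"` or path to a YAML file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results and artifact
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## inputs
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    if (config$simulate$case_oversampling_factor > 1)
      cohort <- ascertain(cohort, config$simulate$case_oversampling_factor,
                          seed = config$seed)
    pheno <- cohort$phenotypes
    genotypes <- cohort$genotypes
    panel <- cohort$snp_weights
    incidence <- cohort$incidence
  } else {
    diags <- validate_inputs(config$inputs)
    if (length(diags))
      stop_kinmr("invalid inputs:\n%s", paste("-", diags, collapse = "\n"))
    pheno <- read_phenotypes(config$inputs$phenotypes)
    genotypes <- read_dosages(config$inputs$dosages)
    panel <- load_snp_weights(config$inputs$snp_weights, config$min_quality)
    incidence <- read_incidence(config$inputs$incidence)
  }
  trait <- config$trait
  k <- config$report_k

  ## scores and scaling
  scores <- build_raw_scores(genotypes, panel)
  scaling <- fit_scaling(scores, stats::setNames(pheno[[trait]],
                                                 pheno$person),
                         non_case = !pheno$case)
  scores <- scale_scores(scores, scaling)
  pheno$gs_scaled <- scores$scaled[match(pheno$person, scores$person)]

  ## weights and episodes
  weights <- build_weights(pheno, incidence, config$band_width,
                           config$min_stratum)
  episodes <- split_episodes(pheno, config$menopause_imputation_age,
                             weights = weights)

  ## sequential-adjustment ladder on the scaled score; drop single-level
  ## factors so small fixtures remain estimable
  usable <- function(covs) Filter(function(cv)
    cv == "postmeno" || length(unique(pheno[[cv]] %||% episodes[[cv]])) > 1,
    covs)
  steps <- ladder_steps()
  ladder <- do.call(rbind, lapply(names(steps), function(lab) {
    fit <- fit_weighted_cox(episodes, c("gs_scaled", usable(steps[[lab]])),
                            ties = config$ties)
    cox_row(fit, "gs_scaled", k, lab)
  }))

  ## subgroups
  sub_rows <- list()
  add_row <- function(fit, label, p_group = NA_real_) {
    r <- cox_row(fit, "gs_scaled", k, label)
    r$p_interaction <- p_group
    sub_rows[[length(sub_rows) + 1]] <<- r
  }
  # a subgroup or interaction fit that fails (separation in a sparse
  # stratum) yields an absent row / NA p rather than aborting the run
  try_fit <- function(expr) tryCatch(expr, error = function(e) {
    message("run_pipeline: subgroup fit skipped: ", conditionMessage(e))
    NULL
  })
  two_genes <- length(unique(pheno$gene)) > 1
  gene_p <- NA_real_
  if (two_genes) {
    episodes$gene_num <- as.numeric(factor(episodes$gene))
    gene_p <- try_fit(interaction_test(
      episodes, "gs_scaled", "gene_num",
      usable(c(paste0("pc", 1:8), "country", "birth_decade", "postmeno")),
      ties = config$ties)$p_interaction) %||% NA_real_
    for (g in sort(unique(pheno$gene))) {
      ep_g <- episodes[episodes$gene == g, , drop = FALSE]
      fit <- try_fit(fit_weighted_cox(
        ep_g, c("gs_scaled", usable(c(paste0("pc", 1:8), "country",
                                      "birth_decade", "postmeno"))),
        ties = config$ties))
      if (!is.null(fit)) add_row(fit, paste("gene:", g), gene_p)
    }
  }
  meno_covs <- usable(c(paste0("pc", 1:8), "country", "birth_decade",
                        "gene"))
  meno_p <- try_fit(interaction_test(episodes, "gs_scaled", "postmeno",
                                     meno_covs,
                                     ties = config$ties)$p_interaction) %||%
    NA_real_
  pre <- try_fit(fit_weighted_cox(
    episodes[episodes$postmeno == 0, , drop = FALSE],
    c("gs_scaled", meno_covs), ties = config$ties))
  post <- try_fit(fit_weighted_cox(
    episodes[episodes$postmeno == 1, , drop = FALSE],
    c("gs_scaled", meno_covs), ties = config$ties))
  if (!is.null(pre)) add_row(pre, "menopause: premenopausal", meno_p)
  if (!is.null(post)) add_row(post, "menopause: postmenopausal", meno_p)

  subtype_covs <- usable(c(paste0("pc", 1:8), "country", "birth_decade",
                           "gene", "postmeno"))
  histo <- try_fit(subtype_analysis(
    episodes, "gs_scaled", "histology",
    list(serous = "serous",
         non_serous = c("mucinous", "endometrioid",
                        "clear cell", "other")),
    subtype_covs, ties = config$ties)) %||% list(p_het = NA_real_)
  grade <- try_fit(subtype_analysis(
    episodes, "gs_scaled", "grade",
    list(well_moderate = c("well", "moderate"),
         poor_undiff = "poor/undiff"),
    subtype_covs, ties = config$ties)) %||% list(p_het = NA_real_)
  for (nm in c("serous", "non_serous")) if (!is.null(histo[[nm]]))
    add_row(histo[[nm]], paste("histology:", nm), histo$p_het)
  for (nm in c("well_moderate", "poor_undiff")) if (!is.null(grade[[nm]]))
    add_row(grade[[nm]], paste("grade:", nm), grade$p_het)
  subgroups <- do.call(rbind, sub_rows)
  interaction_p <- data.frame(
    test = c("gene", "menopausal status", "histology", "grade"),
    p = c(gene_p, meno_p, histo$p_het, grade$p_het))

  ## per-variant scan and combination
  assocs <- scan_snps(episodes, genotypes, panel,
                      usable(c(paste0("pc", 1:8), "country", "birth_decade",
                               "gene", "postmeno")),
                      ties = config$ties)
  ivw <- ivw_estimate(assocs)
  egger <- if (sum(assocs$status == "ok") >= 3) egger_test(assocs) else NULL
  hits <- count_nominal_hits(assocs, config$alpha)

  ## TSRI with family bootstrap
  pheno$birth_decade <- factor(10 * (pheno$birth_year %/% 10))
  tsri <- bootstrap_ci(pheno, scores, trait,
                       covariates = usable(c(paste0("pc", 1:8), "country",
                                             "birth_decade", "gene")),
                       weights = weights, B = config$B, seed = config$seed,
                       menopause_imputation_age =
                         config$menopause_imputation_age,
                       ties = config$ties)

  ## artifacts
  paths <- c(config = file.path(out_dir, "config.json"),
             ladder = file.path(out_dir, "ladder.tsv"),
             subgroups = file.path(out_dir, "subgroups.tsv"),
             per_snp = file.path(out_dir, "per_snp.tsv"),
             ivw = file.path(out_dir, "ivw.json"),
             tsri = file.path(out_dir, "tsri.json"),
             manifest = file.path(out_dir, "manifest.json"))
  wt <- function(df, path) utils::write.table(
    format(df, digits = 10, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_json <- config
  cfg_json$simulate <- unclass(cfg_json$simulate)
  jsonlite::write_json(unclass(cfg_json), paths["config"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  wt(ladder, paths["ladder"])
  wt(subgroups, paths["subgroups"])
  per_snp <- merge(panel, assocs[c("rsid", "beta_yg", "se_yg", "p",
                                   "status")], by = "rsid", sort = TRUE)
  wt(per_snp, paths["per_snp"])
  jsonlite::write_json(
    list(beta_yx = ivw$beta_yx, se_yx = ivw$se_yx, p = ivw$p, k = ivw$k,
         hr_per_k_units = exp(k * ivw$beta_yx),
         ci_lo = exp(k * (ivw$beta_yx - 1.96 * ivw$se_yx)),
         ci_hi = exp(k * (ivw$beta_yx + 1.96 * ivw$se_yx)),
         report_k = k, q = ivw$q, i2 = ivw$i2,
         egger = egger, nominal_hits = hits),
    paths["ivw"], auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(estimate = tsri$estimate, naive_se = tsri$naive_se,
         hr_per_k_units = exp(k * tsri$estimate),
         ci_lo = exp(k * tsri$ci[1]), ci_hi = exp(k * tsri$ci[2]),
         report_k = k,
         stage1 = list(f_stat = tsri$stage1$f_stat, r2 = tsri$stage1$r2,
                       n = tsri$stage1$n),
         B = tsri$B, n_failed = tsri$n_failed, boot_sd = tsri$boot_sd,
         seed = tsri$seed),
    paths["tsri"], auto_unbox = TRUE, digits = NA, null = "null")
  art_names <- c("config", "ladder", "subgroups", "per_snp", "ivw", "tsri")
  artifact_md5 <- stats::setNames(
    unname(tools::md5sum(unname(paths[art_names]))), art_names)
  jsonlite::write_json(
    list(package = "kinmr",
         version = as.character(utils::packageVersion("kinmr")),
         seed = config$seed,
         config_md5 = unname(tools::md5sum(paths[["config"]])),
         n_women = nrow(pheno), n_events = sum(pheno$case),
         n_variants = nrow(panel),
         scaling = scaling[c("beta0", "beta1", "r2", "n_used")],
         artifacts = as.list(artifact_md5)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)

  invisible(list(pheno = pheno, scores = scores, scaling = scaling,
                 weights = weights, episodes = episodes, ladder = ladder,
                 subgroups = subgroups, interaction_p = interaction_p,
                 assocs = assocs, ivw = ivw, egger = egger, hits = hits,
                 tsri = tsri, paths = paths))
}
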