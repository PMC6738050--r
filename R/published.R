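# Shipped worked-example data.

#' Published per-variant carrier associations
#'
#' The height- and BMI-associated variants reported as nominally associated
#' (p < 0.05) with ovarian cancer risk in a large BRCA1/2 carrier
#' consortium: per-allele log hazard ratio, standard error, and p-value
#' from multivariate-adjusted weighted Cox models, with allele and
#' imputation-quality metadata. Used as a worked example for Wald-statistic
#' consistency checks ([wald_p()]).
#'
#' @return Data frame with columns `rsid`, `chrom`, `pos`, `gene`,
#'   `ref_allele`, `effect_allele`, `eaf`, `info`, `log_hr`, `se`, `p`,
#'   `trait`.
#' @export
published_snp_associations <- function() {
  utils::read.delim(system.file("extdata", "carrier_snp_associations.tsv",
                                package = "kinmr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
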