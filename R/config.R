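#' Pipeline configuration
#'
#' Returns the configuration list consumed by the harmonization, pooling,
#' diagnostics and bias modules. Call with name = value pairs to override
#' individual keys; unknown keys are an error.
#'
#' @param ... overrides for the defaults listed below.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{min_k (4)}{minimum number of usable studies for a SNP x population
#'     stratum to be meta-analyzed.}
#'   \item{switch_maf_delta (0.2)}{a reported minor-allele frequency deviating
#'     from the reference MAF by more than this is a candidate label switch.}
#'   \item{switch_match_tol (0.1)}{...and is switched only if it matches
#'     1 - MAF within this tolerance (guards against subpopulation drift).}
#'   \item{palindromic_window (c(0.4, 0.6))}{reference MAF window inside which
#'     A/T and C/G variants are strand-ambiguous and excluded.}
#'   \item{hwe_alpha (0.05)}{significance level for the control-group
#'     Hardy-Weinberg test used in the sensitivity re-analysis.}
#'   \item{hwe_method ("exact")}{"exact" conditional test or "chisq".}
#'   \item{outlier_z (1.96)}{absolute studentized deleted residual above which
#'     a study is flagged as an outlier.}
#'   \item{dffits_mult (3)}{study influential if |DFFITS| > dffits_mult *
#'     sqrt(1/(k-1)).}
#'   \item{covratio_mult (3)}{...or if COVRATIO < 1 - covratio_mult/(k-1).}
#'   \item{bias_min_k (10)}{minimum studies for publication-bias testing.}
#'   \item{bias_alpha (0.05)}{significance level of the asymmetry test that
#'     triggers trim-and-fill adjustment.}
#'   \item{trimfill_estimator ("L0")}{missing-study estimator, "L0" or "R0".}
#'   \item{i2_model_switch (75)}{I-squared (percent) above which the expanded
#'     GWAS combination uses the random-effects rather than fixed-effects Z.}
#'   \item{exclude_caucasian_candidates (TRUE)}{drop Caucasian candidate-gene
#'     strata from the GWAS combination (sample-overlap guard).}
#'   \item{candidate_entry ("pooled")}{candidate-gene evidence enters the GWAS
#'     combination as one pooled random-effects estimate per SNP ("pooled") or
#'     study by study ("study").}
#'   \item{ancestry_population}{named map from study ancestry to reference
#'     panel population; `NA` disables frequency checks for that ancestry.}
#'   \item{trio_se_literal (FALSE)}{if TRUE, use the variance 1/C_T + 1/C_N
#'     itself as the trio standard error (audit/compatibility form) instead of
#'     its square root.}
#'   \item{ci_se_literal (FALSE)}{if TRUE, use CI_up - OR on the odds-ratio
#'     scale as the CI-based standard error (audit/compatibility form) instead
#'     of the log-scale interval width over 2 * 1.96.}
#'   \item{bonferroni_denominator ("snps")}{"snps" divides 0.05 by the number
#'     of meta-analyzed SNPs; "tests" by SNP x population strata.}
#' }
#'
#' @return a named list with class `"meta_config"`.
#' @examples
#' cfg <- meta_config(bias_min_k = 12)
#' cfg$bias_min_k
#' @export
meta_config <- function(...) {
  defaults <- list(
    min_k = 4L,
    switch_maf_delta = 0.2,
    switch_match_tol = 0.1,
    palindromic_window = c(0.4, 0.6),
    hwe_alpha = 0.05,
    hwe_method = "exact",
    outlier_z = 1.96,
    dffits_mult = 3,
    covratio_mult = 3,
    bias_min_k = 10L,
    bias_alpha = 0.05,
    trimfill_estimator = "L0",
    i2_model_switch = 75,
    exclude_caucasian_candidates = TRUE,
    candidate_entry = "pooled",
    ancestry_population = c(Asian = "EAS", Caucasian = "EUR", Other = NA),
    trio_se_literal = FALSE,
    ci_se_literal = FALSE,
    bonferroni_denominator = "snps"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("meta_config() overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  structure(defaults, class = "meta_config")
}

as_meta_config <- function(config) {
  if (is.null(config)) return(meta_config())
  if (inherits(config, "meta_config")) return(config)
  do.call(meta_config, as.list(config))
}
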