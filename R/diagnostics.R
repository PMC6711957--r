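#' @name diagnostics
#' @title Outlier and influence diagnostics for a meta-analysis
#' @description Each study is deleted in turn and the DerSimonian-Laird
#'   model re-fit (with `tau^2` re-estimated). Studentized deleted residuals
#'   flag outliers; DFFITS, DFBETAS and COVRATIO flag influential studies;
#'   a sensitivity re-analysis re-pools after excluding flagged studies and,
#'   separately, after excluding studies whose control group violates
#'   Hardy-Weinberg equilibrium.
NULL

#' Leave-one-out re-analysis
#'
#' @param ae,se study log odds ratios and standard errors, `k >= 3`.
#' @return a list of `k` `meta_result` objects; the i-th is the
#'   DerSimonian-Laird fit with study i removed.
#' @export
leave_one_out <- function(ae, se) {
  check_estimates(ae, se)
  k <- length(ae)
  if (k < 3)
    stop_snpmeta("leave-one-out requires at least 3 studies",
                 class = "snpmeta_diagnostics_error")
  lapply(seq_len(k), function(i)
    dersimonian_laird_meta(ae[-i], se[-i]))
}

#' Studentized deleted residuals
#'
#' `t_i = (ae_i - pooled_(-i)) / sqrt(se_i^2 + tau2_(-i) + se_(-i)^2)`,
#' where the deleted quantities come from the leave-one-out random-effects
#' fit. Studies with `|t_i|` above `outlier_z` (default 1.96) are outliers.
#'
#' @inheritParams leave_one_out
#' @param loo optionally, a precomputed [leave_one_out()] list.
#' @return numeric vector of `t_i`.
#' @export
studentized_deleted_residuals <- function(ae, se, loo = NULL) {
  if (is.null(loo)) loo <- leave_one_out(ae, se)
  vapply(seq_along(ae), function(i) {
    d <- loo[[i]]
    (ae[i] - d$random$est) /
      sqrt(se[i]^2 + d$tau2 + d$random$se^2)
  }, numeric(1))
}

#' DFFITS, DFBETAS and COVRATIO
#'
#' For the intercept-only random-effects model:
#' `dffits_i = (pooled - pooled_(-i)) / se_(-i)`; DFBETAS coincides with
#' DFFITS (the pooled effect is the only coefficient) and is reported
#' separately for completeness; `covratio_i = var_(-i) / var_full`, the
#' ratio of deleted to full pooled-estimate variance. A study is influential
#' when `|dffits| > dffits_mult * sqrt(1/(k-1))` or
#' `covratio < 1 - covratio_mult/(k-1)`.
#'
#' @inheritParams studentized_deleted_residuals
#' @param config a [meta_config()] (`dffits_mult`, `covratio_mult`).
#' @return a data frame with `dffits`, `dfbetas`, `covratio`, `influential`.
#' @export
influence_measures <- function(ae, se, config = meta_config(), loo = NULL) {
  config <- as_meta_config(config)
  if (is.null(loo)) loo <- leave_one_out(ae, se)
  full <- dersimonian_laird_meta(ae, se)
  k <- length(ae)
  dffits <- vapply(seq_len(k), function(i) {
    d <- loo[[i]]
    (full$random$est - d$random$est) / d$random$se
  }, numeric(1))
  covratio <- vapply(seq_len(k), function(i)
    loo[[i]]$random$se^2 / full$random$se^2, numeric(1))
  influential <- abs(dffits) > config$dffits_mult * sqrt(1 / (k - 1)) |
    covratio < 1 - config$covratio_mult / (k - 1)
  data.frame(dffits = dffits, dfbetas = dffits, covratio = covratio,
             influential = influential)
}

#' Full diagnostics report for one stratum
#'
#' @inheritParams influence_measures
#' @param study_id optional study labels.
#' @return a `diagnostics_report`: per-study table (`deleted_est`,
#'   `deleted_se`, `t`, `dffits`, `dfbetas`, `covratio`, `outlier`,
#'   `influential`) plus the full-model `meta_result`. With fewer than 3
#'   studies a `computed = FALSE` marker is returned.
#' @export
meta_influence <- function(ae, se, config = meta_config(),
                           study_id = NULL) {
  config <- as_meta_config(config)
  full <- dersimonian_laird_meta(ae, se)
  if (length(ae) < 3)
    return(structure(list(computed = FALSE, k = length(ae), full = full,
                          studies = NULL),
                     class = "diagnostics_report"))
  loo <- leave_one_out(ae, se)
  t_i <- studentized_deleted_residuals(ae, se, loo = loo)
  infl <- influence_measures(ae, se, config, loo = loo)
  studies <- data.frame(
    study_id = study_id %||% paste0("study_", seq_along(ae)),
    ae = ae, se = se,
    deleted_est = vapply(loo, function(d) d$random$est, 0),
    deleted_se = vapply(loo, function(d) d$random$se, 0),
    t = t_i,
    infl,
    outlier = abs(t_i) > config$outlier_z,
    stringsAsFactors = FALSE
  )
  structure(list(computed = TRUE, k = length(ae), full = full,
                 studies = studies, loo = loo),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  if (!isTRUE(x$computed)) {
    cat(sprintf("diagnostics not computed (k = %d < 3)\n", x$k))
    return(invisible(x))
  }
  cat(sprintf("diagnostics_report: k = %d, %d outlier(s), %d influential\n",
              x$k, sum(x$studies$outlier), sum(x$studies$influential)))
  print(x$studies[c("study_id", "t", "dffits", "covratio",
                    "outlier", "influential")], digits = 3)
  invisible(x)
}

#' Sensitivity re-analysis after exclusions
#'
#' Two independent re-analyses of one stratum: (a) excluding the union of
#' outliers and influential studies, and (b) excluding studies whose control
#' genotypes violate Hardy-Weinberg equilibrium. The `presented` result
#' follows the reporting convention of using the sensitivity result when any
#' outlier/influence exclusion occurred and the primary result otherwise.
#' Exclusions that drop a stratum below `min_k` mark it ineligible after
#' sensitivity exclusion.
#'
#' @inheritParams influence_measures
#' @param hwe_violates logical vector (per study): control-group HWE
#'   violation; `NA`/`FALSE` for untestable studies.
#' @param study_id optional study labels.
#' @param snp_id,population,n_cases,n_controls labels forwarded to the
#'   pooled results.
#' @return a `sensitivity_result` list: `primary` (`meta_result`),
#'   `diagnostics` (`diagnostics_report`), `outlier_influence` and `hwe`
#'   re-analyses (each a `meta_result` or an `eligible = FALSE` marker),
#'   the exclusion index sets, and `presented`.
#' @export
sensitivity_reanalysis <- function(ae, se, hwe_violates = NULL,
                                   config = meta_config(), study_id = NULL,
                                   snp_id = NA_character_,
                                   population = NA_character_,
                                   n_cases = NA_real_, n_controls = NA_real_) {
  config <- as_meta_config(config)
  k <- length(ae)
  primary <- dersimonian_laird_meta(ae, se, snp_id = snp_id,
                                    population = population,
                                    n_cases = n_cases,
                                    n_controls = n_controls)
  diag <- meta_influence(ae, se, config, study_id = study_id)
  excl_oi <- if (isTRUE(diag$computed))
    which(diag$studies$outlier | diag$studies$influential) else integer()
  hwe_violates <- hwe_violates %||% rep(FALSE, k)
  excl_hwe <- which(hwe_violates %in% TRUE)

  repool <- function(excl, label) {
    if (!length(excl)) return(primary)
    left <- setdiff(seq_len(k), excl)
    if (length(left) < config$min_k)
      return(list(eligible = FALSE, k = length(left), snp_id = snp_id,
                  population = population,
                  note = sprintf("ineligible after %s exclusion", label)))
    dersimonian_laird_meta(ae[left], se[left], snp_id = snp_id,
                           population = population,
                           n_cases = n_cases, n_controls = n_controls)
  }
  outlier_influence <- repool(excl_oi, "outlier/influence")
  hwe <- repool(excl_hwe, "HWE")
  presented <- if (length(excl_oi)) outlier_influence else primary
  structure(list(primary = primary, diagnostics = diag,
                 outlier_influence = outlier_influence, hwe = hwe,
                 excluded_outlier_influence = excl_oi,
                 excluded_hwe = excl_hwe, presented = presented,
                 presented_is_sensitivity = length(excl_oi) > 0),
            class = "sensitivity_result")
}
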