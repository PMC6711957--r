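#' @name meta_engine
#' @title Fixed-effects and DerSimonian-Laird random-effects pooling
#' @description Study-level log odds ratios are pooled by inverse variance.
#'   The fixed-effects model weights each study by `1/se^2`; the
#'   DerSimonian-Laird random-effects model adds the moment estimate of the
#'   between-study variance `tau^2` to every study's sampling variance.
#'   Heterogeneity is summarized by Cochran's Q and Higgins's I-squared.
NULL

check_estimates <- function(ae, se) {
  if (length(ae) != length(se))
    stop_snpmeta("ae and se must have equal length",
                 class = "snpmeta_meta_error")
  if (any(!is.finite(ae)) || any(!is.finite(se)) || any(se <= 0))
    stop_snpmeta("all effects must be finite with positive standard errors",
                 class = "snpmeta_meta_error")
}

#' Fixed-effects inverse-variance pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled effect `sum(w*ae)/sum(w)` with standard
#' error `1/sqrt(sum(w))` and a two-sided normal p-value. With a single
#' study the input is returned flagged `degenerate`.
#'
#' @param ae study log odds ratios.
#' @param se their standard errors.
#' @return a list: `est`, `se`, `z`, `p`, `ci` (95%, normal 1.96),
#'   `k`, `degenerate`.
#' @examples
#' fixed_effects_meta(c(0.2, 0.4), c(0.1, 0.1))
#' @export
fixed_effects_meta <- function(ae, se) {
  check_estimates(ae, se)
  k <- length(ae)
  w <- 1 / se^2
  est <- sum(w * ae) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  list(est = est, se = pooled_se, z = est / pooled_se,
       p = wald_p(est, pooled_se), ci = ci95(est, pooled_se), k = k,
       degenerate = k < 2)
}

#' Higgins's I-squared from Cochran's Q
#'
#' `I^2 = 100 * max(0, (Q - (k-1)) / Q)`, the percentage of total variation
#' across studies attributable to heterogeneity rather than chance,
#' truncated at zero; `Q = 0` maps to `I^2 = 0`.
#'
#' @param q_stat Cochran's Q.
#' @param k number of studies.
#' @return I-squared in `[0, 100)`.
#' @examples
#' heterogeneity(8, 5)  # 50
#' @export
heterogeneity <- function(q_stat, k) {
  if (k < 2) stop_snpmeta("k must be >= 2", class = "snpmeta_meta_error")
  if (q_stat <= 0) return(0)
  max(0, (q_stat - (k - 1)) / q_stat) * 100
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Computes the fixed-effects pool, Cochran's
#' `Q = sum(w_i * (ae_i - pooled_fixed)^2)`, the moment estimator
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and re-pools
#' with random-effects weights `1/(se_i^2 + tau^2)`. Confidence intervals
#' use the normal 1.96 multiplier throughout.
#'
#' @param ae study log odds ratios.
#' @param se their standard errors.
#' @param snp_id,population labels carried into the result.
#' @param n_cases,n_controls total subject counts carried into the result.
#' @return a `meta_result`: `k`, `fixed` and `random` (each `est, se, z, p,
#'   ci`), `q`, `df`, `i2`, `tau2`, `or_random` with `or_ci`, and the inputs
#'   (`ae`, `se_ae`).
#' @examples
#' dersimonian_laird_meta(c(0.2, 0.4, 0.6), rep(0.2, 3))
#' @export
dersimonian_laird_meta <- function(ae, se, snp_id = NA_character_,
                                   population = NA_character_,
                                   n_cases = NA_real_, n_controls = NA_real_) {
  check_estimates(ae, se)
  k <- length(ae)
  fixed <- fixed_effects_meta(ae, se)
  if (k < 2) {
    res <- list(snp_id = snp_id, population = population, k = k,
                fixed = fixed, random = fixed, q = 0, df = 0, i2 = 0,
                tau2 = 0, or_random = exp(fixed$est),
                or_ci = exp(fixed$ci), n_cases = n_cases,
                n_controls = n_controls, ae = ae, se_ae = se,
                degenerate = TRUE)
    class(res) <- "meta_result"
    return(res)
  }
  w <- 1 / se^2
  q <- sum(w * (ae - fixed$est)^2)
  df <- k - 1
  c_denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_denom)
  w_star <- 1 / (se^2 + tau2)
  est <- sum(w_star * ae) / sum(w_star)
  pooled_se <- 1 / sqrt(sum(w_star))
  random <- list(est = est, se = pooled_se, z = est / pooled_se,
                 p = wald_p(est, pooled_se), ci = ci95(est, pooled_se),
                 k = k, degenerate = FALSE)
  res <- list(snp_id = snp_id, population = population, k = k,
              fixed = fixed, random = random, q = q, df = df,
              i2 = heterogeneity(q, k), tau2 = tau2,
              or_random = exp(random$est), or_ci = exp(random$ci),
              n_cases = n_cases, n_controls = n_controls,
              ae = ae, se_ae = se, degenerate = FALSE)
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: %s [%s], k = %d\n",
              x$snp_id, x$population, x$k))
  cat(sprintf("  random: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or_random, x$or_ci[1], x$or_ci[2], x$random$p))
  cat(sprintf("  fixed:  OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              exp(x$fixed$est), exp(x$fixed$ci[1]), exp(x$fixed$ci[2]),
              x$fixed$p))
  cat(sprintf("  Q = %.3f (df %d), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, x$i2, x$tau2))
  invisible(x)
}

harmonized_to_matrix <- function(included) {
  data.frame(
    study_id = vapply(included, `[[`, "", "study_id"),
    ancestry = vapply(included, `[[`, "", "ancestry"),
    ae = vapply(included, function(h) h$effect$ae, 0),
    se = vapply(included, function(h) h$effect$se_ae, 0),
    k_cases = vapply(included, function(h) h$effect$k_cases %||% NA_real_, 0),
    k_controls = vapply(included, function(h) h$effect$k_controls %||% NA_real_, 0),
    stringsAsFactors = FALSE
  )
}

#' Pool one SNP across population strata
#'
#' Runs the DerSimonian-Laird meta-analysis on all non-excluded studies
#' (stratum `All`) and separately on the Asian and Caucasian subsets, each
#' gated by the `min_k` eligibility rule applied independently per stratum.
#'
#' @param harmonized a list of `harmonized_study` objects for one SNP.
#' @param config a [meta_config()].
#' @return a named list (`All`, `Asian`, `Caucasian`) where each element is
#'   either a `meta_result` or a list with `eligible = FALSE` and the usable
#'   study count `k`.
#' @export
meta_by_stratum <- function(harmonized, config = meta_config()) {
  config <- as_meta_config(config)
  usable <- eligibility_filter(harmonized, config)$included
  snp_id <- if (length(harmonized)) harmonized[[1]]$snp_id else NA_character_
  strata <- list(
    All = usable,
    Asian = Filter(function(h) identical(h$ancestry, "Asian"), usable),
    Caucasian = Filter(function(h) identical(h$ancestry, "Caucasian"), usable)
  )
  lapply(setNames(names(strata), names(strata)), function(nm) {
    studies <- strata[[nm]]
    if (length(studies) < config$min_k)
      return(list(eligible = FALSE, k = length(studies), snp_id = snp_id,
                  population = nm))
    m <- harmonized_to_matrix(studies)
    dersimonian_laird_meta(m$ae, m$se, snp_id = snp_id, population = nm,
                           n_cases = sum(m$k_cases, na.rm = TRUE),
                           n_controls = sum(m$k_controls, na.rm = TRUE))
  })
}
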