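#' @name effect_extraction
#' @title Allelic effect extraction
#' @description Every study payload is reduced to an allelic effect
#'   `ae` — the natural-log odds ratio for the study's reference allele
#'   (`allele1`) — and its standard error `se_ae`. Counts routes use the
#'   2x2 allele table; statistics routes back-calculate the standard error
#'   from a reported p-value or 95% confidence interval; family studies use
#'   the transmission/non-transmission log relative risk.
NULL

new_effect_estimate <- function(ae, se_ae, route, snp_id = NA_character_,
                                study_id = NA_character_,
                                k_cases = NA_real_, k_controls = NA_real_,
                                table = NULL) {
  if (!is.finite(ae))
    stop_snpmeta("allelic effect is not finite",
                 class = "snpmeta_extraction_error")
  if (!is.finite(se_ae) || se_ae <= 0)
    stop_snpmeta("standard error must be positive and finite",
                 class = "snpmeta_extraction_error")
  structure(
    list(snp_id = snp_id, study_id = study_id, ae = ae, se_ae = se_ae,
         route = route, k_cases = k_cases, k_controls = k_controls,
         table = table),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "effect_estimate: ae = %.4f (se %.4f), OR = %.4f, route = %s\n",
    x$ae, x$se_ae, exp(x$ae), x$route))
  invisible(x)
}

#' Collapse genotype counts to allele counts
#'
#' For each group the count of allele A is `2*AA + Aa` and of allele a is
#' `2*aa + Aa`.
#'
#' @param case_AA,case_Aa,case_aa,ctrl_AA,ctrl_Aa,ctrl_aa non-negative
#'   integer genotype counts.
#' @return named numeric vector `case_A, case_a, ctrl_A, ctrl_a`.
#' @examples
#' genotype_to_allele_counts(10, 20, 10, 12, 18, 10)
#' @export
genotype_to_allele_counts <- function(case_AA, case_Aa, case_aa,
                                      ctrl_AA, ctrl_Aa, ctrl_aa) {
  counts <- c(case_AA, case_Aa, case_aa, ctrl_AA, ctrl_Aa, ctrl_aa)
  if (!all(is_count(counts)))
    stop_snpmeta("genotype counts must be non-negative integers",
                 class = "snpmeta_extraction_error")
  c(case_A = 2 * case_AA + case_Aa, case_a = 2 * case_aa + case_Aa,
    ctrl_A = 2 * ctrl_AA + ctrl_Aa, ctrl_a = 2 * ctrl_aa + ctrl_Aa)
}

#' Allelic effect from a 2x2 allele-count table
#'
#' `ae = log((case_A * ctrl_a) / (case_a * ctrl_A))` — the log odds ratio for
#' allele A (the study's reference allele) — with
#' `se_ae = sqrt(1/case_A + 1/case_a + 1/ctrl_A + 1/ctrl_a)`. When any cell
#' is zero, the Haldane-Anscombe continuity correction adds 0.5 to all four
#' cells before both formulas.
#'
#' @param case_A,case_a,ctrl_A,ctrl_a non-negative allele counts (reference
#'   allele A / other allele a, cases / controls).
#' @param ... passed through to the internal constructor (`snp_id`,
#'   `study_id`).
#' @return an `effect_estimate`; its `table` field retains the (uncorrected)
#'   counts for the score-based asymmetry test.
#' @examples
#' effect_from_allele_counts(30, 70, 20, 80)  # OR = 1.714 for allele A
#' @export
effect_from_allele_counts <- function(case_A, case_a, ctrl_A, ctrl_a, ...) {
  cells <- unname(c(case_A, case_a, ctrl_A, ctrl_a))
  if (!all(is_count(cells)))
    stop_snpmeta("allele counts must be non-negative integers",
                 class = "snpmeta_extraction_error")
  if (case_A + case_a == 0 || ctrl_A + ctrl_a == 0)
    stop_snpmeta("a study group has zero total allele count",
                 class = "snpmeta_extraction_error")
  corrected <- if (any(cells == 0)) cells + 0.5 else cells
  ae <- log((corrected[1] * corrected[4]) / (corrected[2] * corrected[3]))
  se <- sqrt(sum(1 / corrected))
  new_effect_estimate(ae, se, route = "allele_counts",
                      k_cases = sum(cells[1:2]) / 2,
                      k_controls = sum(cells[3:4]) / 2,
                      table = c(case_A = cells[1], case_a = cells[2],
                                ctrl_A = cells[3], ctrl_a = cells[4]), ...)
}

#' Allelic effect from genotype counts
#'
#' Collapses genotypes to allele counts and applies
#' [effect_from_allele_counts()]; subject counts are taken from the genotype
#' totals.
#'
#' @inheritParams genotype_to_allele_counts
#' @param ... passed to the constructor.
#' @return an `effect_estimate` with route `"genotype_counts"`.
#' @export
effect_from_genotype_counts <- function(case_AA, case_Aa, case_aa,
                                        ctrl_AA, ctrl_Aa, ctrl_aa, ...) {
  ac <- genotype_to_allele_counts(case_AA, case_Aa, case_aa,
                                  ctrl_AA, ctrl_Aa, ctrl_aa)
  est <- effect_from_allele_counts(ac["case_A"], ac["case_a"],
                                   ac["ctrl_A"], ac["ctrl_a"], ...)
  est$route <- "genotype_counts"
  est$k_cases <- case_AA + case_Aa + case_aa
  est$k_controls <- ctrl_AA + ctrl_Aa + ctrl_aa
  est
}

# z-approximation used by the p-based route; accurate to ~0.2% for
# central p but degrades in the tails (see the methods vignette)
pvalue_to_z_approx <- function(p) -0.862 + sqrt(0.743 - 2.404 * log(p))

#' Allelic effect from a reported odds ratio and p-value
#'
#' `ae = log(OR)`; the standard error is back-calculated as
#' `|ae| / (-0.862 + sqrt(0.743 - 2.404 * ln p))`, the closed-form
#' approximation to the two-sided normal quantile `qnorm(1 - p/2)`. The
#' reported p is assumed to be the two-sided allelic-test p (input contract).
#'
#' @param or_value reported odds ratio, > 0 and != 1.
#' @param p two-sided p-value in (0, 1).
#' @param ... passed to the constructor.
#' @return an `effect_estimate` with route `"p_based"`.
#' @examples
#' effect_from_pvalue(1.5, 0.05)
#' @export
effect_from_pvalue <- function(or_value, p, ...) {
  if (!is.finite(or_value) || or_value <= 0)
    stop_snpmeta("or_value must be > 0", class = "snpmeta_extraction_error")
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop_snpmeta("p must lie in (0,1)", class = "snpmeta_extraction_error")
  ae <- log(or_value)
  if (ae == 0)
    stop_snpmeta(
      "OR = 1 leaves the p-based standard error undefined; ",
      "use a confidence interval or exclude the record",
      class = "snpmeta_extraction_error")
  se <- abs(ae) / pvalue_to_z_approx(p)
  new_effect_estimate(ae, se, route = "p_based", ...)
}

#' Allelic effect from a reported odds ratio and 95% confidence interval
#'
#' `ae = log(OR)`; `se_ae = (log(ci_up) - log(ci_low)) / (2 * 1.96)`, the
#' log-scale interval width matching how 95% CIs of odds ratios are built.
#' `literal = TRUE` instead uses `ci_up - or_value` on the odds-ratio scale
#' (audit/compatibility form; mixes scales and is not recommended).
#'
#' @param or_value reported odds ratio.
#' @param ci_low,ci_up 95% CI bounds, `0 < ci_low < or_value < ci_up`.
#' @param literal use the scale-mixing compatibility formula.
#' @param ... passed to the constructor.
#' @return an `effect_estimate` with route `"ci_based"`.
#' @examples
#' effect_from_ci(1.18, 1.10, 1.25)
#' @export
effect_from_ci <- function(or_value, ci_low, ci_up, literal = FALSE, ...) {
  if (!is.finite(or_value) || !is.finite(ci_low) || !is.finite(ci_up) ||
      !(0 < ci_low && ci_low < or_value && or_value < ci_up))
    stop_snpmeta("need 0 < ci_low < OR < ci_up",
                 class = "snpmeta_extraction_error")
  ae <- log(or_value)
  se <- if (literal) ci_up - or_value
        else (log(ci_up) - log(ci_low)) / (2 * 1.96)
  new_effect_estimate(ae, se, route = "ci_based", ...)
}

#' Allelic effect from trio transmission counts
#'
#' For family-based studies, `ae = log(C_T / C_N)` where `C_T` and `C_N`
#' count transmissions and non-transmissions of the reference allele from
#' heterozygous parents to affected offspring, with
#' `se_ae = sqrt(1/C_T + 1/C_N)` (the square root of the log relative-risk
#' variance). A 0.5 continuity correction is added to both counts when
#' either is zero. `literal = TRUE` uses the variance itself as the standard
#' error (audit/compatibility form).
#'
#' @param trio_T,trio_N non-negative transmission counts, not both zero.
#' @param literal use the no-square-root compatibility form.
#' @param ... passed to the constructor.
#' @return an `effect_estimate` with route `"trio"`.
#' @examples
#' effect_from_trio(60, 40)
#' @export
effect_from_trio <- function(trio_T, trio_N, literal = FALSE, ...) {
  if (!all(is_count(c(trio_T, trio_N))))
    stop_snpmeta("trio counts must be non-negative integers",
                 class = "snpmeta_extraction_error")
  if (trio_T == 0 && trio_N == 0)
    stop_snpmeta("both trio counts are zero",
                 class = "snpmeta_extraction_error")
  ct <- trio_T; cn <- trio_N
  if (ct == 0 || cn == 0) { ct <- ct + 0.5; cn <- cn + 0.5 }
  ae <- log(ct / cn)
  v <- 1 / ct + 1 / cn
  se <- if (literal) v else sqrt(v)
  new_effect_estimate(ae, se, route = "trio", ...)
}

#' Choose the extraction route for a study record
#'
#' Family studies always use trio counts. Case-control studies use genotype
#' counts when available, then allele counts, then reported statistics (the
#' confidence interval is preferred over the p-value when both are present).
#'
#' @param record a one-row study-table data frame.
#' @return one of `"genotype_counts"`, `"allele_counts"`, `"ci_based"`,
#'   `"p_based"`, `"trio"`.
#' @export
select_data_source <- function(record) {
  if (identical(record$design, "family")) return("trio")
  if (has_genotype_payload(record)) return("genotype_counts")
  if (has_allele_payload(record)) return("allele_counts")
  if (has_statistics_payload(record)) {
    if (!is.na(record$ci_low) && !is.na(record$ci_up)) return("ci_based")
    return("p_based")
  }
  stop_snpmeta("record has no usable payload",
               class = "snpmeta_extraction_error")
}

#' Extract the allelic effect from a validated study record
#'
#' Dispatches on [select_data_source()]. The returned effect is oriented to
#' the record's `allele1`.
#'
#' @param record a one-row study-table data frame.
#' @param config a [meta_config()] (controls the compatibility flags).
#' @return an `effect_estimate`.
#' @export
extract_effect <- function(record, config = meta_config()) {
  config <- as_meta_config(config)
  route <- select_data_source(record)
  ids <- list(snp_id = record$snp_id, study_id = record$study_id)
  est <- switch(route,
    genotype_counts = do.call(effect_from_genotype_counts, c(
      record[c("case_AA", "case_Aa", "case_aa",
               "ctrl_AA", "ctrl_Aa", "ctrl_aa")], ids)),
    allele_counts = do.call(effect_from_allele_counts, c(
      record[c("case_A", "case_a", "ctrl_A", "ctrl_a")], ids)),
    ci_based = do.call(effect_from_ci, c(
      record[c("or_value", "ci_low", "ci_up")],
      list(literal = config$ci_se_literal), ids)),
    p_based = do.call(effect_from_pvalue, c(
      list(or_value = record$or_value, p = record$p_value), ids)),
    trio = do.call(effect_from_trio, c(
      record[c("trio_T", "trio_N")],
      list(literal = config$trio_se_literal), ids))
  )
  est
}
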