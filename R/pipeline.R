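#' @name pipeline
#' @title End-to-end per-SNP analysis and dataset-level report
#' @description For each SNP the pipeline harmonizes every study against the
#'   reference panel, applies the eligibility gate, pools the allelic
#'   effects under fixed- and random-effects models in the all-population,
#'   Asian and Caucasian strata, runs outlier/influence and
#'   Hardy-Weinberg sensitivity re-analyses, and — for strata with enough
#'   studies — tests and adjusts for publication bias. Random-effects
#'   results are the headline numbers; fixed-effects results are always
#'   emitted alongside.
NULL

result_row <- function(snp_id, population, analysis, m) {
  if (inherits(m, "meta_result")) {
    data.frame(
      snp_id = snp_id, population = population, analysis = analysis,
      eligible = TRUE, k = m$k,
      n_cases = m$n_cases, n_controls = m$n_controls,
      ae_fixed = m$fixed$est, se_fixed = m$fixed$se, p_fixed = m$fixed$p,
      ae_random = m$random$est, se_random = m$random$se,
      p_random = m$random$p,
      or_random = m$or_random, or_ci_low = m$or_ci[1],
      or_ci_up = m$or_ci[2],
      q = m$q, i2 = m$i2, tau2 = m$tau2,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      snp_id = snp_id, population = population, analysis = analysis,
      eligible = FALSE, k = m$k %||% NA_integer_,
      n_cases = NA_real_, n_controls = NA_real_,
      ae_fixed = NA_real_, se_fixed = NA_real_, p_fixed = NA_real_,
      ae_random = NA_real_, se_random = NA_real_, p_random = NA_real_,
      or_random = NA_real_, or_ci_low = NA_real_, or_ci_up = NA_real_,
      q = NA_real_, i2 = NA_real_, tau2 = NA_real_,
      stringsAsFactors = FALSE
    )
  }
}

#' Analyze all studies for one SNP
#'
#' Sequence: harmonize -> eligibility -> pool (All/Asian/Caucasian) ->
#' outlier/influence + HWE sensitivity -> publication bias (strata with at
#' least `bias_min_k` studies). Deterministic given inputs and config.
#'
#' @param records study-table rows for a single SNP (validated).
#' @param reference a `reference_table`.
#' @param config a [meta_config()].
#' @return a `snp_report`: `snp_id`, `harmonization` (per-study action
#'   table), `hwe` (per-study test results), `strata` (per-stratum list
#'   with `primary`, `sensitivity`, `bias`), and `rows` (the flat result
#'   rows).
#' @export
run_snp <- function(records, reference, config = meta_config()) {
  config <- as_meta_config(config)
  stopifnot(length(unique(records$snp_id)) == 1)
  snp_id <- records$snp_id[1]

  harmonized <- vector("list", nrow(records))
  hwe <- vector("list", nrow(records))
  errors <- character()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    h <- tryCatch(align_to_reference(rec, reference, config),
                  snpmeta_error = function(e) e)
    if (inherits(h, "error")) {
      errors <- c(errors, sprintf("%s [%s]: %s", snp_id, rec$study_id,
                                  conditionMessage(h)))
      h <- new_harmonized_study(NULL, "excluded_unresolved",
                                conditionMessage(h), rec)
    }
    harmonized[[i]] <- h
    hwe[[i]] <- hwe_test_record(rec, config)
  }

  harmonization <- data.frame(
    study_id = vapply(harmonized, `[[`, "", "study_id"),
    ancestry = vapply(harmonized, `[[`, "", "ancestry"),
    action = vapply(harmonized, `[[`, "", "action"),
    included = vapply(harmonized, `[[`, TRUE, "included"),
    note = vapply(harmonized, `[[`, "", "note"),
    hwe_p = vapply(hwe, `[[`, 0, "p"),
    hwe_violates = vapply(hwe, `[[`, TRUE, "violates"),
    hwe_testable = vapply(hwe, `[[`, TRUE, "testable"),
    stringsAsFactors = FALSE
  )

  usable_idx <- which(harmonization$included)
  strata_members <- list(
    All = usable_idx,
    Asian = usable_idx[harmonization$ancestry[usable_idx] == "Asian"],
    Caucasian = usable_idx[harmonization$ancestry[usable_idx] == "Caucasian"]
  )

  strata <- list()
  rows <- list()
  for (nm in names(strata_members)) {
    idx <- strata_members[[nm]]
    if (length(idx) < config$min_k) {
      strata[[nm]] <- list(eligible = FALSE, k = length(idx))
      rows[[length(rows) + 1L]] <-
        result_row(snp_id, nm, "primary", list(k = length(idx)))
      next
    }
    hs <- harmonized[idx]
    m <- harmonized_to_matrix(hs)
    sens <- sensitivity_reanalysis(
      m$ae, m$se,
      hwe_violates = harmonization$hwe_violates[idx] &
        harmonization$hwe_testable[idx],
      config = config, study_id = m$study_id, snp_id = snp_id,
      population = nm,
      n_cases = sum(m$k_cases, na.rm = TRUE),
      n_controls = sum(m$k_controls, na.rm = TRUE))
    tables <- do.call(rbind, lapply(hs, function(h) {
      tb <- h$effect$table
      if (is.null(tb)) c(case_A = NA_real_, case_a = NA_real_,
                         ctrl_A = NA_real_, ctrl_a = NA_real_) else tb
    }))
    bias <- assess_bias(m$ae, m$se, tables = as.data.frame(tables),
                        config = config, snp_id = snp_id, population = nm)
    strata[[nm]] <- list(eligible = TRUE, k = length(idx),
                         primary = sens$primary,
                         diagnostics = sens$diagnostics,
                         sensitivity = sens, bias = bias)
    rows[[length(rows) + 1L]] <- result_row(snp_id, nm, "primary",
                                            sens$primary)
    rows[[length(rows) + 1L]] <- result_row(snp_id, nm, "sensitivity",
                                            sens$outlier_influence)
    rows[[length(rows) + 1L]] <- result_row(snp_id, nm, "hwe_sensitivity",
                                            sens$hwe)
    rows[[length(rows) + 1L]] <- result_row(snp_id, nm, "presented",
                                            sens$presented)
    if (bias$applicable && bias$bias_detected)
      rows[[length(rows) + 1L]] <- result_row(snp_id, nm, "bias_adjusted",
                                              bias$adjusted)
  }

  structure(list(snp_id = snp_id, harmonization = harmonization,
                 hwe = hwe, strata = strata,
                 rows = do.call(rbind, rows), errors = errors),
            class = "snp_report")
}

#' Bonferroni familywise threshold
#'
#' @param n_snps number of meta-analyzed SNPs (or tests).
#' @return `0.05 / n_snps`.
#' @examples
#' bonferroni_threshold(550)  # 9.09e-05
#' @export
bonferroni_threshold <- function(n_snps) {
  if (n_snps < 1) stop_snpmeta("n_snps must be >= 1",
                               class = "snpmeta_pipeline_error")
  0.05 / n_snps
}

#' Run the full pipeline over a dataset
#'
#' @param studies a study table: a path, a raw data frame, or the output of
#'   [read_study_table()]/[validate_study_records()].
#' @param reference a `reference_table` (or a path to one).
#' @param gwas optional list of `gwas_summary` data frames for the expanded
#'   combination stage.
#' @param config a [meta_config()].
#' @return a `meta_run`: `results` (flat table, one row per SNP x
#'   population x analysis), `reports` (per-SNP [run_snp()] reports, named
#'   by SNP), `summary` (dataset summaries: analyzed SNP count, median and
#'   IQR of studies per SNP and combined sample size, Bonferroni threshold,
#'   nominal and Bonferroni-significant SNP lists), `combined` (expanded
#'   meta-analysis table when `gwas` given), `problems`, `config`.
#' @export
run_all <- function(studies, reference, gwas = NULL,
                    config = meta_config()) {
  config <- as_meta_config(config)
  if (is.character(studies)) studies <- read_study_table(studies)
  if (is.data.frame(studies) && !inherits(studies, "study_table"))
    studies <- validate_study_records(studies)
  problems <- data.frame(row = integer(), reason = character())
  if (is.list(studies) && !is.data.frame(studies)) {
    problems <- studies$problems
    studies <- studies$records
  }
  if (is.character(reference)) reference <- read_reference_frequencies(reference)

  snp_ids <- unique(studies$snp_id)
  reports <- list()
  rows <- list()
  for (snp in snp_ids) {
    rep_snp <- run_snp(studies[studies$snp_id == snp, , drop = FALSE],
                       reference, config)
    reports[[snp]] <- rep_snp
    rows[[snp]] <- rep_snp$rows
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    result_row("x", "All", "primary", list(k = 0L))[0, ]
  rownames(results) <- NULL

  analyzed <- results[results$analysis == "primary" & results$eligible &
                        results$population == "All", , drop = FALSE]
  analyzed_snps <- unique(
    results$snp_id[results$analysis == "primary" & results$eligible])
  n_tests <- sum(results$analysis == "primary" & results$eligible)
  denom <- if (identical(config$bonferroni_denominator, "tests"))
    n_tests else length(analyzed_snps)
  threshold <- if (denom >= 1) bonferroni_threshold(denom) else NA_real_

  pres <- results[results$analysis == "presented" & results$eligible, ,
                  drop = FALSE]
  nominal <- unique(pres$snp_id[pres$p_random < 0.05])
  bonf <- if (is.na(threshold)) character() else
    unique(pres$snp_id[pres$p_random < threshold])

  summary <- list(
    n_snps_input = length(snp_ids),
    n_snps_analyzed = length(analyzed_snps),
    n_strata_analyzed = n_tests,
    median_studies = if (nrow(analyzed)) median(analyzed$k) else NA_real_,
    iqr_studies = if (nrow(analyzed))
      unname(quantile(analyzed$k, c(0.25, 0.75))) else c(NA_real_, NA_real_),
    median_sample_size = if (nrow(analyzed))
      median(analyzed$n_cases + analyzed$n_controls) else NA_real_,
    iqr_sample_size = if (nrow(analyzed))
      unname(quantile(analyzed$n_cases + analyzed$n_controls,
                      c(0.25, 0.75))) else c(NA_real_, NA_real_),
    bonferroni_threshold = threshold,
    nominal_snps = nominal,
    bonferroni_snps = bonf
  )

  run <- structure(list(results = results, reports = reports,
                        summary = summary, problems = problems,
                        config = config, combined = NULL),
                   class = "meta_run")
  if (!is.null(gwas))
    run$combined <- combine_with_gwas(run, gwas, reference, config)
  run
}

#' @export
print.meta_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("meta_run: %d SNPs in, %d analyzed (%d strata)\n",
              s$n_snps_input, s$n_snps_analyzed, s$n_strata_analyzed))
  cat(sprintf("  studies per SNP: median %.0f (IQR %.0f-%.0f)\n",
              s$median_studies, s$iqr_studies[1], s$iqr_studies[2]))
  cat(sprintf("  combined sample size: median %.0f (IQR %.0f-%.0f)\n",
              s$median_sample_size, s$iqr_sample_size[1],
              s$iqr_sample_size[2]))
  cat(sprintf("  Bonferroni threshold %.3g: %d significant, %d nominal\n",
              s$bonferroni_threshold, length(s$bonferroni_snps),
              length(s$nominal_snps)))
  if (!is.null(x$combined))
    cat(sprintf("  expanded GWAS combination: %d SNPs\n", nrow(x$combined)))
  invisible(x)
}
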