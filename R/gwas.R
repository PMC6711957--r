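#' @name gwas_combine
#' @title Expanded meta-analysis with GWAS summary statistics
#' @description Candidate-gene pooled effects for nominally significant SNPs
#'   are combined with per-cohort GWAS summary effects by inverse variance.
#'   The fixed-effects Z-statistic is used unless heterogeneity across the
#'   combined inputs is pronounced (`I^2 >` 75% by default), in which case
#'   the DerSimonian-Laird random-effects Z is reported instead.
NULL

#' Harmonize GWAS summary records against the reference panel
#'
#' Applies the same decision procedure as [align_to_reference()] to each
#' GWAS record, using the reported effect-allele frequency (`frq`) where
#' present. Effects are re-oriented to the reference minor allele;
#' palindromic SNPs without a usable frequency (or with a reference MAF
#' inside the ambiguity window) are excluded.
#'
#' @param records a `gwas_summary` data frame (see [read_gwas_summary()]).
#' @param reference a `reference_table`.
#' @param config a [meta_config()].
#' @param population reference population for the lookup; defaults to the
#'   per-record ancestry mapped through `config$ancestry_population`.
#' @return the records with `beta` re-oriented, alleles on the forward
#'   strand, and added columns `action` and `included`.
#' @export
align_gwas_alleles <- function(records, reference, config = meta_config(),
                               population = NULL) {
  config <- as_meta_config(config)
  n <- nrow(records)
  action <- character(n)
  included <- logical(n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    pop <- population %||% {
      pm <- config$ancestry_population
      if (rec$ancestry %in% names(pm)) pm[[rec$ancestry]] else NA_character_
    }
    ref <- ref_lookup(reference, rec$snp_id, pop)
    a1 <- rec$effect_allele; a2 <- rec$other_allele
    if (!ref$found) {
      action[i] <- "unchanged"; included[i] <- TRUE
      next
    }
    if (is_palindromic(a1, a2)) {
      win <- config$palindromic_window
      if (ref$maf >= win[1] && ref$maf <= win[2] || is.na(rec$frq)) {
        action[i] <- "excluded_ambiguous"
        next
      }
      if (rec$frq == 0.5) { action[i] <- "excluded_ambiguous"; next }
      if (rec$frq > 0.5) {
        records$beta[i] <- -rec$beta
        records$frq[i] <- 1 - rec$frq
        action[i] <- "allele_switched"
      } else action[i] <- "unchanged"
      records$effect_allele[i] <- ref$minor_allele
      records$other_allele[i] <- ref$major_allele
      included[i] <- TRUE
      next
    }
    ref_pair <- c(ref$minor_allele, ref$major_allele)
    flipped <- FALSE
    if (!setequal(c(a1, a2), ref_pair)) {
      if (setequal(complement_allele(c(a1, a2)), ref_pair)) {
        a1 <- complement_allele(a1); a2 <- complement_allele(a2)
        flipped <- TRUE
      } else {
        action[i] <- "excluded_unresolved"
        next
      }
    }
    f_minor <- if (is.na(rec$frq)) NA_real_
               else if (a1 == ref$minor_allele) rec$frq else 1 - rec$frq
    label_switched <- !is.na(f_minor) &&
      abs(f_minor - ref$maf) > config$switch_maf_delta &&
      abs(f_minor - (1 - ref$maf)) <= config$switch_match_tol
    effect_nucleotide <- if (label_switched) a2 else a1
    negate <- effect_nucleotide == ref$major_allele
    if (negate) {
      records$beta[i] <- -records$beta[i]
      if (!is.na(records$frq[i])) records$frq[i] <- 1 - records$frq[i]
    }
    records$effect_allele[i] <- ref$minor_allele
    records$other_allele[i] <- ref$major_allele
    action[i] <- if (flipped && negate) "strand_flipped_and_switched"
                 else if (flipped) "strand_flipped"
                 else if (negate) "allele_switched"
                 else "unchanged"
    included[i] <- TRUE
  }
  records$action <- action
  records$included <- included
  records
}

#' Gate SNPs for the expanded meta-analysis
#'
#' Passes SNPs whose candidate-gene random-effects p-value is below 0.05 in
#' any analyzed stratum (the `presented` result of the sensitivity
#' workflow).
#'
#' @param results the flat results data frame from [run_all()] (or any data
#'   frame with `snp_id`, `analysis`, `p_random` columns).
#' @param alpha nominal level, default 0.05.
#' @return character vector of SNP ids.
#' @export
gate_nominal <- function(results, alpha = 0.05) {
  if (!nrow(results)) return(character())
  pres <- results[results$analysis == "presented" & !is.na(results$p_random), ]
  unique(pres$snp_id[pres$p_random < alpha])
}

#' Inverse-variance combination of summary effects
#'
#' Pools two or more summary effects (per-cohort GWAS betas plus the pooled
#' candidate-gene effect). Heterogeneity across inputs is measured by I^2;
#' at or below `i2_model_switch` (default 75%) the fixed-effects Z is
#' reported, above it the DerSimonian-Laird random-effects Z.
#'
#' @param beta,se input log odds ratios and standard errors.
#' @param inputs optional labels for the inputs.
#' @param config a [meta_config()].
#' @param snp_id label carried into the result.
#' @return a `combined_result`: `beta`, `se`, `z`, `p`, `model`
#'   (`"fixed"`/`"random"`), `i2`, `q`, `k`, `inputs`.
#' @export
combine_inverse_variance <- function(beta, se, inputs = NULL,
                                     config = meta_config(),
                                     snp_id = NA_character_) {
  config <- as_meta_config(config)
  check_estimates(beta, se)
  if (length(beta) < 2)
    stop_snpmeta("combination needs at least two inputs",
                 class = "snpmeta_combine_error")
  dl <- dersimonian_laird_meta(beta, se)
  use_random <- dl$i2 > config$i2_model_switch
  branch <- if (use_random) dl$random else dl$fixed
  structure(list(snp_id = snp_id, beta = branch$est, se = branch$se,
                 z = branch$z, p = branch$p,
                 model = if (use_random) "random" else "fixed",
                 i2 = dl$i2, q = dl$q, tau2 = dl$tau2, k = length(beta),
                 inputs = inputs %||% paste0("input_", seq_along(beta))),
            class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf(
    "combined_result %s: Z = %.3f, p = %.3g, model = %s, I2 = %.1f%% (k = %d)\n",
    x$snp_id, x$z, x$p, x$model, x$i2, x$k))
  invisible(x)
}

#' Combine a pipeline run with GWAS summary data
#'
#' For every nominally significant SNP, gathers the harmonized per-cohort
#' GWAS effects and the pooled candidate-gene random-effects estimate —
#' the Asian stratum when `exclude_caucasian_candidates` is on (the
#' sample-overlap guard), the all-population stratum otherwise — and runs
#' [combine_inverse_variance()].
#'
#' @param run a `meta_run` from [run_all()].
#' @param gwas a list of `gwas_summary` data frames (one per cohort).
#' @param reference a `reference_table`.
#' @param config a [meta_config()].
#' @return a data frame (one row per combined SNP): `snp_id, z, p, model,
#'   i2, k_inputs, inputs`.
#' @export
combine_with_gwas <- function(run, gwas, reference,
                              config = meta_config()) {
  config <- as_meta_config(config)
  gated <- gate_nominal(run$results)
  aligned <- lapply(gwas, align_gwas_alleles, reference = reference,
                    config = config)
  out <- list()
  candidate_stratum <- if (config$exclude_caucasian_candidates) "Asian"
                       else "All"
  for (snp in gated) {
    beta <- numeric(); se <- numeric(); labels <- character()
    for (coh in aligned) {
      hit <- coh[coh$snp_id == snp & coh$included, , drop = FALSE]
      if (nrow(hit)) {
        beta <- c(beta, hit$beta[1])
        se <- c(se, hit$se[1])
        labels <- c(labels, hit$cohort_id[1])
      }
    }
    cand <- run$results[run$results$snp_id == snp &
                          run$results$population == candidate_stratum &
                          run$results$analysis == "presented", , drop = FALSE]
    if (nrow(cand) && !is.na(cand$ae_random[1])) {
      if (config$candidate_entry == "study") {
        rep_snp <- run$reports[[snp]]
        st <- rep_snp$strata[[candidate_stratum]]
        if (!is.null(st$sensitivity)) {
          pres <- st$sensitivity$presented
          if (inherits(pres, "meta_result")) {
            beta <- c(beta, pres$ae)
            se <- c(se, pres$se_ae)
            labels <- c(labels, paste0("candidate_", seq_along(pres$ae)))
          }
        }
      } else {
        beta <- c(beta, cand$ae_random[1])
        se <- c(se, cand$se_random[1])
        labels <- c(labels, sprintf("candidate_%s", candidate_stratum))
      }
    }
    if (length(beta) >= 2) {
      cr <- combine_inverse_variance(beta, se, inputs = labels,
                                     config = config, snp_id = snp)
      out[[snp]] <- data.frame(snp_id = snp, z = cr$z, p = cr$p,
                               model = cr$model, i2 = cr$i2,
                               k_inputs = cr$k,
                               inputs = paste(labels, collapse = ","),
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(), z = numeric(), p = numeric(),
                      model = character(), i2 = numeric(),
                      k_inputs = integer(), inputs = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
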