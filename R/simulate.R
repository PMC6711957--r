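#' @name synthetic_data
#' @title Synthetic study-collection generator
#' @description Generates per-SNP collections of case-control and trio
#'   studies with the statistical structure the pipeline assumes: per-study
#'   true effects drawn around a SNP-level log odds ratio with between-study
#'   variance, allele counts binomial given ancestry-specific control
#'   frequencies, genotypes drawn under Hardy-Weinberg equilibrium (or with
#'   an inbreeding coefficient for contaminated studies), optional
#'   publication bias, strand and allele-label errors, statistics-only
#'   reporting, and GWAS cohort summaries. The generator emits the exact TSV
#'   formats consumed by the readers, so it doubles as the fixture source
#'   for every test.
NULL

#' Simulation configuration
#'
#' Defaults emulate the study collections the pipeline targets: the number
#' of studies per SNP is `4 + Geometric(0.32)` (median 5, upper quartile
#' about 7-8) and per-arm subject counts are LogNormal(log 430, 0.6), so a
#' SNP's combined case+control sample size has median about 5500. Error
#' channels (publication bias, strand/label errors, HWE contamination) are
#' off unless switched on.
#'
#' @param seed master RNG seed; per-SNP streams are derived from it so each
#'   SNP is reproducible independently of dataset order.
#' @param n_snps number of SNPs.
#' @param k_min,k_geom_prob studies per SNP: `k_min + rgeom(k_geom_prob)`.
#' @param n_meanlog,n_sdlog per-arm subject counts: LogNormal parameters.
#' @param maf_range control minor-allele frequency range (uniform per SNP
#'   and population).
#' @param theta true log odds ratio (scalar, or vector of length `n_snps`).
#' @param tau2 between-study variance of per-study true effects.
#' @param pub_alpha,pub_gamma publication rule: a study is published if its
#'   own two-sided Wald p < `pub_alpha`, else with probability `pub_gamma`
#'   (`pub_gamma = 1` disables bias).
#' @param strand_error_rate probability a published study reports its
#'   alleles on the reverse strand.
#' @param label_error_rate probability a study's allele labels are swapped
#'   (counts left attached to the wrong labels).
#' @param hwe_f inbreeding coefficient applied to contaminated studies'
#'   genotypes.
#' @param hwe_violation_rate fraction of case-control studies contaminated
#'   with `hwe_f`.
#' @param frac_trio fraction of studies that are family trios.
#' @param frac_stats_only fraction of case-control studies reduced to
#'   OR + p or OR + CI at reporting time.
#' @param stats_ci_prob among statistics-only studies, probability the CI is
#'   reported (otherwise the p-value).
#' @param palindromic_rate probability a SNP's allele pair is complementary
#'   (A/T or C/G).
#' @param asian_prob probability a study's ancestry is Asian (else
#'   Caucasian).
#' @param gwas_cohorts optional list of cohort specs for
#'   [simulate_gwas_summary()], each with `cohort_id`, `n_case`, `n_ctrl`
#'   and optionally `ancestry`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_snps = 20L,
                              k_min = 4L, k_geom_prob = 0.32,
                              n_meanlog = log(430), n_sdlog = 0.6,
                              maf_range = c(0.05, 0.5),
                              theta = 0, tau2 = 0.02,
                              pub_alpha = 0.05, pub_gamma = 1,
                              strand_error_rate = 0,
                              label_error_rate = 0,
                              hwe_f = 0.3, hwe_violation_rate = 0,
                              frac_trio = 0.1, frac_stats_only = 0.2,
                              stats_ci_prob = 0.5,
                              palindromic_rate = 0.15,
                              asian_prob = 0.5,
                              gwas_cohorts = NULL) {
  cfg <- as.list(environment())
  rates <- c(cfg$pub_gamma, cfg$strand_error_rate, cfg$label_error_rate,
             cfg$hwe_violation_rate, cfg$frac_trio, cfg$frac_stats_only,
             cfg$stats_ci_prob, cfg$palindromic_rate, cfg$asian_prob)
  if (any(rates < 0 | rates > 1))
    stop_snpmeta("all rates must lie in [0, 1]",
                 class = "snpmeta_simulation_error")
  if (cfg$tau2 < 0)
    stop_snpmeta("tau2 must be >= 0", class = "snpmeta_simulation_error")
  structure(cfg, class = "simulation_config")
}

# deterministic per-SNP seed below 2^31, derived from the master seed
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

empty_study_row <- function() {
  row <- as.data.frame(setNames(as.list(rep(NA_real_, length(STUDY_COLUMNS))),
                                STUDY_COLUMNS))
  for (col in c("study_id", "pubmed_id", "snp_id", "ancestry", "design",
                "allele1", "allele2"))
    row[[col]] <- NA_character_
  row
}

# genotype probabilities at allele frequency p with inbreeding coefficient f
genotype_probs <- function(p, f = 0) {
  q <- 1 - p
  c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
}

#' Simulate one case-control study
#'
#' Control genotypes are multinomial under Hardy-Weinberg equilibrium (or
#' with inbreeding `f`) at the control frequency of the effect allele; case
#' genotypes likewise at `plogis(qlogis(maf) + theta_i)`, the per-allele
#' odds model matching the allelic odds ratio the pipeline estimates.
#' Allele counts are derived from the genotypes, so both payloads are
#' always consistent.
#'
#' @param theta_i this study's true log odds ratio (drawn upstream around
#'   the SNP effect).
#' @param maf control frequency of the effect allele.
#' @param n_case,n_ctrl subjects per arm.
#' @param f inbreeding coefficient (0 = Hardy-Weinberg).
#' @return a one-row study-table data frame with genotype and allele
#'   payloads (identity columns unset).
#' @export
simulate_case_control_study <- function(theta_i, maf, n_case, n_ctrl,
                                        f = 0) {
  p_ctrl <- maf
  p_case <- stats::plogis(stats::qlogis(maf) + theta_i)
  g_case <- as.vector(rmultinom(1, n_case, genotype_probs(p_case, f)))
  g_ctrl <- as.vector(rmultinom(1, n_ctrl, genotype_probs(p_ctrl, f)))
  row <- empty_study_row()
  row$design <- "case_control"
  row[c("case_AA", "case_Aa", "case_aa")] <- as.list(g_case)
  row[c("ctrl_AA", "ctrl_Aa", "ctrl_aa")] <- as.list(g_ctrl)
  row$case_A <- 2 * g_case[1] + g_case[2]
  row$case_a <- 2 * g_case[3] + g_case[2]
  row$ctrl_A <- 2 * g_ctrl[1] + g_ctrl[2]
  row$ctrl_a <- 2 * g_ctrl[3] + g_ctrl[2]
  row$reported_freq_allele1 <- row$ctrl_A / (row$ctrl_A + row$ctrl_a)
  row
}

#' Simulate one family trio study
#'
#' Transmissions of the effect allele from heterozygous parents are
#' binomial with probability `plogis(theta_i)`.
#'
#' @param theta_i the study's true log relative risk.
#' @param n_trios number of informative transmissions.
#' @return a one-row study-table data frame with a trio payload.
#' @export
simulate_trio_study <- function(theta_i, n_trios) {
  ct <- rbinom(1, n_trios, stats::plogis(theta_i))
  row <- empty_study_row()
  row$design <- "family"
  row$trio_T <- ct
  row$trio_N <- n_trios - ct
  row
}

#' Apply publication bias and reporting errors to simulated studies
#'
#' Each study is retained according to the publication rule applied to its
#' own Wald p-value (`p < pub_alpha`, else with probability `pub_gamma`).
#' Retained case-control studies are then reduced to statistics-only
#' records (counts stripped, OR with CI or p kept) with probability
#' `frac_stats_only`; allele letters are complemented (strand error) with
#' probability `strand_error_rate`, and allele labels swapped with the
#' counts left in place (label error) with probability `label_error_rate`.
#'
#' @param studies a study-table data frame.
#' @param config a [simulation_config()].
#' @return the published subset with injected errors.
#' @export
apply_reporting_filters <- function(studies, config) {
  keep <- logical(nrow(studies))
  for (i in seq_len(nrow(studies))) {
    est <- extract_effect(studies[i, ])
    p <- wald_p(est$ae, est$se_ae)
    keep[i] <- p < config$pub_alpha || runif(1) < config$pub_gamma
  }
  studies <- studies[keep, , drop = FALSE]
  if (!nrow(studies)) return(studies)
  for (i in seq_len(nrow(studies))) {
    row <- studies[i, ]
    if (row$design == "case_control" &&
        runif(1) < config$frac_stats_only) {
      est <- effect_from_allele_counts(row$case_A, row$case_a,
                                       row$ctrl_A, row$ctrl_a)
      row$or_value <- exp(est$ae)
      # a p-value cannot carry the standard error when OR = 1 exactly,
      # so such studies report their CI
      if (est$ae == 0 || runif(1) < config$stats_ci_prob) {
        ci <- exp(ci95(est$ae, est$se_ae))
        row$ci_low <- ci[1]
        row$ci_up <- ci[2]
      } else {
        row$p_value <- max(wald_p(est$ae, est$se_ae), 1e-300)
      }
      row[c("case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa",
            "ctrl_aa", "case_A", "case_a", "ctrl_A", "ctrl_a")] <-
        NA_real_
      # keep the reported control frequency: statistics-only reports can
      # still be frequency-checked during harmonization
    }
    if (runif(1) < config$strand_error_rate) {
      row$allele1 <- complement_allele(row$allele1)
      row$allele2 <- complement_allele(row$allele2)
    }
    if (runif(1) < config$label_error_rate) {
      a1 <- row$allele1
      row$allele1 <- row$allele2
      row$allele2 <- a1
      # counts and reported frequency stay put: that is the error
    }
    studies[i, ] <- row
  }
  rownames(studies) <- NULL
  studies
}

random_allele_pair <- function(palindromic) {
  a1 <- sample(NUCLEOTIDES, 1)
  if (palindromic) return(c(a1, complement_allele(a1)))
  a2 <- sample(setdiff(NUCLEOTIDES, c(a1, complement_allele(a1))), 1)
  c(a1, a2)
}

#' Simulate a full dataset (study table, reference panel, truth)
#'
#' Draws per-SNP allele pairs, ancestry-specific control frequencies and
#' study collections, applies the reporting filters, and builds the
#' matching reference table (minor/major alleles and MAF per population).
#' Each SNP uses an RNG stream seeded from the master seed and the SNP
#' index, so per-SNP results do not depend on dataset order.
#'
#' @param config a [simulation_config()].
#' @return a list: `studies` (study-table data frame), `reference`
#'   (`reference_table`), `truth` (per-SNP data frame with `snp_id, theta,
#'   maf_EAS, maf_EUR, allele1, allele2, palindromic`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  theta <- rep_len(config$theta, config$n_snps)
  studies <- list()
  ref_rows <- list()
  truth <- list()
  for (s in seq_len(config$n_snps)) {
    set.seed(derive_seed(config$seed, s))
    snp_id <- sprintf("rs%06d", s)
    palindromic <- runif(1) < config$palindromic_rate
    alleles <- random_allele_pair(palindromic)
    maf <- setNames(runif(2, config$maf_range[1], config$maf_range[2]),
                    c("EAS", "EUR"))
    k <- config$k_min + rgeom(1, config$k_geom_prob)
    snp_studies <- list()
    for (j in seq_len(k)) {
      theta_j <- rnorm(1, theta[s], sqrt(config$tau2))
      ancestry <- if (runif(1) < config$asian_prob) "Asian" else "Caucasian"
      pop <- c(Asian = "EAS", Caucasian = "EUR")[[ancestry]]
      if (runif(1) < config$frac_trio) {
        n_tr <- max(10L, round(rlnorm(1, config$n_meanlog, config$n_sdlog)))
        row <- simulate_trio_study(theta_j, n_tr)
      } else {
        n_case <- max(20L, round(rlnorm(1, config$n_meanlog,
                                        config$n_sdlog)))
        n_ctrl <- max(20L, round(rlnorm(1, config$n_meanlog,
                                        config$n_sdlog)))
        f <- if (runif(1) < config$hwe_violation_rate) config$hwe_f else 0
        row <- simulate_case_control_study(theta_j, maf[[pop]],
                                           n_case, n_ctrl, f = f)
      }
      row$study_id <- sprintf("%s_study%02d", snp_id, j)
      row$pubmed_id <- sprintf("PM%07d", s * 100 + j)
      row$snp_id <- snp_id
      row$ancestry <- ancestry
      row$allele1 <- alleles[1]
      row$allele2 <- alleles[2]
      snp_studies[[j]] <- row
    }
    snp_df <- do.call(rbind, snp_studies)
    snp_df <- apply_reporting_filters(snp_df, config)
    studies[[s]] <- snp_df
    for (pop in c("EAS", "EUR")) {
      m <- maf[[pop]]
      ref_rows[[paste(snp_id, pop)]] <- data.frame(
        snp_id = snp_id, population = pop,
        minor_allele = if (m <= 0.5) alleles[1] else alleles[2],
        maf = min(m, 1 - m),
        major_allele = if (m <= 0.5) alleles[2] else alleles[1],
        stringsAsFactors = FALSE)
    }
    truth[[s]] <- data.frame(snp_id = snp_id, theta = theta[s],
                             maf_EAS = maf[["EAS"]], maf_EUR = maf[["EUR"]],
                             allele1 = alleles[1], allele2 = alleles[2],
                             palindromic = palindromic,
                             stringsAsFactors = FALSE)
  }
  studies <- do.call(rbind, studies)
  rownames(studies) <- NULL
  list(studies = studies,
       reference = as_reference_table(do.call(rbind, ref_rows)),
       truth = do.call(rbind, truth))
}

#' Simulate GWAS summary files
#'
#' Per-cohort effects are Normal around the true log odds ratio with the
#' standard error implied by the cohort's sample size and allele frequency:
#' `se^2 = (1/n_case + 1/n_ctrl) / (2 maf (1 - maf))`.
#'
#' @param truth the `truth` table from [simulate_dataset()] (or any data
#'   frame with `snp_id, theta, maf_EAS, allele1, allele2`).
#' @param cohorts list of cohort specs: `cohort_id`, `n_case`, `n_ctrl`,
#'   optional `ancestry` (default `"Asian"`).
#' @param seed RNG seed.
#' @return a named list of `gwas_summary` data frames, one per cohort.
#' @export
simulate_gwas_summary <- function(truth, cohorts, seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  out <- list()
  for (coh in cohorts) {
    ancestry <- coh$ancestry %||% "Asian"
    maf <- truth$maf_EAS
    se <- sqrt((1 / coh$n_case + 1 / coh$n_ctrl) / (2 * maf * (1 - maf)))
    beta <- rnorm(nrow(truth), truth$theta, se)
    df <- data.frame(
      snp_id = truth$snp_id,
      effect_allele = truth$allele1,
      other_allele = truth$allele2,
      beta = beta, se = se, p = wald_p(beta, se),
      n = coh$n_case + coh$n_ctrl,
      frq = maf,
      cohort_id = coh$cohort_id, ancestry = ancestry,
      converted_from_or = FALSE,
      stringsAsFactors = FALSE)
    class(df) <- c("gwas_summary", class(df))
    out[[coh$cohort_id]] <- df
  }
  out
}

#' Write a simulated dataset to disk in the pipeline's TSV formats
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`studies.tsv`, `reference.tsv`).
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(studies = file.path(dir, "studies.tsv"),
             reference = file.path(dir, "reference.tsv"))
  write_study_table(sim$studies, paths["studies"])
  write_reference_table(sim$reference, paths["reference"])
  invisible(paths)
}
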