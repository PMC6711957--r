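#' @name harmonization_qc
#' @title Allele harmonization and quality control
#' @description Every study's effect is re-expressed for the reference
#'   panel's minor allele on the forward strand. Label errors are detected by
#'   comparing the reported control frequency with the reference MAF; strand
#'   errors by allele identity versus the complementary pair; palindromic
#'   (A/T, C/G) variants are oriented by frequency or excluded when the
#'   reference MAF is too close to 0.5 to decide.
NULL

new_harmonized_study <- function(effect, action, note, record,
                                 population = NA_character_,
                                 allele1 = NA_character_,
                                 allele2 = NA_character_) {
  structure(
    list(effect = effect, action = action, note = note,
         snp_id = record$snp_id, study_id = record$study_id,
         ancestry = record$ancestry, design = record$design,
         population = population, allele1 = allele1, allele2 = allele2,
         included = !startsWith(action, "excluded")),
    class = "harmonized_study"
  )
}

# reported frequency of allele1 in controls: explicit report first,
# otherwise derived from control counts
control_freq_allele1 <- function(record) {
  if (!is.na(record$reported_freq_allele1))
    return(record$reported_freq_allele1)
  if (has_allele_payload(record)) {
    tot <- record$ctrl_A + record$ctrl_a
    if (tot > 0) return(record$ctrl_A / tot)
  }
  if (has_genotype_payload(record)) {
    tot <- 2 * (record$ctrl_AA + record$ctrl_Aa + record$ctrl_aa)
    if (tot > 0) return((2 * record$ctrl_AA + record$ctrl_Aa) / tot)
  }
  NA_real_
}

negate_effect <- function(effect) {
  effect$ae <- -effect$ae
  if (!is.null(effect$table))
    effect$table <- c(case_A = unname(effect$table["case_a"]),
                      case_a = unname(effect$table["case_A"]),
                      ctrl_A = unname(effect$table["ctrl_a"]),
                      ctrl_a = unname(effect$table["ctrl_A"]))
  effect
}

#' Align one study to the reference panel
#'
#' Decision procedure: (1) alleles matching the reference pair are checked
#' for frequency concordance — a reported minor-allele frequency deviating
#' from the reference MAF by more than `switch_maf_delta` while matching
#' `1 - MAF` within `switch_match_tol` marks switched labels and negates the
#' effect; (2) alleles matching only the complementary pair are flipped to
#' the forward strand and then checked as in (1); (3) palindromic pairs go
#' through [resolve_palindromic()]; (4) alleles matching neither orientation
#' are excluded as unresolved. After harmonization the effect always refers
#' to the reference minor allele, so a study that legitimately reported the
#' major allele is also sign-flipped (action `allele_switched`, with a note
#' distinguishing orientation from a detected label error).
#'
#' @param record a one-row study-table data frame.
#' @param reference a `reference_table`.
#' @param config a [meta_config()].
#' @param effect optionally, the already-extracted `effect_estimate` for the
#'   record (computed via [extract_effect()] if omitted).
#' @return a `harmonized_study`: the (possibly sign-flipped) effect, the
#'   action taken (`unchanged`, `allele_switched`, `strand_flipped`,
#'   `strand_flipped_and_switched`, `excluded_ambiguous`,
#'   `excluded_unresolved`), and a free-text note. SNPs absent from the
#'   reference are passed through unchanged with a warning note.
#' @export
align_to_reference <- function(record, reference, config = meta_config(),
                               effect = NULL) {
  config <- as_meta_config(config)
  if (is.null(effect)) effect <- extract_effect(record, config)
  pop_map <- config$ancestry_population
  population <- if (record$ancestry %in% names(pop_map))
    pop_map[[record$ancestry]] else NA_character_
  ref <- ref_lookup(reference, record$snp_id, population)
  a1 <- record$allele1; a2 <- record$allele2

  if (!ref$found)
    return(new_harmonized_study(
      effect, "unchanged",
      "SNP/population absent from reference; no frequency or strand check",
      record, population, a1, a2))

  if (is_palindromic(a1, a2))
    return(resolve_palindromic(record, reference, config, effect = effect,
                               population = population))

  ref_pair <- c(ref$minor_allele, ref$major_allele)
  strand_flipped <- FALSE
  if (!setequal(c(a1, a2), ref_pair)) {
    if (setequal(complement_allele(c(a1, a2)), ref_pair)) {
      a1 <- complement_allele(a1)
      a2 <- complement_allele(a2)
      strand_flipped <- TRUE
    } else {
      return(new_harmonized_study(
        NULL, "excluded_unresolved",
        sprintf("alleles %s/%s match neither reference pair %s/%s nor its complement",
                record$allele1, record$allele2, ref_pair[1], ref_pair[2]),
        record, population))
    }
  }

  f1 <- control_freq_allele1(record)  # strand-invariant
  f_minor <- if (is.na(f1)) NA_real_
             else if (a1 == ref$minor_allele) f1 else 1 - f1

  label_switched <- FALSE
  note <- if (strand_flipped) "complemented to forward strand" else ""
  if (!is.na(f_minor)) {
    if (abs(f_minor - ref$maf) > config$switch_maf_delta &&
        abs(f_minor - (1 - ref$maf)) <= config$switch_match_tol) {
      label_switched <- TRUE
      note <- paste0(note, if (nzchar(note)) "; ",
                     sprintf("reported minor-allele frequency %.3f contradicts reference MAF %.3f; labels switched",
                             f_minor, ref$maf))
    } else if (abs(f_minor - ref$maf) > config$switch_maf_delta) {
      note <- paste0(note, if (nzchar(note)) "; ",
                     sprintf("frequency %.3f deviates from reference MAF %.3f but does not match the switched labelling; left unchanged",
                             f_minor, ref$maf))
    }
  }

  # nucleotide the effect actually refers to, after undoing any label error
  effect_nucleotide <- if (label_switched) a2 else a1
  negate <- effect_nucleotide == ref$major_allele
  if (negate) {
    effect <- negate_effect(effect)
    if (!label_switched)
      note <- paste0(note, if (nzchar(note)) "; ",
                     "re-oriented to the reference minor allele")
  }

  action <- if (strand_flipped && negate) "strand_flipped_and_switched"
            else if (strand_flipped) "strand_flipped"
            else if (negate) "allele_switched"
            else "unchanged"
  new_harmonized_study(effect, action, note, record, population,
                       ref$minor_allele, ref$major_allele)
}

#' Orient or exclude a palindromic variant
#'
#' A/T and C/G variants carry no strand information in their labels, so
#' orientation comes from frequency alone: when the reference MAF lies inside
#' `palindromic_window` (default 0.4-0.6) the study is excluded as
#' ambiguous; otherwise a reported frequency on the same side of 0.5 as the
#' reference MAF leaves the record unchanged and one on the opposite side
#' negates the effect (`allele_switched`). Records without any frequency
#' information are excluded.
#'
#' @inheritParams align_to_reference
#' @param population reference population (resolved from ancestry when
#'   called directly).
#' @return a `harmonized_study`.
#' @export
resolve_palindromic <- function(record, reference, config = meta_config(),
                                effect = NULL, population = NULL) {
  config <- as_meta_config(config)
  if (is.null(effect)) effect <- extract_effect(record, config)
  if (is.null(population)) {
    pop_map <- config$ancestry_population
    population <- if (record$ancestry %in% names(pop_map))
      pop_map[[record$ancestry]] else NA_character_
  }
  if (!is_palindromic(record$allele1, record$allele2))
    stop_snpmeta("record alleles are not complementary",
                 class = "snpmeta_harmonization_error")
  ref <- ref_lookup(reference, record$snp_id, population)
  if (!ref$found)
    return(new_harmonized_study(
      effect, "unchanged",
      "palindromic SNP absent from reference; orientation unverified",
      record, population, record$allele1, record$allele2))
  win <- config$palindromic_window
  if (ref$maf >= win[1] && ref$maf <= win[2])
    return(new_harmonized_study(
      NULL, "excluded_ambiguous",
      sprintf("palindromic SNP with reference MAF %.3f inside the ambiguity window [%.2f, %.2f]",
              ref$maf, win[1], win[2]),
      record, population))
  f1 <- control_freq_allele1(record)
  if (is.na(f1) || f1 == 0.5)
    return(new_harmonized_study(
      NULL, "excluded_ambiguous",
      "palindromic SNP without a decisive reported frequency",
      record, population))
  # reference MAF < 0.5 outside the window: minor side of 0.5
  if (f1 < 0.5)
    return(new_harmonized_study(
      effect, "unchanged",
      sprintf("palindromic SNP oriented by frequency (%.3f vs reference MAF %.3f)",
              f1, ref$maf),
      record, population, ref$minor_allele, ref$major_allele))
  new_harmonized_study(
    negate_effect(effect), "allele_switched",
    sprintf("palindromic SNP: reported frequency %.3f on the opposite side of 0.5 from reference MAF %.3f; effect negated",
            f1, ref$maf),
    record, population, ref$minor_allele, ref$major_allele)
}

#' Filter a harmonized stratum for eligibility
#'
#' A SNP x population stratum is meta-analyzed only when at least `min_k`
#' (default 4) non-excluded studies remain after harmonization.
#'
#' @param harmonized a list of `harmonized_study` objects for one stratum.
#' @param config a [meta_config()].
#' @return a list with `included` (the usable studies), `k`, `n_excluded`
#'   and `eligible`.
#' @export
eligibility_filter <- function(harmonized, config = meta_config()) {
  config <- as_meta_config(config)
  usable <- Filter(function(h) isTRUE(h$included), harmonized)
  list(included = usable, k = length(usable),
       n_excluded = length(harmonized) - length(usable),
       eligible = length(usable) >= config$min_k)
}
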