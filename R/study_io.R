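#' @name study_io
#' @title Tabular input/output for study records, reference frequencies and
#'   GWAS summary statistics
#' @description The pipeline consumes three tab-separated formats: a study
#'   table (one row per study x SNP, mixed payloads), a reference
#'   allele-frequency table emulating a population panel, and GWAS
#'   summary-statistic files. Readers validate every row; rows failing an
#'   invariant are reported with their row number and reason, never silently
#'   dropped.
NULL

STUDY_COLUMNS <- c(
  "study_id", "pubmed_id", "snp_id", "ancestry", "design",
  "allele1", "allele2",
  "case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa",
  "case_A", "case_a", "ctrl_A", "ctrl_a",
  "or_value", "p_value", "ci_low", "ci_up",
  "trio_T", "trio_N", "reported_freq_allele1"
)

STUDY_COUNT_COLUMNS <- c(
  "case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa",
  "case_A", "case_a", "ctrl_A", "ctrl_a", "trio_T", "trio_N"
)

REFERENCE_COLUMNS <- c("snp_id", "population", "minor_allele", "maf",
                       "major_allele")

ANCESTRY_LEVELS <- c("Asian", "Caucasian", "Other")
DESIGN_LEVELS <- c("case_control", "family")
POPULATION_LEVELS <- c("AFR", "EAS", "EUR", "SAS")

# ---- payload detection -----------------------------------------------------

has_genotype_payload <- function(row) {
  all(!is.na(unlist(row[c("case_AA", "case_Aa", "case_aa",
                          "ctrl_AA", "ctrl_Aa", "ctrl_aa")])))
}

has_allele_payload <- function(row) {
  all(!is.na(unlist(row[c("case_A", "case_a", "ctrl_A", "ctrl_a")])))
}

has_statistics_payload <- function(row) {
  !is.na(row$or_value) &&
    (!is.na(row$p_value) || (!is.na(row$ci_low) && !is.na(row$ci_up)))
}

has_trio_payload <- function(row) {
  !is.na(row$trio_T) && !is.na(row$trio_N)
}

# ---- row validation --------------------------------------------------------

validate_study_row <- function(row) {
  reasons <- character()
  bad <- function(msg) reasons <<- c(reasons, msg)

  if (is.na(row$study_id) || !nzchar(row$study_id)) bad("missing study_id")
  if (is.na(row$snp_id) || !nzchar(row$snp_id)) bad("missing snp_id")
  if (is.na(row$ancestry) || !row$ancestry %in% ANCESTRY_LEVELS)
    bad(sprintf("ancestry must be one of %s",
                paste(ANCESTRY_LEVELS, collapse = "/")))
  if (is.na(row$design) || !row$design %in% DESIGN_LEVELS)
    bad(sprintf("design must be one of %s",
                paste(DESIGN_LEVELS, collapse = "/")))
  if (is.na(row$allele1) || !row$allele1 %in% NUCLEOTIDES)
    bad("allele1 must be A/C/G/T")
  if (is.na(row$allele2) || !row$allele2 %in% NUCLEOTIDES)
    bad("allele2 must be A/C/G/T")
  if (!is.na(row$allele1) && !is.na(row$allele2) &&
      identical(row$allele1, row$allele2))
    bad("allele1 and allele2 are identical")

  for (col in STUDY_COUNT_COLUMNS) {
    v <- row[[col]]
    if (!is.na(v) && !is_count(v))
      bad(sprintf("%s must be a non-negative integer (got %s)", col,
                  format(v)))
  }

  gen <- has_genotype_payload(row)
  all_ <- has_allele_payload(row)
  sta <- has_statistics_payload(row)
  tri <- has_trio_payload(row)
  if (!any(gen, all_, sta, tri))
    bad("no usable payload (genotype, allele, statistics or trio)")

  if (gen && all_) {
    consistent <-
      isTRUE(all.equal(2 * row$case_AA + row$case_Aa, row$case_A)) &&
      isTRUE(all.equal(2 * row$case_aa + row$case_Aa, row$case_a)) &&
      isTRUE(all.equal(2 * row$ctrl_AA + row$ctrl_Aa, row$ctrl_A)) &&
      isTRUE(all.equal(2 * row$ctrl_aa + row$ctrl_Aa, row$ctrl_a))
    if (!consistent) bad("genotype counts contradict allele counts")
  }

  if (sta) {
    if (row$or_value <= 0) bad("or_value must be > 0")
    if (!is.na(row$p_value) && (row$p_value <= 0 || row$p_value >= 1))
      bad("p_value must lie in (0,1)")
    if (!is.na(row$ci_low) && !is.na(row$ci_up)) {
      if (!(row$ci_low < row$or_value && row$or_value < row$ci_up))
        bad("confidence interval must satisfy ci_low < OR < ci_up")
    }
  }

  if (tri && !identical(row$design, "family"))
    bad("trio counts require design = family")
  if (identical(row$design, "family") && !tri)
    bad("family design requires trio counts")
  if (identical(row$design, "case_control") && !any(gen, all_, sta))
    bad("case_control design requires a case-control payload")

  if (!is.na(row$reported_freq_allele1) &&
      (row$reported_freq_allele1 < 0 || row$reported_freq_allele1 > 1))
    bad("reported_freq_allele1 must lie in [0,1]")

  reasons
}

#' Validate a data frame of study records
#'
#' @param df a data frame with the study-table columns (see
#'   [read_study_table()] for the format).
#' @return a list with `records` (the valid rows, class `study_table`) and
#'   `problems` (a data frame with `row` and `reason` for every rejected row).
#' @export
validate_study_records <- function(df) {
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols))
    stop_snpmeta("study table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "snpmeta_schema_error")
  df <- df[STUDY_COLUMNS]
  for (col in c("study_id", "pubmed_id", "snp_id", "ancestry", "design",
                "allele1", "allele2"))
    df[[col]] <- as.character(df[[col]])
  numeric_cols <- setdiff(STUDY_COLUMNS,
                          c("study_id", "pubmed_id", "snp_id", "ancestry",
                            "design", "allele1", "allele2"))
  problems <- list()
  for (col in numeric_cols) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(num)
    for (i in which(bad))
      problems[[length(problems) + 1L]] <-
        data.frame(row = i, reason = sprintf("%s is not numeric: '%s'",
                                             col, raw[i]))
    df[[col]] <- num
  }
  rows_with_parse_errors <-
    if (length(problems)) unique(vapply(problems, `[[`, 0, "row")) else integer()

  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (i %in% rows_with_parse_errors) next
    reasons <- validate_study_row(df[i, ])
    if (length(reasons)) {
      for (r in reasons)
        problems[[length(problems) + 1L]] <- data.frame(row = i, reason = r)
    } else keep[i] <- TRUE
  }
  problems <- if (length(problems)) do.call(rbind, problems)
              else data.frame(row = integer(), reason = character())
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("study_table", class(records))
  list(records = records, problems = problems[order(problems$row), ,
                                              drop = FALSE])
}

# ---- readers ---------------------------------------------------------------

#' Read a study table
#'
#' Reads the tab-separated study table (one row per study x SNP). Columns:
#' `study_id, pubmed_id, snp_id, ancestry, design, allele1, allele2,
#' case_AA, case_Aa, case_aa, ctrl_AA, ctrl_Aa, ctrl_aa, case_A, case_a,
#' ctrl_A, ctrl_a, or_value, p_value, ci_low, ci_up, trio_T, trio_N,
#' reported_freq_allele1`. Empty cells mark absent payloads; each row must
#' carry at least one complete payload (genotype counts, allele counts,
#' OR with p or 95% CI, or trio transmission counts).
#'
#' @param path path to the TSV file.
#' @return as [validate_study_records()]: valid `records` plus located
#'   `problems`.
#' @export
read_study_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = c("", "NA"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_study_records(df)
}

#' Read a reference allele-frequency table
#'
#' Columns: `snp_id, population, minor_allele, maf, major_allele`, one row
#' per SNP x population, MAF in `[0, 0.5]`.
#'
#' @param path path to the TSV file.
#' @return a `reference_table` data frame; query it with [ref_lookup()].
#' @export
read_reference_frequencies <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  as_reference_table(df)
}

#' @rdname read_reference_frequencies
#' @param df a data frame with the reference-table columns.
#' @export
as_reference_table <- function(df) {
  missing_cols <- setdiff(REFERENCE_COLUMNS, names(df))
  if (length(missing_cols))
    stop_snpmeta("reference table is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "snpmeta_schema_error")
  df$maf <- as.numeric(df$maf)
  bad <- is.na(df$maf) | df$maf < 0 | df$maf > 0.5
  if (any(bad))
    stop_snpmeta("reference MAF outside [0, 0.5] in row(s): ",
                 paste(which(bad), collapse = ", "),
                 class = "snpmeta_validation_error")
  if (any(!df$population %in% POPULATION_LEVELS))
    stop_snpmeta("population must be one of ",
                 paste(POPULATION_LEVELS, collapse = "/"),
                 class = "snpmeta_validation_error")
  same <- df$minor_allele == df$major_allele
  if (any(same))
    stop_snpmeta("minor and major alleles identical in row(s): ",
                 paste(which(same), collapse = ", "),
                 class = "snpmeta_validation_error")
  class(df) <- c("reference_table", class(df))
  df
}

#' Query the reference panel for one SNP in one population
#'
#' @param reference a `reference_table`.
#' @param snp_id,population the query key.
#' @return a list with `found` (logical); when found, also `minor_allele`,
#'   `major_allele` and `maf`. A missing (SNP, population) pair returns
#'   `found = FALSE` rather than an error.
#' @export
ref_lookup <- function(reference, snp_id, population) {
  if (is.na(population))
    return(list(found = FALSE, snp_id = snp_id, population = NA_character_))
  hit <- which(reference$snp_id == snp_id & reference$population == population)
  if (!length(hit))
    return(list(found = FALSE, snp_id = snp_id, population = population))
  row <- reference[hit[1L], ]
  list(found = TRUE, snp_id = snp_id, population = population,
       minor_allele = row$minor_allele, major_allele = row$major_allele,
       maf = row$maf)
}

#' Read a GWAS summary-statistics file
#'
#' Whitespace- or tab-delimited with a header naming `SNP, A1, A2,
#' BETA` (or `OR`), `SE, P, N` and optionally `FRQ` (effect-allele frequency).
#' Odds ratios are converted to the log scale at read time and the conversion
#' recorded in the `converted_from_or` column.
#'
#' @param path path to the file.
#' @param cohort_id label attached to every record.
#' @param ancestry ancestry label for the cohort.
#' @return a list with `records` (class `gwas_summary`: `snp_id,
#'   effect_allele, other_allele, beta, se, p, n, frq, cohort_id, ancestry,
#'   converted_from_or`) and `problems`.
#' @export
read_gwas_summary <- function(path, cohort_id = basename(path),
                              ancestry = "Other") {
  df <- read.table(path, header = TRUE, na.strings = c("", "NA", "."),
                   stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  needed <- c("SNP", "A1", "A2", "SE", "P")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop_snpmeta("GWAS file is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "snpmeta_schema_error")
  has_beta <- "BETA" %in% names(df)
  has_or <- "OR" %in% names(df)
  if (!has_beta && !has_or)
    stop_snpmeta("GWAS file must carry a BETA or OR column",
                 class = "snpmeta_schema_error")
  out <- data.frame(
    snp_id = as.character(df$SNP),
    effect_allele = toupper(as.character(df$A1)),
    other_allele = toupper(as.character(df$A2)),
    beta = if (has_beta) as.numeric(df$BETA) else log(as.numeric(df$OR)),
    se = as.numeric(df$SE),
    p = as.numeric(df$P),
    n = if ("N" %in% names(df)) as.numeric(df$N) else NA_real_,
    frq = if ("FRQ" %in% names(df)) as.numeric(df$FRQ) else NA_real_,
    cohort_id = cohort_id,
    ancestry = ancestry,
    converted_from_or = !has_beta && has_or,
    stringsAsFactors = FALSE
  )
  problems <- data.frame(row = integer(), reason = character())
  bad_se <- !is.na(out$se) & out$se <= 0 | is.na(out$se)
  bad_allele <- !(out$effect_allele %in% NUCLEOTIDES) |
    !(out$other_allele %in% NUCLEOTIDES)
  bad_beta <- is.na(out$beta) | !is.finite(out$beta)
  for (i in which(bad_se))
    problems <- rbind(problems,
                      data.frame(row = i, reason = "SE must be > 0"))
  for (i in which(bad_allele & !bad_se))
    problems <- rbind(problems,
                      data.frame(row = i, reason = "alleles must be A/C/G/T"))
  for (i in which(bad_beta & !bad_se & !bad_allele))
    problems <- rbind(problems,
                      data.frame(row = i, reason = "effect is not numeric"))
  keep <- !(bad_se | bad_allele | bad_beta)
  records <- out[keep, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("gwas_summary", class(records))
  list(records = records, problems = problems)
}

# ---- writers ---------------------------------------------------------------

#' Write pipeline results
#'
#' Writes the flat results table as TSV and, when a full run object is given,
#' a JSON report mirroring the table plus per-study harmonization actions and
#' diagnostics.
#'
#' @param results a data frame (e.g. `run$results` from [run_all()]) or a
#'   `meta_run` object.
#' @param path output TSV path; the JSON report (if any) is written next to
#'   it with extension `.json`.
#' @return invisibly, the path(s) written.
#' @export
write_results <- function(results, path) {
  run <- NULL
  if (inherits(results, "meta_run")) {
    run <- results
    results <- run$results
  }
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  paths <- path
  if (!is.null(run)) {
    json_path <- sub("\\.tsv$", ".json", path)
    if (identical(json_path, path)) json_path <- paste0(path, ".json")
    report <- list(
      results = results,
      summary = run$summary,
      harmonization = lapply(run$reports, function(r) r$harmonization),
      diagnostics = lapply(run$reports, function(r)
        lapply(r$strata, function(s) s$diagnostics$studies))
    )
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
    paths <- c(paths, json_path)
  }
  invisible(paths)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return the results data frame.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
             stringsAsFactors = FALSE)
}

#' Write a study table, reference table or GWAS summary to TSV
#'
#' Inverse of the corresponding readers; `read(write(x))` restores `x`.
#'
#' @param x the data frame to write.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_study_table <- function(x, path) {
  stopifnot(all(STUDY_COLUMNS %in% names(x)))
  write.table(x[STUDY_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_study_table
#' @export
write_reference_table <- function(x, path) {
  stopifnot(all(REFERENCE_COLUMNS %in% names(x)))
  write.table(x[REFERENCE_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_study_table
#' @export
write_gwas_summary <- function(x, path) {
  out <- data.frame(SNP = x$snp_id, A1 = x$effect_allele,
                    A2 = x$other_allele, BETA = x$beta, SE = x$se,
                    P = x$p, N = x$n, FRQ = x$frq)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
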