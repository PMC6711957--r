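test_that("study table rows parse into the right payloads", {
  df <- rbind(
    make_record(study_id = "g", case_AA = 10, case_Aa = 20, case_aa = 10,
                ctrl_AA = 12, ctrl_Aa = 18, ctrl_aa = 10),
    make_record(study_id = "s", or_value = 1.5, p_value = 0.05),
    make_record(study_id = "t", design = "family", trio_T = 60, trio_N = 40)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study_table(df, path)
  res <- read_study_table(path)
  expect_equal(nrow(res$records), 3)
  expect_equal(nrow(res$problems), 0)
  expect_equal(select_data_source(res$records[1, ]), "genotype_counts")
  expect_equal(select_data_source(res$records[2, ]), "p_based")
  expect_equal(select_data_source(res$records[3, ]), "trio")
})

test_that("invalid rows are reported with row number and reason, not dropped silently", {
  df <- rbind(
    make_record(study_id = "ok", case_A = 30, case_a = 70, ctrl_A = 20,
                ctrl_a = 80),
    make_record(study_id = "same_alleles", allele2 = "A",
                case_A = 30, case_a = 70, ctrl_A = 20, ctrl_a = 80),
    make_record(study_id = "no_payload"),
    make_record(study_id = "fractional", case_A = 30.5, case_a = 70,
                ctrl_A = 20, ctrl_a = 80),
    make_record(study_id = "inconsistent", case_AA = 10, case_Aa = 20,
                case_aa = 10, ctrl_AA = 12, ctrl_Aa = 18, ctrl_aa = 10,
                case_A = 99, case_a = 40, ctrl_A = 42, ctrl_a = 38)
  )
  res <- validate_study_records(df)
  expect_equal(res$records$study_id, "ok")
  expect_setequal(res$problems$row, 2:5)
  expect_match(res$problems$reason[res$problems$row == 2],
               "identical")
  expect_match(res$problems$reason[res$problems$row == 4],
               "non-negative integer")
  expect_match(res$problems$reason[res$problems$row == 5],
               "contradict")
})

test_that("non-numeric counts and missing columns are schema-level diagnostics", {
  df <- make_record(case_A = 30, case_a = 70, ctrl_A = 20, ctrl_a = 80)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study_table(df, path)
  txt <- readLines(path)
  txt[2] <- sub("\t30\t", "\tthirty\t", txt[2])
  writeLines(txt, path)
  res <- read_study_table(path)
  expect_equal(nrow(res$records), 0)
  expect_match(res$problems$reason, "not numeric")

  df2 <- df[, setdiff(names(df), "snp_id")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_study_table(path2), class = "snpmeta_schema_error")
})

test_that("reference table validates and supports keyed lookup with unknown marker", {
  ref <- ref_table(list("rs1", "EAS", "A", 0.20, "G"),
                   list("rs1", "EUR", "A", 0.35, "G"))
  hit <- ref_lookup(ref, "rs1", "EAS")
  expect_true(hit$found)
  expect_equal(hit$maf, 0.20)
  expect_equal(hit$minor_allele, "A")
  expect_false(ref_lookup(ref, "rs2", "EAS")$found)
  expect_false(ref_lookup(ref, "rs1", "SAS")$found)
  expect_error(ref_table(list("rs1", "EAS", "A", 0.7, "G")),
               class = "snpmeta_validation_error")
  expect_error(ref_table(list("rs1", "EAS", "A", 0.2, "A")),
               class = "snpmeta_validation_error")
})

test_that("GWAS reader converts OR to log scale and flags bad rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 A2 OR SE P N",
               "rs1 A G 1.10 0.02 1e-6 50000",
               "rs2 C T 0.90 0 0.5 50000"), path)
  res <- read_gwas_summary(path, cohort_id = "coh1", ancestry = "Asian")
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$beta, log(1.10))
  expect_true(res$records$converted_from_or)
  expect_equal(res$problems$row, 2)
  expect_match(res$problems$reason, "SE")

  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE\tP\tN",
               "rs1\tA\tG\t0.0953\t0.02\t1e-6\t50000"), path2)
  res2 <- read_gwas_summary(path2)
  expect_equal(res2$records$beta, 0.0953)
  expect_false(res2$records$converted_from_or)
})

test_that("write/read round trips restore study, reference and GWAS tables", {
  sim <- simulate_dataset(simulation_config(seed = 3, n_snps = 3,
                                            frac_trio = 0.2,
                                            frac_stats_only = 0.3))
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  back <- read_study_table(paths[["studies"]])
  expect_equal(nrow(back$problems), 0)
  expect_equal(back$records$study_id, sim$studies$study_id)
  num_cols <- vapply(sim$studies, is.numeric, TRUE)
  for (col in names(sim$studies)[num_cols])
    expect_equal(back$records[[col]], sim$studies[[col]], tolerance = 1e-12,
                 label = col)
  ref_back <- read_reference_frequencies(paths[["reference"]])
  expect_equal(as.data.frame(ref_back), as.data.frame(sim$reference),
               ignore_attr = TRUE)

  g <- simulate_gwas_summary(sim$truth,
                             list(list(cohort_id = "c1", n_case = 2000,
                                       n_ctrl = 2000)), seed = 3)[[1]]
  gpath <- withr::local_tempfile(fileext = ".txt")
  write_gwas_summary(g, gpath)
  g_back <- read_gwas_summary(gpath, cohort_id = "c1", ancestry = "Asian")
  expect_equal(g_back$records$beta, g$beta, tolerance = 1e-12)
  expect_equal(g_back$records$se, g$se, tolerance = 1e-12)
})

test_that("results TSV + JSON report round trip", {
  sim <- simulate_dataset(simulation_config(seed = 5, n_snps = 3))
  run <- run_all(sim$studies, sim$reference)
  path <- withr::local_tempfile(fileext = ".tsv")
  written <- write_results(run, path)
  expect_length(written, 2)
  back <- read_results(path)
  expect_equal(back$snp_id, run$results$snp_id)
  expect_equal(back$or_random, run$results$or_random, tolerance = 1e-9)
  report <- jsonlite::read_json(written[2])
  expect_named(report, c("results", "summary", "harmonization",
                         "diagnostics"))
})
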