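ref1 <- ref_table(list("rs1", "EAS", "A", 0.20, "G"),
                  list("rs1", "EUR", "A", 0.18, "G"))

test_that("concordant records pass through unchanged", {
  rec <- count_record(190, 810, 200, 800, reported_freq_allele1 = 0.19)
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "unchanged")
  expect_true(h$included)
  expect_equal(h$effect$ae, extract_effect(rec)$ae)
})

test_that("a frequency contradicting the labels switches alleles and negates the effect", {
  rec <- make_record(ancestry = "Caucasian", or_value = 1.4,
                     p_value = 0.01, reported_freq_allele1 = 0.82)
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "allele_switched")
  expect_equal(h$effect$ae, -log(1.4), tolerance = 1e-12)
  expect_equal(h$effect$se_ae, extract_effect(rec)$se_ae)
})

test_that("complementary reporting is flipped to the forward strand", {
  # reference is A/G; the study reports T/C with a concordant frequency
  rec <- count_record(190, 810, 200, 800, allele1 = "T", allele2 = "C",
                      reported_freq_allele1 = 0.19)
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$allele1, "A")
  expect_equal(h$effect$ae, extract_effect(rec)$ae)
})

test_that("a study legitimately reporting the major allele is re-oriented", {
  rec <- count_record(810, 190, 800, 200, allele1 = "G", allele2 = "A",
                      reported_freq_allele1 = 0.81)
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "allele_switched")
  expect_match(h$note, "re-oriented")
  expect_equal(h$effect$ae, -extract_effect(rec)$ae, tolerance = 1e-12)
})

test_that("alleles matching neither orientation are excluded as unresolved", {
  rec <- count_record(190, 810, 200, 800, allele1 = "A", allele2 = "C")
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "excluded_unresolved")
  expect_false(h$included)
  expect_null(h$effect)
})

test_that("SNPs absent from the reference pass through with a warning note", {
  rec <- count_record(190, 810, 200, 800, snp_id = "rs_missing")
  h <- align_to_reference(rec, ref1)
  expect_equal(h$action, "unchanged")
  expect_match(h$note, "absent")
})

test_that("palindromic variants resolve by frequency or are excluded", {
  ref_pal <- ref_table(list("rs1", "EAS", "C", 0.10, "G"),
                       list("rs2", "EAS", "A", 0.45, "T"))
  # ambiguity window: excluded regardless of reported frequency
  amb <- make_record(snp_id = "rs2", allele1 = "A", allele2 = "T",
                     or_value = 1.3, p_value = 0.02,
                     reported_freq_allele1 = 0.44)
  h_amb <- align_to_reference(amb, ref_pal)
  expect_equal(h_amb$action, "excluded_ambiguous")
  # concordant side of 0.5: kept
  keep <- make_record(allele1 = "C", allele2 = "G", or_value = 1.3,
                      p_value = 0.02, reported_freq_allele1 = 0.11)
  h_keep <- align_to_reference(keep, ref_pal)
  expect_equal(h_keep$action, "unchanged")
  expect_equal(h_keep$effect$ae, log(1.3), tolerance = 1e-12)
  # opposite side of 0.5: switched, effect negated
  sw <- make_record(allele1 = "C", allele2 = "G", or_value = 1.3,
                    p_value = 0.02, reported_freq_allele1 = 0.88)
  h_sw <- align_to_reference(sw, ref_pal)
  expect_equal(h_sw$action, "allele_switched")
  expect_equal(h_sw$effect$ae, -log(1.3), tolerance = 1e-12)
  # no frequency at all: undecidable
  nofreq <- make_record(allele1 = "C", allele2 = "G", or_value = 1.3,
                        p_value = 0.02)
  expect_equal(align_to_reference(nofreq, ref_pal)$action,
               "excluded_ambiguous")
  expect_error(resolve_palindromic(make_record(or_value = 1.2, p_value = .1),
                                   ref_pal),
               class = "snpmeta_harmonization_error")
})

test_that("harmonization is idempotent: re-aligning corrected records is a no-op", {
  rec <- count_record(810, 190, 800, 200, allele1 = "G", allele2 = "A",
                      reported_freq_allele1 = 0.81)
  h <- align_to_reference(rec, ref1)
  # rebuild the record as harmonization left it: minor-oriented labels,
  # counts and frequency swapped accordingly
  corrected <- count_record(190, 810, 200, 800, allele1 = h$allele1,
                            allele2 = h$allele2,
                            reported_freq_allele1 = 0.19)
  h2 <- align_to_reference(corrected, ref1)
  expect_equal(h2$action, "unchanged")
  expect_equal(h2$effect$ae, h$effect$ae, tolerance = 1e-12)
  expect_equal(h2$effect$se_ae, h$effect$se_ae, tolerance = 1e-12)
})

test_that("pooled estimates are invariant to the strand each study reported", {
  base <- simulation_config(seed = 77, n_snps = 5, palindromic_rate = 0,
                            frac_stats_only = 0.2, frac_trio = 0.1)
  clean <- simulate_dataset(base)
  run_clean <- run_all(clean$studies, clean$reference)
  cfg <- simulation_config(seed = 77, n_snps = 5, palindromic_rate = 0,
                           frac_stats_only = 0.2, frac_trio = 0.1,
                           strand_error_rate = 1)
  noisy <- simulate_dataset(cfg)
  expect_false(identical(noisy$studies$allele1, clean$studies$allele1))
  run_noisy <- run_all(noisy$studies, noisy$reference)
  expect_equal(run_noisy$results$ae_random, run_clean$results$ae_random,
               tolerance = 1e-12)
})

test_that("label errors are corrected wherever the frequency rule has power", {
  # Swapped labels are detectable only when the reference MAF is far enough
  # from 0.5 (the switch rule needs a > 0.2 deviation) and the record
  # carries a control frequency, which trio studies do not; the test
  # therefore runs the label channel under those conditions.
  base <- simulation_config(seed = 78, n_snps = 5, palindromic_rate = 0,
                            maf_range = c(0.05, 0.30), frac_trio = 0,
                            frac_stats_only = 0.2)
  clean <- simulate_dataset(base)
  run_clean <- run_all(clean$studies, clean$reference)
  for (label_rate in c(1, 0.5)) {
    cfg <- simulation_config(seed = 78, n_snps = 5, palindromic_rate = 0,
                             maf_range = c(0.05, 0.30), frac_trio = 0,
                             frac_stats_only = 0.2,
                             label_error_rate = label_rate)
    noisy <- simulate_dataset(cfg)
    run_noisy <- run_all(noisy$studies, noisy$reference)
    expect_equal(run_noisy$results$ae_random, run_clean$results$ae_random,
                 tolerance = 1e-12)
  }
})

test_that("eligibility requires four usable studies per stratum", {
  mk <- function(n, n_excluded = 0) {
    recs <- lapply(seq_len(n), function(i)
      count_record(190, 810, 200, 800, study_id = paste0("s", i),
                   reported_freq_allele1 = 0.19))
    h <- lapply(recs, align_to_reference, reference = ref1)
    if (n_excluded > 0)
      for (i in seq_len(n_excluded)) {
        h[[i]]$included <- FALSE
        h[[i]]$action <- "excluded_ambiguous"
        h[[i]]$effect <- NULL
      }
    h
  }
  expect_true(eligibility_filter(mk(4))$eligible)
  f3 <- eligibility_filter(mk(3))
  expect_false(f3$eligible)
  expect_equal(f3$k, 3)
  f52 <- eligibility_filter(mk(5, n_excluded = 2))
  expect_false(f52$eligible)
  expect_equal(f52$k, 3)
  expect_equal(f52$n_excluded, 2)
})
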