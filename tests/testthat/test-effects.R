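test_that("genotype counts collapse to allele counts", {
  expect_equal(
    genotype_to_allele_counts(10, 20, 10, 12, 18, 10),
    c(case_A = 40, case_a = 40, ctrl_A = 42, ctrl_a = 38))
  expect_equal(unname(genotype_to_allele_counts(0, 0, 0, 5, 0, 0)),
               c(0, 0, 10, 0))
})

test_that("allele-count route reproduces the 2x2 log odds ratio and its standard error", {
  est <- effect_from_allele_counts(30, 70, 20, 80)
  expect_equal(est$ae, log((30 * 80) / (70 * 20)), tolerance = 1e-12)
  expect_equal(est$ae, 0.5389965, tolerance = 1e-6)
  expect_equal(est$se_ae, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)
  expect_equal(est$se_ae, 0.3318419, tolerance = 1e-6)

  sym <- effect_from_allele_counts(10, 10, 10, 10)
  expect_equal(sym$ae, 0)
  expect_equal(sym$se_ae, sqrt(0.4), tolerance = 1e-12)

  # zero cell: all four cells get the 0.5 continuity correction
  cc <- effect_from_allele_counts(0, 10, 10, 10)
  expect_equal(cc$ae, log((0.5 * 10.5) / (10.5 * 10.5)), tolerance = 1e-12)
  expect_equal(cc$se_ae, sqrt(1 / 0.5 + 3 / 10.5), tolerance = 1e-12)

  expect_error(effect_from_allele_counts(0, 0, 10, 10),
               class = "snpmeta_extraction_error")
})

test_that("counts routes are antisymmetric in allele labels and match the Wald chi-square", {
  set.seed(21)
  for (i in 1:20) {
    tab <- as.numeric(random_tables(1)[1, ])
    est <- effect_from_allele_counts(tab[1], tab[2], tab[3], tab[4])
    swapped <- effect_from_allele_counts(tab[2], tab[1], tab[4], tab[3])
    expect_equal(swapped$ae, -est$ae, tolerance = 1e-12)
    expect_equal(swapped$se_ae, est$se_ae, tolerance = 1e-12)
    # (ae/se)^2 is the 2x2 Wald chi-square on the log-odds scale
    expect_equal((est$ae / est$se_ae)^2,
                 est$ae^2 / sum(1 / tab), tolerance = 1e-12)
  }
})

test_that("genotype payloads and their implied allele payloads give identical estimates", {
  set.seed(22)
  for (i in 1:10) {
    g <- c(rmultinom(1, 500, c(.3, .5, .2)), rmultinom(1, 600, c(.25, .5, .25)))
    est_g <- effect_from_genotype_counts(g[1], g[2], g[3], g[4], g[5], g[6])
    est_a <- effect_from_allele_counts(2 * g[1] + g[2], 2 * g[3] + g[2],
                                       2 * g[4] + g[5], 2 * g[6] + g[5])
    expect_equal(est_g$ae, est_a$ae, tolerance = 1e-14)
    expect_equal(est_g$se_ae, est_a$se_ae, tolerance = 1e-14)
  }
  expect_equal(effect_from_genotype_counts(10, 20, 10, 12, 18, 10)$k_cases, 40)
})

test_that("p-based route back-calculates the standard error from the normal quantile approximation", {
  est <- effect_from_pvalue(1.5, 0.05)
  expect_equal(est$ae, log(1.5))
  expect_equal(est$se_ae, log(1.5) / (-0.862 + sqrt(0.743 - 2.404 * log(0.05))),
               tolerance = 1e-12)
  expect_equal(est$se_ae, 0.2072, tolerance = 1e-3)
  expect_equal(effect_from_pvalue(1.5, 0.01)$se_ae, 0.1575, tolerance = 1e-3)
  # protective ORs give the same positive se via |ae|
  expect_equal(effect_from_pvalue(1 / 1.5, 0.05)$se_ae, est$se_ae,
               tolerance = 1e-12)
  expect_error(effect_from_pvalue(1.0, 0.3),
               class = "snpmeta_extraction_error")
  expect_error(effect_from_pvalue(1.5, 1),
               class = "snpmeta_extraction_error")
})

test_that("p-based denominator tracks qnorm(1 - p/2) closely for central p", {
  # measured accuracy band of the closed-form approximation: within 0.5%
  # of the exact quantile for p in [6e-4, 0.23] (wider p drifts to ~2%)
  p <- exp(seq(log(6e-4), log(0.23), length.out = 200))
  approx <- -0.862 + sqrt(0.743 - 2.404 * log(p))
  exact <- qnorm(1 - p / 2)
  expect_lt(max(abs(approx - exact) / exact), 0.005)
  # and the route itself reproduces |ae|/qnorm(1-p/2) to the same accuracy
  se_route <- vapply(p, function(pp) effect_from_pvalue(1.4, pp)$se_ae, 0)
  se_exact <- log(1.4) / exact
  expect_lt(max(abs(se_route - se_exact) / se_exact), 0.005)
})

test_that("CI-based route uses the log-scale interval width", {
  est <- effect_from_ci(1.18, 1.10, 1.25)
  expect_equal(est$se_ae, (log(1.25) - log(1.10)) / (2 * 1.96),
               tolerance = 1e-12)
  expect_equal(est$se_ae, 0.0326, tolerance = 1e-3)
  sym <- effect_from_ci(1, 1 / 1.4, 1.4)
  expect_equal(sym$ae, 0)
  expect_equal(sym$se_ae, log(1.4) / 1.96, tolerance = 1e-12)
  expect_error(effect_from_ci(1.15, 1.2, 1.1),
               class = "snpmeta_extraction_error")
  # audit-only literal form: upper bound minus OR on the ratio scale
  expect_equal(effect_from_ci(1.18, 1.10, 1.25, literal = TRUE)$se_ae,
               1.25 - 1.18, tolerance = 1e-12)
})

test_that("trio route gives the transmission log relative risk", {
  est <- effect_from_trio(60, 40)
  expect_equal(est$ae, log(1.5), tolerance = 1e-12)
  expect_equal(est$se_ae, sqrt(1 / 60 + 1 / 40), tolerance = 1e-12)
  expect_equal(effect_from_trio(50, 50)$ae, 0)
  cc <- effect_from_trio(0, 10)
  expect_equal(cc$ae, log(0.5 / 10.5), tolerance = 1e-12)
  expect_equal(cc$se_ae, sqrt(1 / 0.5 + 1 / 10.5), tolerance = 1e-12)
  expect_error(effect_from_trio(0, 0), class = "snpmeta_extraction_error")
  # audit-only literal form: the variance without the square root
  expect_equal(effect_from_trio(60, 40, literal = TRUE)$se_ae,
               1 / 60 + 1 / 40, tolerance = 1e-12)
})

test_that("data-source priority is genotype > allele > CI > p; trio iff family", {
  rec <- make_record(case_AA = 10, case_Aa = 20, case_aa = 10,
                     ctrl_AA = 12, ctrl_Aa = 18, ctrl_aa = 10,
                     or_value = 1.5, p_value = 0.05)
  expect_equal(select_data_source(rec), "genotype_counts")
  rec2 <- make_record(case_A = 40, case_a = 40, ctrl_A = 42, ctrl_a = 38,
                      or_value = 1.5, p_value = 0.05)
  expect_equal(select_data_source(rec2), "allele_counts")
  rec3 <- make_record(or_value = 1.5, p_value = 0.05, ci_low = 1.1,
                      ci_up = 2.0)
  expect_equal(select_data_source(rec3), "ci_based")
  expect_equal(select_data_source(make_record(or_value = 1.5, p_value = 0.05)),
               "p_based")
  expect_equal(select_data_source(make_record(design = "family", trio_T = 60,
                                              trio_N = 40)), "trio")
  # extract_effect follows the same priority and records the route
  expect_equal(extract_effect(rec)$route, "genotype_counts")
  expect_equal(extract_effect(rec3)$route, "ci_based")
})
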