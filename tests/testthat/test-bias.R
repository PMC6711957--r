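test_that("the asymmetry assessment is gated at ten studies", {
  set.seed(61)
  tabs <- random_tables(9)
  est <- lapply(seq_len(9), function(i)
    do.call(effect_from_allele_counts, as.list(as.numeric(tabs[i, ]))))
  ae <- vapply(est, `[[`, 0, "ae")
  se <- vapply(est, `[[`, 0, "se_ae")
  b <- assess_bias(ae, se, tables = tabs)
  expect_false(b$applicable)
  expect_null(b$test)
  expect_equal(b$k0, 0L)
  expect_equal(b$funnel, funnel_data(ae, se))
})

test_that("a mirror-symmetric funnel has zero intercept", {
  set.seed(62)
  tabs <- random_tables(7)
  mirrored <- tabs[, c("case_a", "case_A", "ctrl_a", "ctrl_A")]
  names(mirrored) <- names(tabs)
  both <- rbind(tabs, mirrored)
  h <- harbord_test(both)
  expect_equal(h$intercept, 0, tolerance = 1e-10)
  expect_gt(h$p, 0.5)
})

test_that("the Harbord intercept is antisymmetric under an effect-sign flip", {
  set.seed(63)
  tabs <- random_tables(12, p_case = 0.35, p_ctrl = 0.3)
  flipped <- tabs[, c("case_a", "case_A", "ctrl_a", "ctrl_A")]
  names(flipped) <- names(tabs)
  a <- harbord_test(tabs)
  b <- harbord_test(flipped)
  expect_equal(b$intercept, -a$intercept, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})

test_that("the score regression agrees with an explicit least-squares oracle", {
  set.seed(64)
  tabs <- random_tables(11, p_case = 0.32)
  h <- harbord_test(tabs)
  a <- tabs$case_A
  n1 <- tabs$case_A + tabs$case_a
  n0 <- tabs$ctrl_A + tabs$ctrl_a
  m <- tabs$case_A + tabs$ctrl_A
  n <- n1 + n0
  z <- a - n1 * m / n
  v <- n1 * n0 * m * (n - m) / (n^2 * (n - 1))
  o <- ols_intercept_oracle(z / sqrt(v), sqrt(v))
  expect_equal(h$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(h$se, o$se, tolerance = 1e-10)
  expect_equal(h$p, o$p, tolerance = 1e-10)
  expect_equal(h$df, 9)
})

test_that("the Egger fallback is used when too few studies carry tables", {
  set.seed(65)
  ae <- rnorm(12, 0.2, 0.2)
  se <- runif(12, 0.05, 0.4)
  tabs <- as.data.frame(matrix(NA_real_, 12, 4,
                               dimnames = list(NULL, c("case_A", "case_a",
                                                       "ctrl_A", "ctrl_a"))))
  b <- assess_bias(ae, se, tables = tabs)
  expect_true(b$applicable)
  expect_equal(b$test$method, "egger")
  o <- ols_intercept_oracle(ae / se, 1 / se)
  expect_equal(b$test$intercept, o$intercept, tolerance = 1e-10)
})

test_that("trim-and-fill leaves symmetric inputs alone and only ever adds studies", {
  ae <- c(-0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3, -0.05, 0.05, 0)
  se <- c(0.3, 0.2, 0.1, 0.05, 0.1, 0.2, 0.3, 0.15, 0.15, 0.25)
  tf <- trim_and_fill(ae, se, side = "left")
  expect_equal(tf$k0, 0L)
  expect_equal(tf$adjusted$random$est,
               dersimonian_laird_meta(ae, se)$random$est, tolerance = 1e-12)
  expect_length(tf$filled_ae, length(ae) + tf$k0)

  set.seed(66)
  y <- c(); s <- c()
  while (length(y) < 14) {
    si <- runif(1, 0.05, 0.5)
    yi <- rnorm(1, 0, si)
    if (yi / si > 0.5) { y <- c(y, yi); s <- c(s, si) }
  }
  tf2 <- trim_and_fill(y, s, side = "left")
  expect_gt(tf2$k0, 0)
  expect_length(tf2$filled_ae, length(y) + tf2$k0)
  # every observed study is still in the filled set
  expect_equal(tf2$filled_ae[seq_along(y)], y)
  expect_equal(tf2$filled_se[seq_along(s)], s)
  # the adjustment pulls the estimate toward the suppressed side
  expect_lt(tf2$adjusted$random$est,
            dersimonian_laird_meta(y, s)$random$est)
})

test_that("trim-and-fill matches metafor for both estimators and sides", {
  set.seed(67)
  y <- c(); s <- c()
  while (length(y) < 13) {
    si <- runif(1, 0.05, 0.5)
    yi <- rnorm(1, 0.1, si)
    if (yi / si > 0.3) { y <- c(y, yi); s <- c(s, si) }
  }
  for (est in c("L0", "R0")) {
    ref_fit <- metafor::trimfill(metafor::rma(yi = y, sei = s, method = "DL"),
                                 estimator = est, side = "left")
    mine <- trim_and_fill(y, s, side = "left", estimator = est)
    expect_equal(mine$k0, ref_fit$k0, ignore_attr = TRUE)
    expect_equal(mine$adjusted$random$est, as.numeric(ref_fit$beta),
                 tolerance = 1e-10)
    expect_equal(mine$adjusted$random$se, ref_fit$se, tolerance = 1e-10)
  }
  ref_r <- metafor::trimfill(metafor::rma(yi = -y, sei = s, method = "DL"),
                             estimator = "L0", side = "right")
  mine_r <- trim_and_fill(-y, s, side = "right", estimator = "L0")
  expect_equal(mine_r$k0, ref_r$k0, ignore_attr = TRUE)
  expect_equal(mine_r$adjusted$random$est, as.numeric(ref_r$beta),
               tolerance = 1e-10)
})

test_that("bias assessment wires the Harbord decision into trim-and-fill", {
  set.seed(68)
  # censored collection with real tables: suppress negative effects
  tabs <- data.frame()
  while (nrow(tabs) < 12) {
    cand <- random_tables(1, p_case = 0.3, p_ctrl = 0.3,
                          n_range = c(100, 1500))
    e <- do.call(effect_from_allele_counts, as.list(as.numeric(cand[1, ])))
    if (e$ae / e$se_ae > 0.6) tabs <- rbind(tabs, cand)
  }
  est <- lapply(seq_len(nrow(tabs)), function(i)
    do.call(effect_from_allele_counts, as.list(as.numeric(tabs[i, ]))))
  ae <- vapply(est, `[[`, 0, "ae")
  se <- vapply(est, `[[`, 0, "se_ae")
  b <- assess_bias(ae, se, tables = tabs)
  expect_true(b$applicable)
  expect_equal(b$test$method, "harbord")
  if (b$bias_detected) {
    expect_gt(b$k0, 0)
    expect_lt(abs(b$adjusted$random$est),
              abs(dersimonian_laird_meta(ae, se)$random$est))
  }
})
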