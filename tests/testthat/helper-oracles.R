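# Independent oracles and fixture builders shared across the suite.

# Direct evaluation of the inverse-variance and DerSimonian-Laird formulas,
# kept free of any package code so pooling results can be checked against it.
dl_oracle <- function(ae, se) {
  w <- 1 / se^2
  mu_f <- sum(w * ae) / sum(w)
  se_f <- sqrt(1 / sum(w))
  q <- sum(w * (ae - mu_f)^2)
  df <- length(ae) - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu_r <- sum(ws * ae) / sum(ws)
  se_r <- sqrt(1 / sum(ws))
  list(mu_f = mu_f, se_f = se_f, q = q, df = df, tau2 = tau2,
       mu_r = mu_r, se_r = se_r,
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
       p_r = 2 * pnorm(-abs(mu_r) / se_r))
}

# Full-enumeration Hardy-Weinberg oracle: walks every genotype triple
# compatible with the table's margins and accumulates multinomial x 2^het
# weights directly.
hwe_enum_oracle <- function(AA, Aa, aa) {
  n <- AA + Aa + aa
  nA <- 2 * AA + Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  wt <- vapply(hets, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- n - hom1 - h
    if (hom1 < 0 || hom2 < 0) return(0)
    exp(lchoose(n, hom1) + lchoose(n - hom1, h) + h * log(2))
  }, numeric(1))
  prob <- wt / sum(wt)
  obs <- prob[match(Aa, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Ordinary least squares by explicit normal equations, as the independent
# route for the regression-based asymmetry tests.
ols_intercept_oracle <- function(y, x) {
  n <- length(y)
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  a <- yb - slope * xb
  res <- y - a - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_a <- sqrt(s2 * (1 / n + xb^2 / sum((x - xb)^2)))
  list(intercept = a, se = se_a, t = a / se_a,
       p = 2 * pt(-abs(a / se_a), df = n - 2))
}

# A complete study-table row with every column present; override by name.
make_record <- function(...) {
  row <- data.frame(
    study_id = "s1", pubmed_id = "PM1", snp_id = "rs1",
    ancestry = "Asian", design = "case_control",
    allele1 = "A", allele2 = "G",
    case_AA = NA_real_, case_Aa = NA_real_, case_aa = NA_real_,
    ctrl_AA = NA_real_, ctrl_Aa = NA_real_, ctrl_aa = NA_real_,
    case_A = NA_real_, case_a = NA_real_, ctrl_A = NA_real_,
    ctrl_a = NA_real_,
    or_value = NA_real_, p_value = NA_real_, ci_low = NA_real_,
    ci_up = NA_real_,
    trio_T = NA_real_, trio_N = NA_real_,
    reported_freq_allele1 = NA_real_,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# A record with an allele-count payload drawn at given frequencies.
count_record <- function(case_A, case_a, ctrl_A, ctrl_a, ...) {
  make_record(case_A = case_A, case_a = case_a, ctrl_A = ctrl_A,
              ctrl_a = ctrl_a, ...)
}

ref_table <- function(...) {
  rows <- list(...)
  as_reference_table(do.call(rbind, lapply(rows, function(r)
    data.frame(snp_id = r[[1]], population = r[[2]], minor_allele = r[[3]],
               maf = as.numeric(r[[4]]), major_allele = r[[5]],
               stringsAsFactors = FALSE))))
}

# Homogeneous stratum of k allele-count studies around a common frequency.
random_tables <- function(k, p_case = 0.3, p_ctrl = 0.3,
                          n_range = c(200, 3000)) {
  tabs <- data.frame(case_A = integer(k), case_a = integer(k),
                     ctrl_A = integer(k), ctrl_a = integer(k))
  for (i in seq_len(k)) {
    n1 <- round(runif(1, n_range[1], n_range[2]))
    n0 <- round(runif(1, n_range[1], n_range[2]))
    a <- rbinom(1, 2 * n1, p_case)
    b <- rbinom(1, 2 * n0, p_ctrl)
    tabs[i, ] <- c(a, 2 * n1 - a, b, 2 * n0 - b)
  }
  tabs
}
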