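#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on a genotype-count triple: conditioning on the
#' total sample size and allele count, the p-value sums the probabilities of
#' all heterozygote counts no more probable than the one observed under the
#' Hardy-Weinberg conditional distribution
#' `P(n_Aa | n, n_A) = (n! / (n_AA! n_Aa! n_aa!)) 2^n_Aa n_A! n_a! / (2n)!`.
#' A chi-square (1 df, no continuity correction) alternative is available via
#' `method = "chisq"`.
#'
#' @param AA,Aa,aa genotype counts (typically the control group).
#' @param alpha significance level for the `violates` flag.
#' @param method `"exact"` or `"chisq"`.
#' @return an `hwe_result` list: `p`, `violates` (`p < alpha`), `method`,
#'   `testable = TRUE`.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(AA, Aa, aa, alpha = 0.05, method = "exact") {
  if (!all(is_count(c(AA, Aa, aa))))
    stop_snpmeta("genotype counts must be non-negative integers",
                 class = "snpmeta_validation_error")
  n <- AA + Aa + aa
  if (n == 0)
    stop_snpmeta("empty genotype table", class = "snpmeta_validation_error")
  nA <- 2 * AA + Aa
  na <- 2 * aa + Aa
  method <- match.arg(method, c("exact", "chisq"))
  if (method == "chisq") {
    p_hat <- nA / (2 * n)
    e <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    o <- c(AA, Aa, aa)
    nonzero <- e > 0
    x2 <- sum((o[nonzero] - e[nonzero])^2 / e[nonzero])
    p <- pchisq(x2, df = 1, lower.tail = FALSE)
  } else {
    rare <- min(nA, na)
    hets <- seq(rare %% 2, rare, by = 2)
    lp <- vapply(hets, function(h) {
      n_hom1 <- (nA - h) / 2
      n_hom2 <- (na - h) / 2
      if (n_hom1 < 0 || n_hom2 < 0) return(-Inf)
      lgamma(n + 1) - lgamma(n_hom1 + 1) - lgamma(h + 1) -
        lgamma(n_hom2 + 1) + h * log(2) +
        lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    prob <- exp(lp - max(lp))
    prob <- prob / sum(prob)
    obs <- prob[match(Aa, hets)]
    p <- min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
  }
  structure(list(p = p, violates = p < alpha, method = method,
                 testable = TRUE),
            class = "hwe_result")
}

#' Hardy-Weinberg test for a study record's control group
#'
#' Statistics-only and family records carry no control genotype table and
#' return a `testable = FALSE` marker rather than an error.
#'
#' @param record a one-row study-table data frame.
#' @param config a [meta_config()] (`hwe_alpha`, `hwe_method`).
#' @return an `hwe_result`; `testable = FALSE` when no genotype payload.
#' @export
hwe_test_record <- function(record, config = meta_config()) {
  config <- as_meta_config(config)
  if (!has_genotype_payload(record))
    return(structure(list(p = NA_real_, violates = FALSE,
                          method = config$hwe_method, testable = FALSE),
                     class = "hwe_result"))
  hwe_exact_test(record$ctrl_AA, record$ctrl_Aa, record$ctrl_aa,
                 alpha = config$hwe_alpha, method = config$hwe_method)
}
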