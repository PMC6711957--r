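NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(COMPLEMENT[x])

#' Is an allele pair palindromic?
#'
#' A/T and C/G variants read the same on both strands, so strand cannot be
#' inferred from allele labels alone.
#'
#' @param a1,a2 single nucleotide characters.
#' @return logical.
#' @export
is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & complement_allele(a1) == a2
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  !is.na(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

# two-sided normal p for an estimate/se pair
wald_p <- function(est, se) 2 * pnorm(-abs(est) / se)

# 95% CI on the log scale, normal multiplier 1.96 throughout
ci95 <- function(est, se) c(est - 1.96 * se, est + 1.96 * se)

stop_snpmeta <- function(..., class) {
  stop(structure(
    class = c(class, "snpmeta_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
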