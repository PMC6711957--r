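---
title: "Methods: pooling candidate-gene allelic association evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling candidate-gene allelic association evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

# The problem

Candidate-gene association studies of complex disease report their evidence
in wildly heterogeneous forms: genotype tables, allele counts, bare odds
ratios with a p-value or a 95% confidence interval, or — for family-based
designs — transmission counts in parent-offspring trios. Published alleles
may sit on either DNA strand, labels are sometimes swapped, and small
studies are more likely to be published when significant. `snpmeta`
implements the full chain needed to pool such evidence per SNP: effect
extraction, allele harmonization against a reference frequency panel,
fixed- and random-effects pooling with heterogeneity statistics,
outlier/influence/HWE sensitivity analyses, small-study-effects testing and
adjustment, and inverse-variance combination with GWAS summary statistics.
A synthetic-data generator reproduces the statistical structure of such
study collections so every stage is testable without any external data.

# Allelic effect extraction

Every study is reduced to an allelic effect `AE` — the natural-log odds
ratio for the study's reference allele — and a standard error `seAE`.

**Counts.** With allele counts $C_A^{(1)}, C_a^{(1)}$ in cases and
$C_A^{(0)}, C_a^{(0)}$ in controls,

$$\mathrm{AE} = \log\frac{C_A^{(1)} C_a^{(0)}}{C_a^{(1)} C_A^{(0)}},
\qquad
\mathrm{seAE} = \sqrt{\tfrac{1}{C_A^{(1)}} + \tfrac{1}{C_a^{(1)}} +
\tfrac{1}{C_A^{(0)}} + \tfrac{1}{C_a^{(0)}}}.$$

Genotype tables are collapsed first ($C_A = 2\,AA + Aa$); genotype and
allele payloads therefore always give identical estimates, and genotype
counts are preferred when both are present (they additionally support the
Hardy–Weinberg check). When any cell is zero the Haldane–Anscombe
correction adds 0.5 to all four cells, keeping the estimate and its
standard error finite; the same correction applies to trio counts.

**Reported statistics.** When only an odds ratio and p-value are available,
the standard error is back-calculated as
$\mathrm{seAE} = |\mathrm{AE}| / z(p)$ with the closed-form approximation
$z(p) = -0.862 + \sqrt{0.743 - 2.404 \ln p}$ to the two-sided normal
quantile $\Phi^{-1}(1-p/2)$. The reported p is assumed to be a two-sided
allelic-test p — an input contract that curation must enforce. The
approximation's accuracy is itself a tested property of the package:

```{r approx}
p <- exp(seq(log(1e-8), log(0.5), length.out = 500))
rel_err <- abs((-0.862 + sqrt(0.743 - 2.404 * log(p))) -
                 qnorm(1 - p / 2)) / qnorm(1 - p / 2)
range(p[rel_err <= 0.005])   # where the approximation is within 0.5%
max(rel_err)                 # worst case at the p = 0.5 end
```

It is excellent in the range where published candidate-gene p-values
actually live (roughly 5e-4 to 0.2) and degrades to about 2% at the
extremes; records reporting an exact OR of 1 cannot use this route at all
(the standard error is 0/0) and are routed to the CI branch or excluded.

When a 95% CI is available it is preferred over the p-value and the
standard error is taken from the log-scale interval width,
$\mathrm{seAE} = (\log CI_{up} - \log CI_{low})/(2 \times 1.96)$, matching
how confidence intervals of odds ratios are constructed. A
`ci_se_literal` compatibility flag preserves the scale-mixing form
$CI_{up} - OR$ for audit of legacy curation; it is never the default.

**Trios.** Family studies contribute the Kazeem–Farrall log relative risk
$\mathrm{AE} = \log(C_T/C_N)$ from transmissions and non-transmissions of
the reference allele by heterozygous parents. Its sampling variance is
$1/C_T + 1/C_N$, so the standard error is the square root of that sum; a
`trio_se_literal` flag reproduces the variance-as-se form for comparison
with sources that print the formula without the root.

# Harmonization and quality control

All effects are re-expressed for the reference panel's **minor allele on
the forward strand** before pooling, using a per-population MAF table
(ancestry maps to panel population as Asian → EAS, Caucasian → EUR by
default; records with ancestry `Other` are pooled but cannot be
frequency-checked). The decision procedure per record:

1. If the reported allele pair matches the reference pair, the reported
   control frequency of the minor allele $f$ is compared with the panel
   MAF. A deviation $|f - \mathrm{MAF}| > 0.2$ that simultaneously matches
   the complementary labelling ($|f - (1-\mathrm{MAF})| \le 0.1$) marks
   switched labels: the effect sign is flipped. Both thresholds are config
   keys (`switch_maf_delta`, `switch_match_tol`); the defaults separate
   genuine label errors from subpopulation frequency drift, and
   discordant-but-unmatched frequencies are kept with a warning note
   rather than silently switched.
2. A pair matching only the complement of the reference alleles is flipped
   to the forward strand, then checked as in 1.
3. Palindromic (A/T, C/G) variants carry no strand information in their
   labels. When the panel MAF lies in the ambiguity window
   (`palindromic_window`, default [0.4, 0.6]) orientation is undecidable
   and the record is excluded; outside the window the reported frequency's
   side of 0.5 orients the record, and records with no frequency at all
   are excluded.
4. Pairs matching neither orientation are excluded as unresolved.

Sign coherence is exact: enabling the simulator's strand-error channel
changes every raw record but leaves every pooled estimate identical to
machine precision. Label-error correction is exact too wherever the
frequency rule has power — it requires a record-level control frequency
(trio records have none) and a panel MAF far enough from 0.5 that a 0.2
deviation is observable.

Control-group Hardy–Weinberg equilibrium is tested with the conditional
exact test (summing the probabilities of heterozygote counts no more
probable than the observed one under
$P(n_{Aa}\mid n, n_A) \propto \binom{n}{n_{AA},\,n_{Aa},\,n_{aa}} 2^{n_{Aa}}$);
a chi-square variant is available by config. The two order the sample
space differently, so mid-range p-values can drift apart; their rejection
decisions at $\alpha = 0.05$ agree, which is what the exclusion rule uses.
HWE exclusion is applied only in the sensitivity re-analysis, never in the
primary analysis. Statistics-only records are HWE-untestable and are
marked as such.

A SNP × population stratum is analyzed only when **four or more**
non-excluded studies remain (`min_k`).

# Pooling and heterogeneity

Fixed-effects weights are $w_i = 1/\mathrm{se}_i^2$. The
DerSimonian–Laird random-effects model adds the moment estimate of the
between-study variance,

$$\hat\tau^2 = \max\!\left(0,\;
\frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
\qquad Q = \sum_i w_i (\mathrm{AE}_i - \hat\mu_F)^2,$$

and re-pools with weights $1/(\mathrm{se}_i^2 + \hat\tau^2)$.
Heterogeneity is summarized as Higgins's
$I^2 = 100 \cdot \max\{0, (Q - (k-1))/Q\}$, the percentage of total
variation attributable to heterogeneity. All confidence intervals use the
normal 1.96 multiplier (no Knapp–Hartung adjustment), and p-values are
two-sided normal. Random-effects results are the headline numbers; fixed
effects are always emitted alongside. Single-study strata are reported but
flagged degenerate, never pooled.

Two calibration facts worth knowing, both reproduced by the test suite:
with homogeneous studies the truncation $\hat\tau^2 \ge 0$ makes the
random-effects CI slightly conservative (empirical coverage near 0.96),
while with substantial heterogeneity and few studies (k ≈ 10,
$\tau^2 \approx 0.05$) it is mildly anti-conservative (coverage near
0.92) — the well-documented small-k behaviour of the DL estimator. The
same mechanism inflates the null rate of nominal findings for small,
heterogeneous strata, and the convention of presenting post-exclusion
sensitivity results inflates it further; dataset-level significance claims
should lean on the Bonferroni threshold, not the nominal one.

# Sensitivity analyses

Each study is deleted in turn and the model re-fit with $\tau^2$
re-estimated. A study is an **outlier** when its studentized deleted
residual

$$t_i = \frac{\mathrm{AE}_i - \hat\mu_{(-i)}}
{\sqrt{\mathrm{se}_i^2 + \hat\tau^2_{(-i)} + \mathrm{se}(\hat\mu_{(-i)})^2}}$$

exceeds 1.96 in absolute value (`outlier_z`), and **influential** when
$|\mathrm{DFFITS}_i| = |\hat\mu - \hat\mu_{(-i)}|/\mathrm{se}(\hat\mu_{(-i)})
> 3\sqrt{1/(k-1)}$ or
$\mathrm{COVRATIO}_i = \mathrm{var}(\hat\mu_{(-i)})/\mathrm{var}(\hat\mu)
< 1 - 3/(k-1)$ (multipliers are config keys; the cutoffs follow the
influence-diagnostics literature since no numeric rule is standard).
DFBETAS coincides with DFFITS in this intercept-only model and is reported
for completeness. Two independent re-analyses are always emitted: one
excluding the union of outliers and influential studies, one excluding
HWE-violating studies; the per-SNP `presented` result uses the
outlier/influence sensitivity estimate whenever exclusions occurred, and
the primary estimate otherwise. Exclusions that drop a stratum below four
studies mark it ineligible after sensitivity exclusion.

# Small-study effects

For strata with at least ten studies (`bias_min_k`, following the usual
recommendation against testing smaller collections), funnel asymmetry is
tested with Harbord's score-based regression: each 2×2 allele table
contributes the score $Z = a - E[a\mid\text{margins}]$ and hypergeometric
variance $V$; $Z/\sqrt V$ is regressed on $\sqrt V$ and the intercept
tested against $t_{k-2}$. The score form avoids the inflated type-I error
the classical Egger regression suffers with binary outcomes; the Egger
form is retained only as a fallback for strata where fewer than ten
studies carry tables (statistics-only records contribute no score), and
the report records which test ran.

When asymmetry is significant at `bias_alpha`, Duval–Tweedie trim-and-fill
(L0 estimator by default, R0 by config) estimates the number of suppressed
studies from the signed ranks of centered effects, trims and re-centers
iteratively (the center re-estimated by DL each round, at most 50
iterations), then fills mirrored pseudo-studies and reports the
random-effects estimate on the filled set. The side on which studies are
presumed missing is taken from the sign of the asymmetry-test intercept.
Filling never removes an observed study. Under one-sided censoring of a
null effect the adjustment moves the pooled estimate toward zero in well
over 80% of simulated collections; under a symmetric funnel it imputes
nothing and returns the unadjusted result.

# Combination with GWAS summary statistics

SNPs nominally significant (random-effects p < 0.05 in any analyzed
stratum) are eligible for an expanded meta-analysis. Per-cohort GWAS
effects are harmonized with the same decision procedure (using the
reported effect-allele frequency; palindromic records without one are
excluded) and combined with the candidate-gene evidence by inverse
variance. The candidate side enters as a single pooled random-effects
estimate per SNP — by default the Asian stratum, because Caucasian
candidate-gene samples are presumed to overlap the large Caucasian GWAS
consortia (`exclude_caucasian_candidates`); a config switch allows
study-level entry instead. The fixed-effects Z-statistic is reported
unless heterogeneity across the combined inputs is pronounced
($I^2 > 75$, `i2_model_switch`), in which case the DerSimonian–Laird
random-effects Z is used (the normal-quantile DL form; no published
definition pins the random-effects Z beyond the model choice).

Dataset-level significance uses the Bonferroni threshold $0.05/m$ with
$m$ the number of meta-analyzed SNPs (not SNP × population tests; a
config switch flips this).

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the pipeline
assumes, not any particular gene. Per SNP: an allele pair (palindromic
with probability 0.15), ancestry-specific control minor-allele frequencies
uniform on [0.05, 0.5], a study count $4 + \mathrm{Geom}(0.32)$ (median 5,
quartiles about 4–7), and per-study true effects
$\theta_i \sim N(\theta, \tau^2)$. Case-control studies draw control
genotypes multinomially under Hardy–Weinberg equilibrium at the control
frequency (or with inbreeding coefficient F for contaminated studies) and
case genotypes at $\mathrm{logit}^{-1}(\mathrm{logit}(maf) + \theta_i)$ —
the per-allele odds model matching the allelic odds ratio the pipeline
estimates — so genotype and allele payloads are consistent by
construction. Per-arm subject counts are LogNormal(log 430, 0.6), making a
SNP's combined case+control sample size median about 5,500, the scale of
real candidate-gene collections. Trio studies draw transmissions
binomially at $\mathrm{logit}^{-1}(\theta_i)$.

Reporting filters then model the observation process: publication (keep
if the study's own Wald p < α, else with probability γ), reduction to
statistics-only records (counts stripped, OR with CI or p retained),
strand errors (allele letters complemented) and label errors (allele
letters swapped while counts stay put). Each SNP runs on an RNG stream
derived from the master seed and the SNP index, so per-SNP data are
reproducible regardless of dataset size or order.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium between SNPs,
haplotype effects, duplicated or overlapping samples across studies,
genotyping error beyond the inbreeding channel, population stratification
within ancestry groups, and the selective non-reporting of whole SNPs
within published studies.

# Numerical choices and degenerate inputs

Continuity correction 0.5 on all four cells (or both trio counts) only
when a zero occurs; empty study arms are extraction errors. OR = 1 with
only a p-value is an extraction error instructing fallback or exclusion.
$I^2$ truncates at 0, as does $\hat\tau^2$. Rank ties in trim-and-fill are
broken by first occurrence; the estimator caps $k_0$ at $k - 1$. The exact
HWE p-value accumulates probabilities with a $1 + 10^{-9}$ slack to absorb
floating-point ties, and works on log-scale weights to survive large
tables. Reference MAFs are capped at 0.5 by validation; a reported
frequency of exactly 0.5 cannot orient a palindromic record. All
problem-size choices in the test suite (fixtures of 3–15 studies,
simulation batches of 200–1000 replicates) were picked to make the Monte
Carlo error small relative to the property being asserted.

# Known limitations

Statistics-only records cannot be HWE-checked, contribute no Harbord
score and no subject counts, so dataset summaries of sample size cover
count-bearing studies only. The p-based standard-error route inherits the
approximation error quantified above. Harmonization cannot rescue label
errors on trio records or on SNPs with panel MAF near 0.5; such errors
pass through undetected, which is a property of the frequency rule itself,
not of its implementation. The pipeline treats studies as independent —
overlapping samples bias pooled estimates in either direction and must be
handled upstream.
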