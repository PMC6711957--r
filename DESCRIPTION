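Package: snpmeta
Title: Meta-Analysis of Candidate-Gene Allelic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for pooling published single-nucleotide polymorphism
    (SNP) association evidence across heterogeneous study designs. Per-study
    allelic effects (log odds ratios) are extracted from genotype or allele
    count tables, from reported odds ratios with p-values or confidence
    intervals, or from transmission counts in family trios; alleles are
    harmonized to a reference panel's forward strand and minor/major
    labelling, with frequency-based resolution or exclusion of palindromic
    variants; effects are pooled under fixed-effects and DerSimonian-Laird
    random-effects models with Cochran's Q and Higgins's I-squared;
    leave-one-out influence diagnostics, outlier detection and
    Hardy-Weinberg sensitivity re-analyses are computed per SNP; small-study
    effects are tested with Harbord's score-based regression and adjusted by
    trim-and-fill; and candidate-gene results can be combined with GWAS
    summary statistics by inverse variance. A synthetic-data generator
    emulating between-study heterogeneity, publication bias, strand and
    allele-label errors makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
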