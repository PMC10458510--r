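Package: micromr
Title: Two-Sample Mendelian Randomization for Microbiome, Metabolite and
    Pathway Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of gut-microbiome
    taxon abundances, blood metabolites and microbial pathways against binary
    disease outcomes such as respiratory tract infections. Provides reading,
    validation and effect-allele harmonization of GWAS summary statistics;
    instrument selection by significance and minor-allele-frequency thresholds,
    greedy LD clumping, and R-squared/F instrument-strength filtering with a
    file-based confounder exclusion list; five causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple and weighted
    mode) with odds-ratio reporting; sensitivity analyses (Cochran's Q
    heterogeneity, MR-Egger intercept pleiotropy, Steiger directionality) and
    category-wise Bonferroni correction; a seeded generator of synthetic GWAS
    summary statistics for pipeline testing without data downloads; and an
    orchestrating study pipeline that emits tidy per-method report tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
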