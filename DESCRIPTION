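Package: proteogpc
Title: Proteomic Subtyping and Pharmaco-Proteogenomic Analysis of
    Glioblastoma TMT Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrated
    pharmaco-proteogenomic analysis of IDH wild-type glioblastoma
    cohorts profiled by isobaric TMT labeling against pooled global
    internal standards (GIS).  Covers GIS ratio normalization, median
    centering, second-smallest imputation and GIS-coverage filtering;
    phosphopeptide-to-phosphosite aggregation with intensity-weighted
    class averaging; consensus clustering with PAC-based selection of
    the number of proteomic subtypes (GPC1/GPC2); differential protein
    and phosphoprotein testing with a same-direction phosphoprotein
    filter; hypergeometric over-representation analysis and
    single-sample GSEA; a signature delta-Z permutation classifier for
    surrogate subtyping of bulk and single-cell expression; drug
    screen processing (viability smoothing, trapezoidal AUC,
    four-parameter log-logistic ED50 with a top-dose cap) with
    subtype-selectivity and biomarker-correlation statistics; and
    construction of sample-specific variant-peptide databases from
    transcript models and variant calls.  Synthetic-data generators
    emulate every input so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    minpack.lm,
    pracma,
    randomForest,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
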