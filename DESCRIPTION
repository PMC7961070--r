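Package: tilmark
Title: Biomarkers of Tumour-Reactive TIL Products in Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which ovarian-cancer patients yield
    tumour-reactive (TR) tumour-infiltrating lymphocyte (TIL) products.
    Implements tumour-only somatic SNV filtering with an auditable filter
    cascade and panel-normalised tumour mutational burden (TMB); nCounter-style
    normalisation of immune gene-expression count matrices with log10
    signature scoring (IFN-gamma, Expanded immune, T-cell-inflamed GEP) and
    differential expression; the ELISPOT specific-spot reactivity statistic
    with positivity, HLA-I-restriction and tumour-specificity calls; flow
    cytometry subset frequencies and multiplex-immunofluorescence field
    percentages; exact and Monte-Carlo small-sample nonparametric tests; the
    joint TMB/GEP OR-rule stratification; and a seeded synthetic-cohort
    generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
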