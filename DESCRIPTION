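Package: ovcand
Title: Cross-Species Candidate Gene Prioritization for Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes ovarian cancer candidate genes by intersecting
    genes regulated in murine ovarian surface epithelium across the
    estrous cycle with genes dysregulated in human ovarian cancer, and
    triaging the overlap against copy-number, somatic-mutation,
    immunohistochemistry and survival evidence. Includes a two-class
    permutation differential-expression caller (SAM-style d statistic
    with fudge factor and permutation q-values), mouse-to-human ortholog
    harmonization, gene-set overlap enrichment tests, dual-source
    copy-number consensus and expression-concordance tests, mutation
    catalog triage, histoscore quantification with paired and ANOVA/LSD
    comparisons, Kaplan-Meier and log-rank survival analysis, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
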