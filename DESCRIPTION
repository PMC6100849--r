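Package: weedspread
Title: Residence-Time-Corrected Spread Analysis of Naturalized Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing Darwin's naturalization hypothesis on herbarium
    records of nonnative weeds. Implements detection-effort correction of
    residence times via a saturating collection-effort model, log-log
    regression of occupied localities on adjusted residence time with
    confidence-band classification of species into widespread and
    limited-spread sets, kinship association tests (chi-squared, Spearman,
    Mann-Whitney), attribute screening through Jaccard/UPGMA/cophenetic
    analysis, nonmetric multidimensional scaling with permutation-based
    vector fitting, and clustering-on-subsets-of-attributes (COSA) attribute
    importance with randomization nulls. A synthetic herbarium-data generator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    ape,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
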