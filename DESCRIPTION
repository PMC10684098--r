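Package: vitdgwas
Title: Cross-Ancestry Genetic Analysis of 25-Hydroxyvitamin D
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, simulation-backed pipeline for the genetic analysis of
    serum 25-hydroxyvitamin D (25OHD) across ancestry groups: multi-ancestry
    cohort simulation with known genetic truth (Balding-Nichols allele
    frequencies, block LD, seasonal phenotype component, ordinal skin colour),
    principal-component ancestry assignment with a multivariate Gaussian
    posterior, two-component (bK-thresholded) GREML heritability, additive and
    dominance genome-wide association testing, conditional-and-joint selection
    of independent loci from summary statistics, skin-colour-stratified
    meta-analysis with new/lost locus classification, error-adjusted
    cross-population effect-size correlation, vQTL-based gene-by-skin-colour
    interaction testing, permutation enrichment, and analytic power from the
    non-centrality parameter of the association chi-square test. Reads and
    writes PLINK bed/bim/fam and COJO .ma summary files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    metafor,
    jsonlite
Config/testthat/edition: 3
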