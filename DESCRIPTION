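Package: msatcc
Title: Microsatellite Case-Control Association, Loss of Heterozygosity
    and Repeat Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-locus microsatellite case-control studies in
    wildlife populations: homozygosity odds ratios from logit-link binomial
    models with likelihood-ratio tests, Mantel-Haenszel common odds ratios
    with continuity-corrected Cochran-Mantel-Haenszel chi-squared tests and
    the Breslow-Day-Tarone homogeneity test over per-allele strata,
    grid-based binomial genotype-risk profiles, loss-of-heterozygosity
    calling from paired-tissue electropherogram peak-height ratios, repeat
    structure parsing and instability detection for dinucleotide
    microsatellites, and sliding-window percent identity with low-identity
    masking over aligned sequence pairs. Includes a synthetic-data
    generator emulating an inbred population with a homozygosity-linked
    disease model, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
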