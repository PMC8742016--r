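Package: pedmut
Title: Direct Estimation of the Spontaneous Germline Mutation Rate from
    Pedigree Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the spontaneous single-nucleotide germline
    mutation rate per site per generation from whole-genome joint variant
    calls of a single mating pair and its offspring. Implements paternity
    confirmation among candidate males (KING-robust kinship with a rank-sum
    comparison, and Mendelian concordance at opposite-homozygote sites),
    trio-based de novo mutation filtering with a focal/bait offspring
    design, exact callable-site accounting from per-sample depth masks,
    false-negative-rate estimation by synthetic mutation spike-in with
    empirical allele-depth matching, and FNR-corrected rate estimation with
    exact Poisson (Garwood) confidence intervals. Includes a synthetic
    pedigree generator with planted mutations, sequencing error and shared
    mis-mapping artifacts for validation and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
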