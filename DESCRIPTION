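Package: regvaran
Title: Regulatory Region Databases and Prioritization of Non-Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a queryable database of regulatory regions (enhancers,
    promoters, silencers, insulators, bivalent elements) from heterogeneous
    region tables, computes a per-region variation-constraint metric from
    observed variant counts via a covariate-adjusted expectation model,
    benchmarks non-coding impact prediction scores with ROC-based threshold
    calibration, annotates VCF variants with regulatory evidence, and assigns
    a four-level prioritization integrating population allele frequency,
    functional elements, prediction scores, region constraint and HPO-driven
    gene ranking, including trio segregation and compound-heterozygote
    filters. Ships a seeded synthetic-data generator producing genomes,
    region catalogs, score tracks, labeled variant sets and trio VCFs for
    testing the full pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    DBI,
    RSQLite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
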