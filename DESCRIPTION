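Package: sparGWAS
Title: Semi-Parallel Logistic Regression GWAS with Encryption-Friendly
    Numerics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plaintext implementation of a semi-parallel logistic
    regression pipeline for genome-wide association studies, using the
    numeric machinery designed for evaluation under torus-based
    homomorphic encryption: gradient descent with a lookup-table
    discretized sigmoid, Gram-matrix score statistics for all SNPs at
    once, Taylor-series and Cholesky Gram inversion, fixed-point torus
    scaling with range simulation and overflow checks, and a log-domain
    statistic built from an even least-squares polynomial approximation
    of a smoothed log-absolute-value. Includes a synthetic genotype and
    phenotype generator, file ingestion from CSV/TSV/VCF, and a
    projection-based oracle used to validate the simplified statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
biocViews: GenomeWideAssociation, SNP, Regression, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
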