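Package: strpanel
Title: SNP-STR Haplotype Reference Panels, STR Imputation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building phased SNP plus short tandem repeat (STR)
    haplotype reference panels from quad families, imputing STR genotypes
    into SNP haplotypes by weighted haplotype matching, and evaluating
    imputation quality with concordance, length r-squared and allelic
    r-squared against random and naive null models. Includes locus-level
    quality control (call rate, expected heterozygosity, exact-binomial
    Hardy-Weinberg heterozygosity test, Mendelian inheritance rate,
    segmental-duplication and homopolymer filters), dosage-based
    association and power simulation for quantitative, case-control and
    quadratic trait models, expression STR (eSTR) regression with nested
    model comparison, and founder-haplotype Hamming-distance analysis.
    A stepwise-mutation simulator with tunable SNP-STR linkage
    disequilibrium, PCR stutter and dropout generates fully synthetic
    cohorts so every stage can be exercised without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
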