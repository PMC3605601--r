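Package: ppgwas
Title: Privacy-Preserving Genome-Wide Association Testing on Secret-Shared Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-host secure multi-party computation engine
    (3-out-of-3 additive secret sharing over a ring of modulus 2^k, Beaver-triple
    multiplication, dealer-assisted comparison) and runs genome-wide association
    tests on secret-shared genotype and phenotype data. Genotype calls are encoded
    as allele-count pairs, case and control cohorts are formed from plaintext
    member lists or evaluated obliviously from inclusion criteria, contingency
    tables are assembled by secure inner products, and chi-square,
    Cochran-Armitage trend and transmission disequilibrium statistics are held as
    exact integer fractions whose significance against a rational chi-square
    critical-value threshold is decided by secure comparison, with Bonferroni and
    an oblivious Benjamini-Hochberg procedure. Only per-SNP decision bits are ever
    released. Includes a synthetic-data generator (Hardy-Weinberg genotypes,
    planted associations, parent-child trios with transmission distortion) and an
    exact plaintext reference pipeline for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
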