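Package: sibkit
Title: Sibling-Pair Recombination Mapping and Polygenic Score Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects DNA recombination breakpoints from the genotypes of two
    siblings alone (no parental genotypes required) by scanning for statistical
    discontinuities in flanking-window genotype similarity, and aggregates the
    resulting break catalogs into per-chromosome genetic map lengths,
    cumulative maps and hotspot densities. Also implements the classical
    population-genetics statistics used to quantify sibling versus population
    variation in polygenic scores: the sqrt(2) variance law for sibling score
    differences, assortative-mating and narrow-sense heritability estimators,
    family closure and score centering, a liability mixture model of absolute
    disease risk, and a life-year weighted composite health index. A built-in
    meiosis and cohort simulator (phased parental haplotypes, genetic-map
    driven crossovers with optional gamma-renewal interference, genotyping
    error, configurable assortative mating and heritability) provides ground
    truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
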