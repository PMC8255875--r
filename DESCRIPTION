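Package: breeddiv
Title: Conservation-Genetics Analysis of SNP-Array Genotypes in Livestock Breeds
Version: 0.1.0
Authors@R: person("breeddiv", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for within- and between-breed conservation-genetics analysis of
    diploid biallelic SNP-array genotypes in PLINK text (PED/MAP) format: quality
    control, per-breed diversity statistics (MAF, observed and expected
    heterozygosity, identity-by-state distance), runs-of-homozygosity detection and
    the genomic inbreeding coefficient F_ROH, linkage-disequilibrium decay and
    LD-based current and historical effective population size, principal component
    analysis of the genotype matrix, Weir-Cockerham F_ST, Tajima-Nei evolutionary
    distances with neighbour-joining tree construction, and a forward-time
    Wright-Fisher multi-breed simulator that produces PLINK-format synthetic data
    with known demographic truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
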