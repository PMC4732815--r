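Package: canidiv
Title: Genealogical and Molecular Genome Diversity Analysis for Dog Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing genetic diversity in closed dog-breed
    populations from pedigree registries and SNP-array genotypes.
    Pedigree-based statistics include Meuwissen-Luo inbreeding
    coefficients, complete equivalent generations, generation interval,
    effective numbers of founders and ancestors from probabilities of
    gene origin, the inbreeding rate per generation and the realized
    effective population size. Molecular statistics include multilocus
    heterozygosity, excess-homozygosity inbreeding, runs of homozygosity
    with length-class F_ROH, and the linkage-disequilibrium effective
    population size. Population structure is summarised through
    identity-by-state distances, mutual k-nearest-neighbour networks with
    community detection, and neighbour-joining trees. Pedigree, gene-drop
    and Wright-Fisher simulators provide ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
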