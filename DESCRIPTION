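Package: dompop
Title: Dominant-Marker Population Genetics: Diversity, Assignment and
    Outlier Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dominant (presence/absence) marker data
    such as AFLP band matrices, aimed at highly selfing plant
    metapopulations. Covers marker quality control (replicate error rate,
    clone detection, size-homoplasy screen, linkage-disequilibrium scan,
    frequency filtering), Bayesian estimation of null-allele frequencies
    under partial selfing, genetic diversity statistics (proportion of
    polymorphic loci, Nei's gene diversity, frequency-down-weighted
    rarity), population structure (Fst with permutation tests, Phi-PT
    AMOVA, Nei distances, principal coordinates, bootstrap
    neighbour-joining consensus trees, Mantel isolation-by-distance),
    a gridded sliding-window Shannon diversity map, band-frequency
    likelihood assignment tests with simulated power and exclusion
    p-values yielding bounds on effective long-distance dispersal rates,
    and an Fst-outlier scan (heterozygosity-conditional simulation
    envelope and a spike-and-slab Bayesian detector) with multi-scale
    consensus and replication decision rules. Includes a metapopulation
    simulator with planted migrants, selected loci, genotyping error and
    replicate samples for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    phangorn,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
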