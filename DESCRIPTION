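Package: breedpop
Title: Temporal Population Structure and Diversity in Hybrid Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to track the evolution of population structure and genetic
    diversity across the history of a hybrid breeding program organised in
    complementary heterotic groups. Implements the per-marker two-population
    Weir-Cockerham fixation index (theta) with a resampling variance protocol,
    expected heterozygosity and minor-allele-frequency fixation indicators,
    pairwise Hamming distances, intrachromosomal linkage-disequilibrium decay
    summarised by a monotone-decreasing convex penalized B-spline, eigenstrat
    principal components, supervised admixture-proportion estimation with
    cluster maximum assignation probability (CMAP) classification, and a
    forward-time simulator of a two-heterotic-group inbred development program
    (three ancestral founder pools, recurrent selection, doubled haploids,
    gene flow, and a programmed pool merge) for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    pracma,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
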