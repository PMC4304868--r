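Package: copyvar
Title: Intragenomic Polymorphism Detection in High-Copy Loci from Shotgun Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes polymorphisms among the copies of a high-copy locus
    (such as the 18S-ITS1-5.8S-ITS2-26S nuclear ribosomal DNA cistron) within
    individual genomes sequenced by low-coverage shotgun ("genome skimming")
    reads. Provides per-position tallies of reads differing from each
    individual's consensus, classification of sites as polymorphic (>= 2
    percent differing reads) or highly polymorphic (>= 10 percent), projection
    of per-sample profiles into shared group-reference coordinates, region and
    secondary-structure statistics (logistic regression and type III ANOVA),
    and phylogenetic-signal analyses of polymorphism abundance
    (squared-change parsimony ancestral states, tip-permutation tests, Pagel's
    lambda likelihood-ratio tests, and bounded Brownian-motion simulation).
    Includes a synthetic-data generator producing copy pools with planted
    variant frequencies, error-bearing reads, and lambda-scaled Brownian
    traits, so the full pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
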