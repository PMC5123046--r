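Package: consensusRef
Title: Population Consensus Reference Construction and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a population consensus reference genome by substituting
    cohort-major single-nucleotide alleles and cohort-frequent indels into a
    baseline reference under ploidy-aware haploid-count thresholds, tracks the
    induced coordinate changes as a UCSC lift-over chain, and quantifies how
    reference choice changes variant calls. Also provides structural-variant
    concordance machinery (reciprocal-overlap identity, single-end/paired-end
    read-ratio misassembly filtering by Fisher's exact test, exclusive sharing
    decomposition, novelty annotation, group enrichment), assembly statistics
    (Nxx/Lxx, gap fraction, genome recovery rate, novel-region detection), and
    rule-based chromosome building from scaffold alignment anchors with AGP
    emission. Seeded synthetic-data generators with planted ground truth make
    the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
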