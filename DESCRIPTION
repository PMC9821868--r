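Package: sleepv2g
Title: Variant-to-Gene Mapping of Sleep GWAS Loci and Cross-Species Sleep Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map GWAS association signals to candidate effector genes
    through open chromatin and promoter-focused Capture C chromatin loops, and
    to phenotype sleep in Drosophila and larval zebrafish. Includes in-silico
    restriction digestion and fragment-resolution annotation of promoter
    interactions, LD-proxy expansion and expression filtering, activity-monitor
    sleep-bout scoring and RNAi screen hit calling, arousal-threshold and
    reactivity analysis, movement-threshold zebrafish sleep scoring with
    Welch-corrected group comparison and a CRISPR mutation-efficiency inclusion
    filter, plus a seeded synthetic-data generator that plants known effector
    genes and sleep effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    graphics,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
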