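Package: sedchiron
Title: Sediment DNA Metabarcoding of Chironomidae Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterising Chironomidae (non-biting
    midge) assemblages in lake-sediment DNA (sedDNA) by CO1 amplicon
    metabarcoding. Covers curation of a reference sequence database with
    in-silico PCR against degenerate primer sets, paired-end read processing
    into denoised exact sequence variants (ESVs) via d=1 single-linkage
    clustering with chimera and numt (nuclear mitochondrial pseudogene)
    filtering, best-hit plus lowest-common-ancestor taxonomic assignment with
    a 95 percent species-identity threshold, translation of assignments to
    chitinous-remain morphotypes, and presence-absence assemblage comparison
    by detrended correspondence analysis. A synthetic-data generator emulates
    CO1 amplicon reads with quality-driven errors, chimeras, numts and
    contaminants, structured into sediment cores and layers with controllable
    taxon sharing, so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
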