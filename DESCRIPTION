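Package: pamscape
Title: CRISPR PAM Site Repertoires, Density Statistics, Guide Design and
    Indel Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide enumeration of degenerate protospacer-adjacent
    motif (PAM) classes on both strands of a genome, BED annotation of
    candidate CRISPR target sites and their intersection with coding
    exons, closed-form and simulated site-density statistics under an
    i.i.d. base-composition model, oligo design for cloning-free
    T7-transcribed guide-RNA templates, and amplicon indel
    characterization from Sanger-sequenced alleles and T7 endonuclease I
    band intensities.  Includes seeded synthetic-data generators (random
    genomes, exon intervals, planted PAM sites, mutant alleles) so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
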