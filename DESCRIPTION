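Package: polyfate
Title: Structural and Functional Fate of Duplicated Genes in an
    Allopolyploid Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for tracing the fate of duplicated genes
    in an allohexaploid grain transcriptome assayed by expressed-sequence
    reads.  Includes a synthetic allohexaploid transcriptome simulator
    (three diverged subgenomes, ancestral whole-genome-duplication paralog
    blocks, tandem copy-number variants, stage-wise expression truth and
    read sampling), greedy overlap read clustering into unigene clusters,
    cumulative-identity/cumulative-alignment-length (CIP/CALP) scoring of
    chained local-alignment HSPs with ortholog, tandem-CNV and
    presence/absence classification, homoeolog copy counting and
    merged-homoeolog flagging, synteny-based virtual gene ordering from
    prioritised reference genomes, duplicate-fate summaries (structural
    loss, expression divergence, concerted cross-species expression,
    gene-ontology bias, network enrichment, differential expression), and
    a logarithmic temporal model of post-duplication gene shuffling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
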