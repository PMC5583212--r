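Package: lncfibro
Title: Discovery and Prioritization of Renal-Fibrosis lncRNAs from Tissue and Urine RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying long non-coding RNA
    (lncRNA) candidates in a rodent model of renal fibrosis (unilateral
    ureteral obstruction, UUO, versus sham surgery) and prioritizing them as
    TGF-beta pathway candidates and urinary biomarkers. Stages: consensus
    coding-potential filtering of transcripts, RPKM-based differential
    expression in renal tissue and urine, cis-neighbor search for
    protein-coding genes within 100 kb of dysregulated lncRNA loci, Smad3
    binding-element (CAGACA) scanning of 5 kb putative promoters with a
    more-than-4-motifs prioritization rule, tissue-urine concordance for
    biomarker candidates, and 2^-ddCt qPCR quantification with reference-gene
    or spike-in normalization. Ships a fully deterministic synthetic-data
    generator (genome, annotation, negative-binomial counts, Ct tables) with
    planted ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
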