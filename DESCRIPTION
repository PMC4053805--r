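Package: readthroughr
Title: Readthrough Transcription and Upstream Divergent RNA Detection from
    Strand-Specific RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for strand-specific RNA-seq of perturbation
    experiments (e.g. 7SK snRNA knockdown with antisense oligonucleotides)
    in which changes in transcription extend beyond annotated gene bodies.
    Implements background-adjusted gene expression calling against local
    intronic/intergenic transcription, detection of upstream divergent RNA
    (udRNA) transcription units with a two-fold-over-background criterion,
    detection of failed transcriptional termination (readthrough) downstream
    of polyadenylation sites with change-point estimation of its genomic
    extent, TMM and total-count normalization, negative-binomial differential
    testing with per-oligo intersection, feature-overlap enrichment
    statistics, and a synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    methods,
    edgeR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
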