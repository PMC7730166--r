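Package: peakcons
Title: Consensus ChIP-Seq Target-Gene Discovery and qPCR Candidate Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for prioritizing transcription-factor
    target genes from replicated ChIP-seq experiments and evaluating the
    resulting candidates by quantitative PCR. Peaks called per library pool
    (a simplified local-Poisson caller is included for synthetic coverage)
    are cleaned by IgG-control subtraction, assigned to genes by three
    independent annotation strategies (nearest TSS, windowed footprint,
    distance-decay regulatory potential), and a gene is selected when at
    least two annotators report it in at least two pools. Selected genes are
    grouped into distinct binding regions, scanned for over-represented
    sequence motifs by a ZOOPS EM stand-in with permutation E-values, and
    carried into a Ct-based expression workflow (expression calling at
    Ct < 35, the comparative ΔΔCt method, Student's t-tests, and
    correlation-based hierarchical clustering). Seeded synthetic generators
    produce every input with planted truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
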