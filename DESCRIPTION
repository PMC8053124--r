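Package: rearescan
Title: Genome-Wide Co-Occurrence Analysis of p63 Response Elements and
    NRF2 Antioxidant Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies composite RE-ARE regulatory elements, in which a
    p53-family (p63) response element (RE) and an NRF2 antioxidant
    response element (ARE) co-occur within a short spacer, permitting
    simultaneous binding of both transcription factors. Provides IUPAC
    degenerate consensus scanning of genome sequences on both strands,
    nearest-neighbour RE-to-ARE pairing with spacer statistics and a
    steric-feasibility filter, a randomized-genome null model with
    chromosome-length-proportional motif allocation, two-sample
    Kolmogorov-Smirnov enrichment testing of spacer and TSS-distance
    distributions, ChIP-seq peak containment annotation with per-state
    percentages and unique/common peak set algebra, closest-gene
    association within a distance cutoff, and a synthetic-genome
    generator with machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
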