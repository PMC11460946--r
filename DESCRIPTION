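Package: irminer
Title: Discovery of Putative ITIM/ITSM-Bearing Immune Inhibitory Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening pipeline for putative immune inhibitory receptors.
    Scans protein sequences for immunoreceptor tyrosine-based inhibitory and
    switch motifs (ITIM/ITSM), restricts hits to predicted intracellular
    domains using per-residue membrane-topology annotation, estimates the
    chance of observing the motifs under composition-preserving sequence
    permutation, scores motif accessibility with per-residue AlphaFold-style
    structure confidence (pLDDT), and classifies candidate receptors into
    functional categories (threshold, negative feedback,
    threshold-disinhibition, threshold-negative feedback) from
    resting/activated expression data. Includes seed-reproducible synthetic
    fixture generators so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
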